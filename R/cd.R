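#' Mean residue ellipticity
#'
#' Normalises a CD signal in millidegrees per residue, path and
#' concentration: `MRE = CD(mdeg) / (10 n l Cp)` in deg cm^2 / dmol.
#'
#' @param cd_mdeg CD signal in mdeg; vectorised.
#' @param n_residues Number of amino-acid residues (583 for BSA).
#' @param path_cm Cuvette path length in cm.
#' @param protein_conc Protein concentration in mol/L.
#' @return Mean residue ellipticity in deg cm^2 / dmol.
#' @export
mean_residue_ellipticity <- function(cd_mdeg, n_residues = 583, path_cm = 0.1,
                                     protein_conc = 5e-6) {
  if (n_residues <= 0 || path_cm <= 0 || protein_conc <= 0)
    stop("n_residues, path_cm and protein_conc must be > 0", call. = FALSE)
  cd_mdeg / (10 * n_residues * path_cm * protein_conc)
}

#' Alpha-helix content from the 208 nm mean residue ellipticity
#'
#' Two-point formula anchored at the MRE of a beta/random-coil form (-4000)
#' and of a pure alpha-helix (-33000) at 208 nm:
#' `alpha(%) = (-MRE208 - 4000) / (33000 - 4000) * 100`. Values are not
#' clamped; results outside 0-100% indicate an MRE outside the anchor
#' range.
#'
#' @param mre_208 Mean residue ellipticity at 208 nm, deg cm^2 / dmol.
#' @return Alpha-helix content in percent (may lie outside `[0, 100]`).
#' @export
helix_percent <- function(mre_208) {
  stopifnot(all(is.finite(mre_208)))
  (-mre_208 - 4000) / (33000 - 4000) * 100
}

# MRE at exactly 208 nm via linear interpolation on the CD grid
mre_at_208 <- function(cd_spectrum, n_residues, path_cm, protein_conc) {
  validate_spectrum(cd_spectrum)
  w <- cd_spectrum$wavelength
  if (208 < w[1] || 208 > w[length(w)])
    stop("CD spectrum does not cover 208 nm (grid ", w[1], "-",
         w[length(w)], " nm)", call. = FALSE)
  cd208 <- stats::approx(w, cd_spectrum$value, xout = 208)$y
  mean_residue_ellipticity(cd208, n_residues, path_cm, protein_conc)
}

#' Helicity estimate from a CD spectrum
#'
#' Reads the CD signal at 208 nm (linear interpolation between the
#' bracketing grid points), converts to mean residue ellipticity and maps
#' to alpha-helix percent.
#'
#' @param cd_spectrum A [spectrum()] of kind `"cd"` covering 208 nm.
#' @inheritParams mean_residue_ellipticity
#' @return An object of class `helix_estimate`: `mre_208`, `alpha_percent`,
#'   `out_of_range` flag, and the normalisation inputs.
#' @export
helix_estimate <- function(cd_spectrum, n_residues = 583, path_cm = 0.1,
                           protein_conc = 5e-6) {
  mre <- mre_at_208(cd_spectrum, n_residues, path_cm, protein_conc)
  alpha <- helix_percent(mre)
  structure(list(mre_208 = mre, alpha_percent = alpha,
                 out_of_range = alpha < 0 || alpha > 100,
                 n_residues = n_residues, path_cm = path_cm,
                 protein_conc = protein_conc),
            class = "helix_estimate")
}

#' @export
print.helix_estimate <- function(x, ...) {
  cat(sprintf("<helix estimate: MRE208 = %.0f, alpha = %.2f%%%s>\n",
              x$mre_208, x$alpha_percent,
              if (x$out_of_range) " (out of range)" else ""))
  invisible(x)
}

#' Helicity change between free and ligand-bound protein
#'
#' @param free_spectrum,complex_spectrum CD [spectrum()] objects for the
#'   free protein and the protein-ligand complex, both covering 208 nm.
#' @inheritParams mean_residue_ellipticity
#' @return A list with `free` and `complex` [helix_estimate()]s and
#'   `delta` = complex - free in percentage points.
#' @export
helix_change <- function(free_spectrum, complex_spectrum, n_residues = 583,
                         path_cm = 0.1, protein_conc = 5e-6) {
  free <- helix_estimate(free_spectrum, n_residues, path_cm, protein_conc)
  cplx <- helix_estimate(complex_spectrum, n_residues, path_cm, protein_conc)
  list(free = free, complex = cplx,
       delta = cplx$alpha_percent - free$alpha_percent)
}
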