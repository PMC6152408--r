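#' Ground truth for the synthetic study generator
#'
#' Forward-model parameters from which titrations, temperature series and CD
#' spectra are simulated with a recoverable answer. Defaults describe a
#' typical flavonoid-BSA system: static quenching with Kb in the 1e4-1e5
#' L/mol range, 1:1 stoichiometry, exothermic binding with negative entropy
#' (van der Waals / hydrogen-bond type), 5 uM protein titrated to a 6:1
#' ligand:protein ratio, and ~59% native alpha-helix.
#'
#' @param model `"static_hill"` (F = F0 / (1 + Kb [Q]^n)) or `"dynamic_sv"`
#'   (F = F0 / (1 + Ksv [Q])); for the dynamic model `kb` plays the role of
#'   Ksv.
#' @param kb Binding (or Stern-Volmer) constant, L/mol.
#' @param n Hill stoichiometry (static model only).
#' @param delta_H Binding enthalpy, J/mol.
#' @param delta_S Binding entropy, J/mol/K.
#' @param F0 Ligand-free fluorescence intensity, a.u.
#' @param ife_ex,ife_em Inner-filter absorbance per mol/L of ligand at the
#'   excitation / emission wavelength (0 disables the inner-filter effect).
#' @param alpha_helix Native alpha-helix fraction in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise sd on intensities, a.u.
#' @param seed Integer seed making every generator deterministic.
#'
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(model = c("static_hill", "dynamic_sv"),
                         kb = 5e4, n = 1, delta_H = -38e3, delta_S = -38.1,
                         F0 = 1000, ife_ex = 0, ife_em = 0,
                         alpha_helix = 0.5861, noise_sd = 0, seed = 1L) {
  model <- match.arg(model)
  stopifnot(kb > 0, n > 0, F0 > 0, noise_sd >= 0,
            alpha_helix >= 0, alpha_helix <= 1, ife_ex >= 0, ife_em >= 0)
  structure(list(model = model, kb = kb, n = n, delta_H = delta_H,
                 delta_S = delta_S, F0 = F0, ife_ex = ife_ex,
                 ife_em = ife_em, alpha_helix = alpha_helix,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground truth: %s, Kb = %g L/mol, n = %g, seed %d>\n",
              x$model, x$kb, x$n, x$seed))
  invisible(x)
}

#' Default titration design
#'
#' Ligand concentrations at molar ratios 0, 1, 1.5, 2, 3, 4, 5 and 6 to the
#' protein (5 uM by default), i.e. 0-30 uM.
#'
#' @param protein_conc Protein concentration in mol/L.
#' @return Numeric vector of ligand concentrations in mol/L.
#' @export
default_ligand_concs <- function(protein_conc = 5e-6) {
  c(0, 1, 1.5, 2, 3, 4, 5, 6) * protein_conc
}

#' Default study temperatures
#' @return `c(289, 297, 307)` K.
#' @export
default_temperatures <- function() c(289, 297, 307)

# run expr with a local, seeded RNG without disturbing the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Gaussian spectral band
#'
#' A Gaussian profile parameterised by full width at half maximum, used to
#' emulate the tryptophan emission band of serum albumin (maximum near 340
#' nm when excited at 280 nm) and ligand absorbance bands.
#'
#' @param center Band centre in nm.
#' @param fwhm Full width at half maximum in nm (> 0).
#' @param amplitude Peak value, a.u.
#' @param grid Ascending wavelength grid in nm.
#' @inheritParams spectrum
#' @param ... Further metadata passed to [spectrum()].
#' @return A [spectrum()] object.
#' @export
gaussian_band <- function(center, fwhm, amplitude, grid, kind = "emission",
                          ...) {
  if (!length(grid)) stop("empty wavelength grid", call. = FALSE)
  if (fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  v <- amplitude * exp(-(grid - center)^2 / (2 * sigma^2))
  spectrum(grid, v, kind = kind, ...)
}

#' Simulate a fluorescence quenching titration
#'
#' Forward model of the binding analysis. For the static model,
#' `F = F0 / (1 + Kb [Q]^n)` (so `(F0 - F)/F = Kb [Q]^n` identically); for
#' the dynamic model, `F = F0 / (1 + Ksv [Q])`. Non-zero inner-filter
#' coefficients attenuate the observed signal by `10^-((A_ex + A_em)/2)`
#' with `A_ex = ife_ex [Q]`, `A_em = ife_em [Q]`, and the per-point
#' absorbances are recorded so [inner_filter_correct()] can undo them.
#' Gaussian noise of sd `noise_sd` is added under the ground-truth seed.
#'
#' @param truth A [ground_truth()].
#' @param ligand_concs Ligand concentrations (mol/L) starting at 0.
#' @param temperature Temperature in K recorded on the series.
#' @param protein_conc Protein concentration in mol/L.
#' @return A [titration_series()]; `corrected` is `FALSE` when the
#'   inner-filter effect was applied, `TRUE` otherwise.
#' @export
simulate_titration <- function(truth, ligand_concs = default_ligand_concs(),
                               temperature = 297,
                               protein_conc = 5e-6) {
  stopifnot(inherits(truth, "ground_truth"))
  q <- as.numeric(ligand_concs)
  if (any(q < 0)) stop("negative ligand concentrations", call. = FALSE)
  f_true <- switch(truth$model,
    static_hill = truth$F0 / (1 + truth$kb * q^truth$n),
    dynamic_sv = truth$F0 / (1 + truth$kb * q))
  ife <- truth$ife_ex > 0 || truth$ife_em > 0
  a_ex <- a_em <- NULL
  f_obs <- f_true
  if (ife) {
    a_ex <- truth$ife_ex * q
    a_em <- truth$ife_em * q
    f_obs <- f_true * 10^(-(a_ex + a_em) / 2)
  }
  if (truth$noise_sd > 0)
    f_obs <- f_obs + with_seed(truth$seed,
                               stats::rnorm(length(q), 0, truth$noise_sd))
  titration_series(q, f_obs, temperature = temperature,
                   protein_conc = protein_conc,
                   a_ex = a_ex, a_em = a_em, corrected = !ife)
}

#' Simulate a Van't Hoff temperature series
#'
#' Binding constants follow `Kb(T) = exp(-delta_H / (R T) + delta_S / R)`
#' with `R = 8.314` J/mol/K; one titration is generated per temperature
#' (seeded independently from the ground-truth seed).
#'
#' @param truth A [ground_truth()]; its `kb` is ignored in favour of the
#'   thermodynamic forward model.
#' @param temperatures At least two distinct temperatures in K.
#' @inheritParams simulate_titration
#' @return A list with `kb` (named by temperature) and `titrations`.
#' @export
simulate_temperature_series <- function(truth,
                                        temperatures =
                                          default_temperatures(),
                                        ligand_concs =
                                          default_ligand_concs(),
                                        protein_conc = 5e-6) {
  stopifnot(inherits(truth, "ground_truth"))
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 2L)
    stop("need at least 2 temperatures", call. = FALSE)
  if (anyDuplicated(temperatures) || any(temperatures <= 0))
    stop("temperatures must be distinct and > 0 K", call. = FALSE)
  kb <- exp(-truth$delta_H / (GAS_CONSTANT * temperatures) +
              truth$delta_S / GAS_CONSTANT)
  names(kb) <- format(temperatures)
  titrations <- lapply(seq_along(temperatures), function(i) {
    t_i <- truth
    t_i$kb <- kb[[i]]
    t_i$seed <- truth$seed + i
    simulate_titration(t_i, ligand_concs, temperature = temperatures[i],
                       protein_conc = protein_conc)
  })
  names(titrations) <- names(kb)
  list(kb = kb, titrations = titrations)
}

#' Simulate a far-UV CD spectrum with known helicity
#'
#' Builds an alpha-helix-like CD trace with two negative lobes near 208 and
#' 222 nm, scaled so that the mean residue ellipticity at 208 nm equals
#' `-(4000 + 29000 * alpha_fraction)` exactly; the millidegree signal is
#' `MRE * 10 * n_residues * path_cm * protein_conc`, inverting the
#' mean-residue-ellipticity normalisation.
#'
#' @param alpha_fraction Alpha-helix fraction in `[0, 1]`.
#' @param protein_conc Protein concentration in mol/L (> 0).
#' @param n_residues Number of amino-acid residues (583 for BSA).
#' @param path_cm Cuvette path length in cm (> 0).
#' @param grid Wavelength grid in nm; must cover 208 nm.
#' @return A [spectrum()] of kind `"cd"` in mdeg.
#' @export
simulate_cd <- function(alpha_fraction, protein_conc = 5e-6,
                        n_residues = 583, path_cm = 0.1,
                        grid = seq(200, 250, by = 1)) {
  stopifnot(alpha_fraction >= 0, alpha_fraction <= 1)
  if (protein_conc <= 0 || path_cm <= 0 || n_residues <= 0)
    stop("protein_conc, path_cm and n_residues must be > 0", call. = FALSE)
  mre_208 <- -(4000 + 29000 * alpha_fraction)
  cd_208 <- mre_208 * 10 * n_residues * path_cm * protein_conc
  # two-lobe helix-like shape; unit amplitude at 208 nm by construction
  shape <- function(l) {
    exp(-(l - 208)^2 / (2 * (9 / 2.3548)^2)) +
      0.92 * exp(-(l - 222)^2 / (2 * (11 / 2.3548)^2))
  }
  v <- cd_208 * shape(grid) / shape(208)
  spectrum(grid, v, kind = "cd", protein_conc = protein_conc)
}

#' Simulate a ligand absorbance spectrum
#'
#' Beer-Lambert absorbance `A = epsilon(lambda) * conc * 1 cm` with a
#' Gaussian molar absorptivity profile; used as FRET acceptor input.
#'
#' @param band_center Band centre in nm.
#' @param band_width Full width at half maximum in nm.
#' @param epsilon_max Peak molar absorptivity, L/mol/cm (> 0).
#' @param conc Ligand concentration in mol/L (>= 0).
#' @param grid Wavelength grid in nm.
#' @return A [spectrum()] of kind `"absorbance"`.
#' @export
simulate_absorbance <- function(band_center, band_width, epsilon_max, conc,
                                grid = seq(300, 400, by = 1)) {
  if (epsilon_max <= 0) stop("epsilon_max must be > 0", call. = FALSE)
  if (conc < 0) stop("negative concentration", call. = FALSE)
  sigma <- band_width / (2 * sqrt(2 * log(2)))
  eps <- epsilon_max * exp(-(grid - band_center)^2 / (2 * sigma^2))
  spectrum(grid, eps * conc, kind = "absorbance", ligand_conc = conc)
}

#' Emit a complete synthetic study to a directory
#'
#' Writes titrations at three temperatures, a donor emission spectrum, an
#' acceptor absorbance spectrum, a free/complex CD pair and a ground-truth
#' YAML into `dir`, giving every analysis stage a file-based input with a
#' known answer.
#'
#' @param dir Output directory (created if missing).
#' @param truth A [ground_truth()].
#' @param temperatures Temperatures in K.
#' @param alpha_complex Alpha-helix fraction of the ligand-bound protein.
#' @inheritParams simulate_titration
#' @return Invisibly, a named list of the files written.
#' @export
simulate_study <- function(dir, truth = ground_truth(),
                           temperatures = default_temperatures(),
                           ligand_concs = default_ligand_concs(),
                           protein_conc = 5e-6, alpha_complex = 0.6417) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts <- simulate_temperature_series(truth, temperatures, ligand_concs,
                                    protein_conc)
  files <- list()
  for (i in seq_along(temperatures)) {
    f <- file.path(dir, sprintf("titration_%gK.csv", temperatures[i]))
    write_titration(ts$titrations[[i]], f)
    files[[sprintf("titration_%g", temperatures[i])]] <- f
  }
  donor <- gaussian_band(340, 60, truth$F0, seq(290, 450, by = 1),
                         kind = "emission")
  files$donor <- file.path(dir, "donor_emission.csv")
  write_spectrum(donor, files$donor)
  acceptor <- simulate_absorbance(350, 50, 1.2e4, max(ligand_concs),
                                  grid = seq(300, 400, by = 1))
  files$acceptor <- file.path(dir, "acceptor_absorbance.csv")
  write_spectrum(acceptor, files$acceptor)
  files$cd_free <- file.path(dir, "cd_free.csv")
  write_spectrum(simulate_cd(truth$alpha_helix, protein_conc), files$cd_free)
  files$cd_complex <- file.path(dir, "cd_complex.csv")
  write_spectrum(simulate_cd(alpha_complex, protein_conc), files$cd_complex)
  files$truth <- file.path(dir, "ground_truth.yaml")
  yaml::write_yaml(c(unclass(truth),
                     list(temperatures = as.numeric(temperatures),
                          kb_by_temperature = as.list(ts$kb),
                          alpha_complex = alpha_complex,
                          protein_conc = protein_conc)),
                   files$truth)
  invisible(files)
}
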