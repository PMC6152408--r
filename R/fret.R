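#' Donor-acceptor spectral overlap integral
#'
#' `J = sum(F(l) eps(l) l^4 dl) / sum(F(l) dl)` over the overlapping
#' wavelength range, with the wavelength converted to cm so that J carries
#' the conventional unit cm^3 L / mol. Both spectra are resampled onto the
#' merged grid of the overlap region. The default evaluation is the
#' discrete Riemann sum; `method = "trapezoid"` uses trapezoidal weights
#' instead (the two agree closely on instrument-resolution grids).
#'
#' @param donor_emission Donor [spectrum()] (fluorescence, a.u.).
#' @param acceptor_molar_absorptivity Acceptor [spectrum()] whose values are
#'   molar absorptivity in L/mol/cm (divide an absorbance spectrum by
#'   concentration and path upstream).
#' @param method Quadrature weighting, `"riemann"` or `"trapezoid"`.
#' @return Overlap integral J in cm^3 L / mol.
#' @export
overlap_integral <- function(donor_emission, acceptor_molar_absorptivity,
                             method = c("riemann", "trapezoid")) {
  method <- match.arg(method)
  validate_spectrum(donor_emission)
  validate_spectrum(acceptor_molar_absorptivity)
  lo <- max(min(donor_emission$wavelength),
            min(acceptor_molar_absorptivity$wavelength))
  hi <- min(max(donor_emission$wavelength),
            max(acceptor_molar_absorptivity$wavelength))
  if (lo >= hi)
    stop("donor and acceptor grids do not overlap", call. = FALSE)
  grid <- sort(unique(c(
    donor_emission$wavelength[donor_emission$wavelength >= lo &
                                donor_emission$wavelength <= hi],
    acceptor_molar_absorptivity$wavelength[
      acceptor_molar_absorptivity$wavelength >= lo &
        acceptor_molar_absorptivity$wavelength <= hi],
    lo, hi)))
  if (length(grid) < 2L)
    stop("overlap region contains fewer than 2 grid points", call. = FALSE)
  f <- resample(donor_emission, grid)$value
  eps <- resample(acceptor_molar_absorptivity, grid)$value
  if (all(f == 0))
    stop("donor emission is zero over the overlap region", call. = FALSE)
  d <- diff(grid)
  w <- switch(method,
    riemann = c(d, d[length(d)]),
    trapezoid = c(d[1] / 2, (d[-length(d)] + d[-1]) / 2,
                  d[length(d)] / 2))
  lambda_cm <- grid * 1e-7
  sum(f * eps * lambda_cm^4 * w) / sum(f * w)
}

#' Forster radius from the overlap integral
#'
#' `R0^6 = 8.8e-25 k^2 N^-4 Phi J` (R0 in cm, J in cm^3 L / mol), returned
#' in nm. Defaults: isotropic orientation factor `k^2 = 2/3`, aqueous-buffer
#' refractive index 1.336 and donor quantum yield 0.118 (tryptophan in
#' serum albumin).
#'
#' @param J Overlap integral in cm^3 L / mol (>= 0).
#' @param k2 Dipole orientation factor.
#' @param refractive_index Refractive index of the medium.
#' @param quantum_yield Donor fluorescence quantum yield.
#' @return Forster radius R0 in nm.
#' @export
forster_radius <- function(J, k2 = 2 / 3, refractive_index = 1.336,
                           quantum_yield = 0.118) {
  if (any(J < 0)) stop("J must be >= 0", call. = FALSE)
  r0_cm <- (8.8e-25 * k2 * refractive_index^-4 * quantum_yield * J)^(1 / 6)
  r0_cm * 1e7
}

#' Energy-transfer efficiency from quenched intensities
#'
#' `E = 1 - F/F0` with F the donor intensity in the presence of the
#' acceptor and F0 without it.
#'
#' @param F_quenched Donor intensity with acceptor present (0 < F <= F0).
#' @param F0 Donor intensity without acceptor.
#' @return Transfer efficiency in `[0, 1)`.
#' @export
transfer_efficiency <- function(F_quenched, F0) {
  if (any(F_quenched <= 0) || any(F0 <= 0))
    stop("intensities must be > 0", call. = FALSE)
  if (any(F_quenched > F0))
    stop("F must not exceed F0", call. = FALSE)
  1 - F_quenched / F0
}

#' Donor-acceptor distance from efficiency and Forster radius
#'
#' Inverts `E = R0^6 / (r^6 + R0^6)`: `r = R0 ((1 - E)/E)^(1/6)`.
#'
#' @param E Transfer efficiency, strictly inside (0, 1).
#' @param R0 Forster radius in nm (> 0).
#' @return Distance r in nm.
#' @export
donor_acceptor_distance <- function(E, R0) {
  if (any(E <= 0) || any(E >= 1))
    stop("E must be strictly between 0 and 1", call. = FALSE)
  if (any(R0 <= 0)) stop("R0 must be > 0", call. = FALSE)
  R0 * ((1 - E) / E)^(1 / 6)
}

#' Complete FRET analysis for one donor-acceptor pair
#'
#' Computes the overlap integral from donor emission and acceptor
#' absorbance (converted to molar absorptivity via the acceptor
#' concentration and path length), the Forster radius, the transfer
#' efficiency from the chosen titration intensities, and the donor-acceptor
#' distance, together with the standard validity flags: r inside the 2-8 nm
#' Forster window, r within `0.5 R0` to `1.5 R0`, and `r > R0` (consistent
#' with inefficient transfer / static quenching).
#'
#' @param donor_emission Donor [spectrum()].
#' @param acceptor_absorbance Acceptor absorbance [spectrum()] (unitless).
#' @param acceptor_conc Acceptor concentration in mol/L used to record the
#'   absorbance spectrum.
#' @param F_quenched,F0 Donor intensities with / without acceptor.
#' @param path_cm Absorbance path length in cm.
#' @inheritParams forster_radius
#' @return An object of class `fret_result` with `J`, `R0`, `E`, `r` and
#'   logical `flags`.
#' @export
fret_analysis <- function(donor_emission, acceptor_absorbance, acceptor_conc,
                          F_quenched, F0, path_cm = 1, k2 = 2 / 3,
                          refractive_index = 1.336, quantum_yield = 0.118) {
  if (acceptor_conc <= 0 || path_cm <= 0)
    stop("acceptor_conc and path_cm must be > 0", call. = FALSE)
  eps <- acceptor_absorbance
  eps$value <- eps$value / (acceptor_conc * path_cm)
  J <- overlap_integral(donor_emission, eps)
  R0 <- forster_radius(J, k2, refractive_index, quantum_yield)
  E <- transfer_efficiency(F_quenched, F0)
  r <- donor_acceptor_distance(E, R0)
  structure(list(
    J = J, R0 = R0, E = E, r = r,
    flags = c(in_2_8_nm_range = r >= 2 && r <= 8,
              within_half_to_1p5_R0 = r > 0.5 * R0 && r < 1.5 * R0,
              r_greater_than_R0 = r > R0)),
    class = "fret_result")
}

#' @export
print.fret_result <- function(x, ...) {
  cat(sprintf(
    "<FRET: J = %.3g cm^3 L/mol, R0 = %.2f nm, E = %.1f%%, r = %.2f nm>\n",
    x$J, x$R0, 100 * x$E, x$r))
  flags <- x$flags
  cat("  flags:", paste(names(flags), unname(flags), sep = " = ",
                        collapse = ", "), "\n")
  invisible(x)
}
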