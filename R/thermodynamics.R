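#' Van't Hoff regression of binding constants
#'
#' Ordinary least squares of `ln(Kb)` against `1/T`:
#' `ln Kb = -delta_H/(R T) + delta_S/R`, so the slope gives the binding
#' enthalpy (`delta_H = -slope * R`) and the intercept the entropy
#' (`delta_S = intercept * R`), with `R = 8.314` J/mol/K.
#'
#' @param temperature Temperatures in K (>= 2 distinct values).
#' @param kb Binding constants in L/mol (> 0), one per temperature.
#' @return A list with `delta_H` (J/mol), `delta_S` (J/mol/K) and
#'   `r_squared`.
#' @export
vant_hoff <- function(temperature, kb) {
  temperature <- as.numeric(temperature)
  kb <- as.numeric(kb)
  if (length(temperature) < 2L || length(kb) != length(temperature))
    stop("need >= 2 (temperature, kb) pairs", call. = FALSE)
  if (anyDuplicated(temperature))
    stop("temperatures must be distinct", call. = FALSE)
  if (any(kb <= 0)) stop("binding constants must be > 0", call. = FALSE)
  inv_t <- 1 / temperature
  fit <- stats::lm(log(kb) ~ inv_t)
  list(delta_H = -unname(stats::coef(fit)[2]) * GAS_CONSTANT,
       delta_S = unname(stats::coef(fit)[1]) * GAS_CONSTANT,
       r_squared = r_squared_of(fit, log(kb)))
}

#' Gibbs free energy of binding
#'
#' `delta_G = -R T ln(Kb)` in J/mol.
#'
#' @param kb Binding constant in L/mol (> 0); vectorised.
#' @param temperature Temperature in K.
#' @return Gibbs energy in J/mol.
#' @export
gibbs <- function(kb, temperature) {
  if (any(kb <= 0)) stop("kb must be > 0", call. = FALSE)
  -GAS_CONSTANT * temperature * log(kb)
}

#' Classify the dominant binding force from thermodynamic signs
#'
#' Ross-Subramanian sign rules: `delta_H > 0, delta_S > 0` indicates
#' hydrophobic interactions; `delta_H < 0, delta_S < 0` van der Waals
#' contacts and hydrogen bonds; `delta_H < 0, delta_S > 0` electrostatic
#' interactions. The remaining quadrant is not covered by the rules and is
#' labelled `"unclassified"`.
#'
#' @param delta_H Binding enthalpy, J/mol.
#' @param delta_S Binding entropy, J/mol/K.
#' @return One of `"hydrophobic"`, `"vdw_hbond"`, `"electrostatic"`,
#'   `"unclassified"`.
#' @export
classify_forces <- function(delta_H, delta_S) {
  stopifnot(is.finite(delta_H), is.finite(delta_S))
  if (delta_H > 0 && delta_S > 0) "hydrophobic"
  else if (delta_H < 0 && delta_S < 0) "vdw_hbond"
  else if (delta_H < 0 && delta_S > 0) "electrostatic"
  else "unclassified"
}

#' Full thermodynamic characterisation at a reference temperature
#'
#' Combines [vant_hoff()], [gibbs()] and [classify_forces()]. The Gibbs
#' energy is evaluated at `reference_T` from the measured Kb at that
#' temperature when present (matching how binding tables are usually
#' reported), falling back to the Van't Hoff model prediction otherwise.
#'
#' @inheritParams vant_hoff
#' @param reference_T Reference temperature in K for the reported
#'   `delta_G`.
#' @return An object of class `thermo_params` with `delta_H`, `delta_S`,
#'   `delta_G` (all J-based), `reference_T`, `r_squared` and `force_label`.
#' @export
thermo_params <- function(temperature, kb, reference_T = 297) {
  vh <- vant_hoff(temperature, kb)
  i <- match(reference_T, temperature)
  kb_ref <- if (!is.na(i)) kb[i] else
    exp(-vh$delta_H / (GAS_CONSTANT * reference_T) +
          vh$delta_S / GAS_CONSTANT)
  structure(list(delta_H = vh$delta_H, delta_S = vh$delta_S,
                 delta_G = gibbs(kb_ref, reference_T),
                 reference_T = reference_T, r_squared = vh$r_squared,
                 force_label = classify_forces(vh$delta_H, vh$delta_S)),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    paste0("<thermodynamics: dH = %.2f kJ/mol, dS = %.2f J/mol/K, ",
           "dG(%g K) = %.2f kJ/mol, %s>\n"),
    x$delta_H / 1000, x$delta_S, x$reference_T, x$delta_G / 1000,
    x$force_label))
  invisible(x)
}
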