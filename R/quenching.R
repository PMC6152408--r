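# universal gas constant, J/mol/K
GAS_CONSTANT <- 8.314

# diffusion-limited maximum collisional quenching constant, L/mol/s
KQ_DIFFUSION_LIMIT <- 2.0e10

# coefficient of determination; avoids summary.lm's near-perfect-fit warning
# on exact synthetic data. A constant response fitted by a constant is R2 = 1.
r_squared_of <- function(fit, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / tss
}

#' Inner-filter correction of a titration
#'
#' Corrects observed fluorescence for attenuation of the excitation and
#' emission beams by absorbing species:
#' `F_cor = F_obs * 10^((A_ex + A_em)/2)`, the standard half-path
#' correction. Absorbances must be recorded on the series and the series
#' must not already be corrected.
#'
#' @param series A [titration_series()] with `a_ex`/`a_em` present and
#'   `corrected = FALSE`.
#' @return The corrected [titration_series()] (`corrected = TRUE`).
#' @export
inner_filter_correct <- function(series) {
  validate_titration(series)
  if (series$corrected)
    stop("series is already inner-filter corrected", call. = FALSE)
  if (is.null(series$a_ex))
    stop("inner-filter correction needs a_ex and a_em absorbances",
         call. = FALSE)
  out <- series
  out$intensity <- series$intensity * 10^((series$a_ex + series$a_em) / 2)
  out$corrected <- TRUE
  out
}

# shared precondition for the quenching fits
check_fit_input <- function(series) {
  validate_titration(series)
  if (!series$corrected && !is.null(series$a_ex))
    stop("series carries absorbances but is not inner-filter corrected; ",
         "call inner_filter_correct() first", call. = FALSE)
  f0 <- series$intensity[1]
  if (f0 <= 0) stop("F0 must be > 0", call. = FALSE)
  f0
}

#' Stern-Volmer quenching fit
#'
#' Ordinary least squares of `F0/F` against quencher concentration over the
#' non-zero titration points, with `F0` the measured ligand-free intensity
#' and a free intercept. The slope is the Stern-Volmer constant Ksv; the
#' bimolecular quenching rate is `kq = Ksv / tau0` with the fluorophore
#' lifetime `tau0 = 1e-8` s by default.
#'
#' @param series A corrected [titration_series()] with at least 3 non-zero
#'   concentration points.
#' @param tau0 Unquenched fluorophore lifetime in s.
#' @return An object of class `stern_volmer_fit` with fields `ksv`
#'   (L/mol), `intercept`, `kq` (L/mol/s), `r_squared` and `temperature`.
#' @export
stern_volmer_fit <- function(series, tau0 = 1e-8) {
  f0 <- check_fit_input(series)
  nz <- series$ligand_conc > 0
  if (sum(nz) < 3L)
    stop("Stern-Volmer fit needs >= 3 non-zero concentration points",
         call. = FALSE)
  q <- series$ligand_conc[nz]
  y <- f0 / series$intensity[nz]
  fit <- stats::lm(y ~ q)
  structure(list(ksv = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 kq = unname(stats::coef(fit)[2]) / tau0,
                 r_squared = r_squared_of(fit, y),
                 temperature = series$temperature),
            class = "stern_volmer_fit")
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf(
    "<Stern-Volmer fit: Ksv = %.4g L/mol, kq = %.4g L/mol/s, R2 = %.4f, %s K>\n",
    x$ksv, x$kq, x$r_squared, format(x$temperature)))
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Ordinary least squares of `log10((F0 - F)/F)` against `log10([Q])` over
#' the non-zero titration points: the intercept is `log10(Kb)` (binding
#' constant) and the slope is the number of binding sites n. Points with
#' `F >= F0` carry no quenching information and are dropped with a warning.
#'
#' @inheritParams stern_volmer_fit
#' @return An object of class `binding_fit` with fields `log_kb`, `kb`
#'   (L/mol), `n`, `r_squared`, `temperature` and `n_points`.
#' @export
double_log_fit <- function(series) {
  f0 <- check_fit_input(series)
  nz <- series$ligand_conc > 0
  q <- series$ligand_conc[nz]
  f <- series$intensity[nz]
  usable <- f < f0
  if (any(!usable))
    warning(sum(!usable), " point(s) with F >= F0 dropped from the ",
            "double-log fit", call. = FALSE)
  if (sum(usable) < 3L)
    stop("double-log fit needs >= 3 usable points", call. = FALSE)
  x <- log10(q[usable])
  y <- log10((f0 - f[usable]) / f[usable])
  fit <- stats::lm(y ~ x)
  log_kb <- unname(stats::coef(fit)[1])
  structure(list(log_kb = log_kb, kb = 10^log_kb,
                 n = unname(stats::coef(fit)[2]),
                 r_squared = r_squared_of(fit, y),
                 temperature = series$temperature,
                 n_points = sum(usable)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "<binding fit: log Kb = %.3f (Kb = %.3g L/mol), n = %.3f, R2 = %.4f>\n",
    x$log_kb, x$kb, x$n, x$r_squared))
  invisible(x)
}

#' Classify the quenching mechanism from multi-temperature fits
#'
#' Two diagnostic rules distinguish static (ground-state complex) from
#' dynamic (collisional) quenching:
#' * rule A: Ksv strictly decreases with increasing temperature;
#' * rule B: every kq exceeds the diffusion-limited collisional maximum of
#'   2e10 L/mol/s.
#'
#' Both rules firing gives `"static"`; neither gives `"dynamic"`. A single
#' firing rule gives its verdict (`"static"`), unless the other rule
#' actively points the opposite way (Ksv strictly increasing while kq is
#' above the collisional limit), which is reported as `"ambiguous"` with
#' both reasons recorded.
#'
#' @param sv_fits List of [stern_volmer_fit()] objects at >= 2 distinct
#'   temperatures.
#' @param kq_max Collisional quenching ceiling in L/mol/s.
#' @return An object of class `mechanism_call`: `label` (`"static"`,
#'   `"dynamic"` or `"ambiguous"`) and `reasons` (character).
#' @export
classify_mechanism <- function(sv_fits, kq_max = KQ_DIFFUSION_LIMIT) {
  stopifnot(length(sv_fits) >= 2L,
            all(vapply(sv_fits, inherits, logical(1), "stern_volmer_fit")))
  temps <- vapply(sv_fits, `[[`, numeric(1), "temperature")
  if (anyDuplicated(temps))
    stop("duplicate temperatures in Stern-Volmer fits", call. = FALSE)
  o <- order(temps)
  ksv <- vapply(sv_fits, `[[`, numeric(1), "ksv")[o]
  kq <- vapply(sv_fits, `[[`, numeric(1), "kq")[o]

  decreasing <- all(diff(ksv) < 0)
  increasing <- all(diff(ksv) > 0)
  above_limit <- all(kq > kq_max)

  reasons <- character()
  if (decreasing)
    reasons <- c(reasons, "Ksv decreases with temperature (static signature)")
  if (increasing)
    reasons <- c(reasons,
                 "Ksv increases with temperature (dynamic signature)")
  if (above_limit)
    reasons <- c(reasons, sprintf(
      "all kq > %.1e L/mol/s diffusion limit (static signature)", kq_max))
  else
    reasons <- c(reasons, sprintf(
      "kq within diffusion-limited range (<= %.1e L/mol/s)", kq_max))

  label <- if (decreasing && above_limit) {
    "static"
  } else if (!decreasing && !above_limit) {
    "dynamic"
  } else if (increasing && above_limit) {
    "ambiguous"
  } else {
    "static"  # exactly one positive rule, no conflicting signature
  }
  structure(list(label = label, reasons = reasons), class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat("<quenching mechanism:", x$label, ">\n")
  cat(paste0("  - ", x$reasons, collapse = "\n"), "\n")
  invisible(x)
}

# vertex of the parabola through the 3 points around the discrete maximum
refine_peak <- function(w, v) {
  i <- which.max(v)
  if (i == 1L || i == length(v)) return(w[i])
  y1 <- v[i - 1]; y2 <- v[i]; y3 <- v[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(w[i])
  # assumes locally uniform spacing around the maximum
  w[i] + 0.5 * (y1 - y3) / denom * (w[i + 1] - w[i])
}

#' Synchronous-fluorescence peak-shift analysis
#'
#' Locates the emission maximum of each synchronous spectrum in a
#' ligand-concentration-ordered series (3-point parabolic refinement around
#' the discrete maximum) and reports the net shift from first to last
#' spectrum. Offsets of 15 nm probe tyrosine and 60 nm tryptophan
#' microenvironments; a shift beyond `tol` signals a polarity change around
#' the residues.
#'
#' @param spectra List of synchronous [spectrum()] objects sharing one
#'   `delta_lambda`, ordered by ligand concentration.
#' @param tol Shift tolerance in nm below which the peak is called
#'   unchanged (default 1 nm, about one instrument step).
#' @return A list with `peaks` (nm per spectrum), `net_shift` (nm),
#'   `label` (`"red"`, `"blue"` or `"unchanged"`) and `delta_lambda`.
#' @export
synchronous_shift <- function(spectra, tol = 1) {
  stopifnot(length(spectra) >= 2L)
  lapply(spectra, validate_spectrum)
  if (!all(vapply(spectra, function(s) s$kind == "synchronous", logical(1))))
    stop("all spectra must be synchronous", call. = FALSE)
  dl <- unique(vapply(spectra, function(s) s$meta$delta_lambda, numeric(1)))
  if (length(dl) != 1L)
    stop("mixed delta_lambda across the series", call. = FALSE)
  peaks <- vapply(spectra, function(s) refine_peak(s$wavelength, s$value),
                  numeric(1))
  net <- peaks[length(peaks)] - peaks[1]
  label <- if (net > tol) "red" else if (net < -tol) "blue" else "unchanged"
  list(peaks = peaks, net_shift = net, label = label, delta_lambda = dl)
}

#' Site-marker competitive displacement verdict
#'
#' Compares the ligand's binding constant measured alone with the constants
#' measured in the presence of a site I marker (warfarin) and a site II
#' marker (ibuprofen). A marker "competes" when it lowers log10(Kb) by more
#' than `threshold`; if both compete, the primary site is the one whose
#' marker depresses the constant further.
#'
#' @param base [double_log_fit()] result for ligand + protein alone.
#' @param with_site1_marker,with_site2_marker Fits in the presence of the
#'   site I / site II marker.
#' @param threshold Minimum drop in log10(Kb) counted as competition.
#' @return A list with `site` (`"site I"`, `"site II"` or
#'   `"neither marker site"`), `competes` (named logical) and `drop`
#'   (named numeric, log10 units).
#' @export
competitive_site_assignment <- function(base, with_site1_marker,
                                        with_site2_marker,
                                        threshold = 0.05) {
  fits <- list(base, with_site1_marker, with_site2_marker)
  stopifnot(all(vapply(fits, inherits, logical(1), "binding_fit")))
  drop <- c(site1 = base$log_kb - with_site1_marker$log_kb,
            site2 = base$log_kb - with_site2_marker$log_kb)
  competes <- drop > threshold
  site <- if (all(competes)) {
    if (drop[["site1"]] >= drop[["site2"]]) "site I" else "site II"
  } else if (competes[["site1"]]) {
    "site I"
  } else if (competes[["site2"]]) {
    "site II"
  } else {
    "neither marker site"
  }
  list(site = site, competes = competes, drop = drop)
}
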