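#' Read a study configuration from YAML
#'
#' A study configuration lists the input files and constants for
#' [run_study()]: `titrations` (named `temperature = path` map),
#' optional `donor`/`acceptor` spectra with `acceptor_conc`, an optional
#' `cd_free`/`cd_complex` pair, optional `markers` (`base`, `site1`,
#' `site2` titration paths) and a `constants` block (`tau0`, `k2`,
#' `refractive_index`, `quantum_yield`, `n_residues`, `path_cm`,
#' `reference_T`, `protein_conc`).
#'
#' @param path Path to a YAML file.
#' @return A named list usable as [run_study()] input.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

default_constants <- function() {
  list(tau0 = 1e-8, k2 = 2 / 3, refractive_index = 1.336,
       quantum_yield = 0.118, n_residues = 583, path_cm = 0.1,
       reference_T = 297, protein_conc = 5e-6)
}

run_stage <- function(expr) {
  tryCatch(c(list(status = "ok"), expr),
           error = function(e) list(status = "failed",
                                    error = conditionMessage(e)))
}

#' Run a complete binding study
#'
#' Orchestrates every analysis stage from a configuration: per-temperature
#' inner-filter correction and Stern-Volmer / double-log fits, quenching
#' mechanism classification, Van't Hoff thermodynamics with force typing,
#' FRET distance estimation, CD helicity change, and site-marker
#' competition. Stages whose inputs are absent are reported as `"skipped"`;
#' a stage failure is recorded without stopping the others. The result is
#' deterministic given the input files.
#'
#' @param config A named list (see [read_study_config()]) or a path to a
#'   YAML file.
#' @return An object of class `study_report`: one entry per stage, each
#'   with a `status` of `"ok"`, `"failed"` or `"skipped"`, plus the
#'   constants used.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  const <- utils::modifyList(default_constants(),
                             config$constants %||% list())
  report <- list(constants = const, inputs = config)

  # quenching fits per temperature
  report$quenching <- run_stage({
    if (is.null(config$titrations)) stop("no titration files configured")
    series <- lapply(config$titrations, function(p) {
      s <- read_titration(p, protein_conc = const$protein_conc)
      if (!is.null(s$a_ex)) inner_filter_correct(s) else {
        s$corrected <- TRUE  # no recorded absorbance: nothing to correct
        s
      }
    })
    sv <- lapply(series, stern_volmer_fit, tau0 = const$tau0)
    dl <- lapply(series, double_log_fit)
    list(stern_volmer = sv, binding = dl)
  })

  report$mechanism <- if (report$quenching$status != "ok") {
    list(status = "skipped", reason = "quenching stage unavailable")
  } else run_stage({
    list(call = classify_mechanism(report$quenching$stern_volmer,
                                   kq_max = KQ_DIFFUSION_LIMIT))
  })

  report$thermodynamics <- if (report$quenching$status != "ok" ||
                               length(report$quenching$binding) < 2L) {
    list(status = "skipped", reason = "need binding fits at >= 2 temperatures")
  } else run_stage({
    b <- report$quenching$binding
    temps <- vapply(b, `[[`, numeric(1), "temperature")
    kb <- vapply(b, `[[`, numeric(1), "kb")
    list(params = thermo_params(temps, kb, reference_T = const$reference_T))
  })

  report$fret <- if (is.null(config$donor) || is.null(config$acceptor)) {
    list(status = "skipped", reason = "no donor/acceptor spectra configured")
  } else run_stage({
    donor <- read_spectrum(config$donor, kind = "emission")
    acceptor <- read_spectrum(config$acceptor, kind = "absorbance")
    # F/F0 from the highest-concentration point of the reference titration
    if (report$quenching$status != "ok")
      stop("FRET efficiency needs the corrected titrations")
    ref <- report$quenching$stern_volmer
    temps <- vapply(ref, `[[`, numeric(1), "temperature")
    i <- which.min(abs(temps - const$reference_T))
    s <- read_titration(config$titrations[[i]],
                        protein_conc = const$protein_conc)
    if (!is.null(s$a_ex)) s <- inner_filter_correct(s)
    conc <- config$acceptor_conc %||%
      s$ligand_conc[length(s$ligand_conc)]
    list(result = fret_analysis(
      donor, acceptor, acceptor_conc = conc,
      F_quenched = s$intensity[length(s$intensity)], F0 = s$intensity[1],
      k2 = const$k2, refractive_index = const$refractive_index,
      quantum_yield = const$quantum_yield))
  })

  report$cd <- if (is.null(config$cd_free) || is.null(config$cd_complex)) {
    list(status = "skipped", reason = "no CD spectra configured")
  } else run_stage({
    free <- read_spectrum(config$cd_free, kind = "cd")
    cplx <- read_spectrum(config$cd_complex, kind = "cd")
    helix_change(free, cplx, n_residues = const$n_residues,
                 path_cm = const$path_cm,
                 protein_conc = const$protein_conc)
  })

  report$competition <- if (is.null(config$markers)) {
    list(status = "skipped", reason = "no site-marker titrations configured")
  } else run_stage({
    fit_one <- function(p) {
      s <- read_titration(p, protein_conc = const$protein_conc)
      if (!is.null(s$a_ex)) s <- inner_filter_correct(s) else
        s$corrected <- TRUE
      double_log_fit(s)
    }
    m <- config$markers
    list(verdict = competitive_site_assignment(
      fit_one(m$base), fit_one(m$site1), fit_one(m$site2)))
  })

  structure(report, class = "study_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.study_report <- function(x, ...) {
  cat("<study report>\n")
  for (stage in c("quenching", "mechanism", "thermodynamics", "fret", "cd",
                  "competition"))
    cat(sprintf("  %-15s %s\n", stage, x[[stage]]$status))
  invisible(x)
}

#' Extract the binding table from a study report
#'
#' One row per temperature mirroring the conventional layout of binding
#' summaries: Ksv, its R^2, kq, log Kb, Kb, n, its R^2, and the
#' thermodynamic summary on the reference-temperature row.
#'
#' @param report A [run_study()] result.
#' @return A data frame.
#' @export
study_binding_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  if (report$quenching$status != "ok")
    stop("quenching stage did not run", call. = FALSE)
  sv <- report$quenching$stern_volmer
  dl <- report$quenching$binding
  d <- data.frame(
    temperature_K = vapply(sv, `[[`, numeric(1), "temperature"),
    ksv = vapply(sv, `[[`, numeric(1), "ksv"),
    r2_sv = vapply(sv, `[[`, numeric(1), "r_squared"),
    kq = vapply(sv, `[[`, numeric(1), "kq"),
    log_kb = vapply(dl, `[[`, numeric(1), "log_kb"),
    kb = vapply(dl, `[[`, numeric(1), "kb"),
    n = vapply(dl, `[[`, numeric(1), "n"),
    r2_dl = vapply(dl, `[[`, numeric(1), "r_squared"),
    delta_G_kJ = NA_real_, delta_H_kJ = NA_real_, delta_S_J = NA_real_)
  th <- report$thermodynamics
  if (identical(th$status, "ok")) {
    i <- which(d$temperature_K == th$params$reference_T)
    if (!length(i)) i <- which.min(abs(d$temperature_K -
                                         th$params$reference_T))
    d$delta_G_kJ[i] <- th$params$delta_G / 1000
    d$delta_H_kJ[i] <- th$params$delta_H / 1000
    d$delta_S_J[i] <- th$params$delta_S
  }
  d
}

#' Serialise a study report
#'
#' Writes `report.json` (full nested report) and `binding_table.csv` (the
#' [study_binding_table()] mirror) into `dir`.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass_deep(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  csv_path <- file.path(dir, "binding_table.csv")
  if (identical(report$quenching$status, "ok"))
    utils::write.csv(study_binding_table(report), csv_path,
                     row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
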