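#' Fluorescence titration series
#'
#' Observed fluorescence at a fixed emission wavelength across increasing
#' ligand (quencher) concentration at one temperature. The first point must
#' be the ligand-free reference (concentration 0), which supplies F0 for the
#' quenching fits. Optional per-point absorbances at the excitation and
#' emission wavelengths enable inner-filter correction.
#'
#' @param ligand_conc Ligand concentrations in mol/L, strictly increasing,
#'   first entry 0.
#' @param intensity Fluorescence intensities (a.u.), all > 0.
#' @param temperature Temperature in K.
#' @param protein_conc Protein concentration in mol/L.
#' @param a_ex,a_em Optional absorbances at the excitation / emission
#'   wavelength, one per titration point; supply both or neither.
#' @param corrected Logical: are the intensities already inner-filter
#'   corrected (or free of inner-filter attenuation)?
#'
#' @return An object of class `titration_series`.
#' @seealso [inner_filter_correct()], [stern_volmer_fit()], [double_log_fit()]
#' @export
titration_series <- function(ligand_conc, intensity, temperature,
                             protein_conc = 5e-6, a_ex = NULL, a_em = NULL,
                             corrected = FALSE) {
  obj <- structure(
    list(ligand_conc = as.numeric(ligand_conc),
         intensity = as.numeric(intensity),
         temperature = temperature, protein_conc = protein_conc,
         a_ex = if (!is.null(a_ex)) as.numeric(a_ex),
         a_em = if (!is.null(a_em)) as.numeric(a_em),
         corrected = isTRUE(corrected)),
    class = "titration_series")
  validate_titration(obj)
  obj
}

validate_titration <- function(x) {
  stopifnot(inherits(x, "titration_series"))
  q <- x$ligand_conc
  if (length(q) != length(x$intensity))
    stop("ligand_conc and intensity lengths differ", call. = FALSE)
  if (length(q) < 2L)
    stop("titration needs at least 2 points", call. = FALSE)
  if (q[1] != 0)
    stop("first titration point must be the ligand-free reference ([Q] = 0)",
         call. = FALSE)
  if (any(diff(q) <= 0))
    stop("ligand concentrations must be strictly increasing", call. = FALSE)
  if (any(x$intensity <= 0))
    stop("intensities must be > 0", call. = FALSE)
  if (xor(is.null(x$a_ex), is.null(x$a_em)))
    stop("supply both a_ex and a_em or neither", call. = FALSE)
  if (!is.null(x$a_ex)) {
    if (length(x$a_ex) != length(q) || length(x$a_em) != length(q))
      stop("a_ex/a_em must match the number of titration points",
           call. = FALSE)
    if (any(x$a_ex < 0) || any(x$a_em < 0))
      stop("absorbances must be >= 0", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration: %d points, [Q] 0-%g M, %s K, %scorrected>\n",
    length(x$ligand_conc), max(x$ligand_conc),
    format(x$temperature), if (x$corrected) "" else "un"))
  invisible(x)
}

#' Read a titration table from delimited text
#'
#' Columns `ligand_conc_M,intensity` with optional `a_ex,a_em`; `# key:
#' value` metadata lines carry `temperature_K` and `protein_conc_M`. The
#' table must contain the zero-concentration reference row and strictly
#' increasing concentrations.
#'
#' @param source Path to a file, or a character vector of lines.
#' @param temperature,protein_conc Used when the file carries no metadata.
#' @return A [titration_series()] with `corrected = FALSE`.
#' @export
read_titration <- function(source, temperature = NA_real_,
                           protein_conc = 5e-6) {
  tab <- read_numeric_table(source, 2L, 4L, "titration")
  d <- tab$data
  m <- tab$meta
  has_abs <- ncol(d) == 4L
  if (ncol(d) == 3L)
    stop("titration has a_ex but not a_em: supply both or neither",
         call. = FALSE)
  titration_series(
    ligand_conc = d[, 1], intensity = d[, 2],
    temperature = if (!is.null(m$temperature_K)) m$temperature_K else
      temperature,
    protein_conc = if (!is.null(m$protein_conc_M)) m$protein_conc_M else
      protein_conc,
    a_ex = if (has_abs) d[, 3], a_em = if (has_abs) d[, 4],
    corrected = FALSE)
}

#' Write a titration table as delimited text
#'
#' @param x A [titration_series()].
#' @param path Destination file path.
#' @return `x`, invisibly.
#' @export
write_titration <- function(x, path) {
  validate_titration(x)
  hdr <- c(sprintf("# temperature_K: %s", format_full(x$temperature)),
           sprintf("# protein_conc_M: %s", format_full(x$protein_conc)))
  if (is.null(x$a_ex)) {
    lines <- c(hdr, "ligand_conc_M,intensity",
               paste(format_full(x$ligand_conc), format_full(x$intensity),
                     sep = ","))
  } else {
    lines <- c(hdr, "ligand_conc_M,intensity,a_ex,a_em",
               paste(format_full(x$ligand_conc), format_full(x$intensity),
                     format_full(x$a_ex), format_full(x$a_em), sep = ","))
  }
  writeLines(lines, path)
  invisible(x)
}
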