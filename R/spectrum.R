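#' Spectrum container
#'
#' A `quench_spectrum` holds a signal sampled on an ascending wavelength grid
#' together with acquisition metadata. Four kinds are supported: `emission`
#' (fluorescence, arbitrary units), `absorbance` (unitless, must be
#' non-negative), `synchronous` (fixed excitation-emission offset scans,
#' which require `delta_lambda`), and `cd` (circular dichroism, millidegrees).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing,
#'   length >= 2.
#' @param value Numeric signal, one value per wavelength.
#' @param kind One of `"emission"`, `"absorbance"`, `"synchronous"`, `"cd"`.
#' @param temperature Optional temperature in K.
#' @param delta_lambda Offset between excitation and emission in nm; required
#'   for (and only allowed with) `kind = "synchronous"`.
#' @param ligand_conc,protein_conc Optional concentrations in mol/L.
#'
#' @return An object of class `quench_spectrum`.
#' @examples
#' s <- spectrum(c(300, 340, 400), c(0, 1, 0.1), kind = "emission")
#' s
#' @export
spectrum <- function(wavelength, value,
                     kind = c("emission", "absorbance", "synchronous", "cd"),
                     temperature = NULL, delta_lambda = NULL,
                     ligand_conc = NULL, protein_conc = NULL) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  obj <- structure(
    list(kind = kind, wavelength = wavelength, value = value,
         meta = list(temperature = temperature, delta_lambda = delta_lambda,
                     ligand_conc = ligand_conc, protein_conc = protein_conc)),
    class = "quench_spectrum")
  validate_spectrum(obj)
  obj
}

validate_spectrum <- function(x) {
  stopifnot(inherits(x, "quench_spectrum"))
  w <- x$wavelength
  v <- x$value
  if (length(w) < 2L)
    stop("spectrum needs at least 2 points", call. = FALSE)
  if (length(w) != length(v))
    stop("wavelength and value lengths differ", call. = FALSE)
  if (anyNA(w) || anyNA(v))
    stop("spectrum contains missing values", call. = FALSE)
  if (any(diff(w) <= 0))
    stop("wavelengths must be strictly increasing (duplicates not allowed)",
         call. = FALSE)
  if (x$kind == "absorbance" && any(v < 0))
    stop("absorbance values must be >= 0", call. = FALSE)
  if (x$kind == "synchronous" && is.null(x$meta$delta_lambda))
    stop("synchronous spectra require delta_lambda", call. = FALSE)
  if (x$kind != "synchronous" && !is.null(x$meta$delta_lambda))
    stop("delta_lambda is only meaningful for synchronous spectra",
         call. = FALSE)
  invisible(x)
}

#' @export
print.quench_spectrum <- function(x, ...) {
  rng <- range(x$wavelength)
  cat(sprintf("<%s spectrum: %d points, %g-%g nm>\n",
              x$kind, length(x$wavelength), rng[1], rng[2]))
  m <- x$meta[!vapply(x$meta, is.null, logical(1))]
  if (length(m))
    cat("  ", paste(names(m), unlist(m), sep = " = ", collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

# split a delimited line, auto-detecting comma vs tab
split_fields <- function(line) {
  delim <- if (grepl(",", line, fixed = TRUE)) "," else "\t"
  trimws(strsplit(line, delim, fixed = TRUE)[[1]])
}

# parse "# key: value" metadata headers emitted by the writers
parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    kv <- strsplit(body, ":", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      key <- trimws(kv[1])
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      meta[[key]] <- if (is.na(val)) trimws(kv[2]) else val
    }
  }
  meta
}

read_numeric_table <- function(source, n_cols_min, n_cols_max, what) {
  lines <- if (length(source) > 1 || grepl("\n", source[1], fixed = TRUE)) {
    unlist(strsplit(source, "\n", fixed = TRUE))
  } else {
    readLines(source, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  is_meta <- startsWith(trimws(lines), "#")
  meta <- parse_meta_lines(lines[is_meta])
  data_lines <- lines[!is_meta]
  line_no <- seq_along(lines)[!is_meta]
  if (!length(data_lines)) stop("no data rows in ", what, call. = FALSE)

  first <- split_fields(data_lines[1])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  if (has_header) {
    header <- first
    data_lines <- data_lines[-1]
    line_no <- line_no[-1]
  } else {
    header <- NULL
  }
  if (!length(data_lines)) stop("no data rows in ", what, call. = FALSE)

  rows <- lapply(seq_along(data_lines), function(i) {
    fields <- split_fields(data_lines[i])
    if (length(fields) < n_cols_min || length(fields) > n_cols_max)
      stop(sprintf("line %d: expected %d-%d columns, found %d",
                   line_no[i], n_cols_min, n_cols_max, length(fields)),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals))
      stop(sprintf("line %d: non-numeric field '%s'",
                   line_no[i], fields[which(is.na(vals))[1]]), call. = FALSE)
    vals
  })
  n_cols <- unique(lengths(rows))
  if (length(n_cols) != 1)
    stop("rows have inconsistent column counts", call. = FALSE)
  list(data = do.call(rbind, rows), meta = meta, header = header)
}

#' Read a spectrum from delimited text
#'
#' Two-column text (wavelength in nm, signal), comma- or tab-delimited, with
#' an optional single header line and optional `# key: value` metadata lines
#' (as written by [write_spectrum()]). Rows are sorted by wavelength.
#'
#' @param source Path to a file, or a character vector of lines.
#' @inheritParams spectrum
#' @return A [spectrum()] object.
#' @export
read_spectrum <- function(source,
                          kind = c("emission", "absorbance", "synchronous",
                                   "cd")) {
  kind <- match.arg(kind)
  tab <- read_numeric_table(source, 2L, 2L, "spectrum")
  w <- tab$data[, 1]
  v <- tab$data[, 2]
  if (anyDuplicated(w))
    stop("duplicate wavelengths in spectrum", call. = FALSE)
  o <- order(w)
  m <- tab$meta
  spectrum(w[o], v[o], kind = if (!is.null(m$kind)) m$kind else kind,
           temperature = m$temperature_K,
           delta_lambda = m$delta_lambda_nm,
           ligand_conc = m$ligand_conc_M,
           protein_conc = m$protein_conc_M)
}

#' Write a spectrum as delimited text
#'
#' Emits `# key: value` metadata headers followed by a `wavelength_nm,value`
#' CSV table at full double precision, so that a read/write round trip is
#' exact.
#'
#' @param x A [spectrum()] object.
#' @param path Destination file path.
#' @return `x`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  validate_spectrum(x)
  meta <- c(kind = x$kind,
            temperature_K = x$meta$temperature,
            delta_lambda_nm = x$meta$delta_lambda,
            ligand_conc_M = x$meta$ligand_conc,
            protein_conc_M = x$meta$protein_conc)
  hdr <- sprintf("# %s: %s", names(meta),
                 vapply(meta, format_full, character(1)))
  lines <- c(hdr, "wavelength_nm,value",
             paste(format_full(x$wavelength), format_full(x$value), sep = ","))
  writeLines(lines, path)
  invisible(x)
}

format_full <- function(x) {
  if (is.character(x)) return(x)
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation; the new grid must lie within the spectrum's range
#' (no extrapolation). Kind and metadata are preserved.
#'
#' @param x A [spectrum()] object.
#' @param new_grid Ascending wavelengths in nm.
#' @return A [spectrum()] on `new_grid`.
#' @export
resample <- function(x, new_grid) {
  validate_spectrum(x)
  new_grid <- as.numeric(new_grid)
  if (any(new_grid < x$wavelength[1]) ||
      any(new_grid > x$wavelength[length(x$wavelength)]))
    stop("resample grid extends beyond the spectrum range (",
         x$wavelength[1], "-", x$wavelength[length(x$wavelength)], " nm)",
         call. = FALSE)
  v <- stats::approx(x$wavelength, x$value, xout = new_grid)$y
  out <- x
  out$wavelength <- new_grid
  out$value <- v
  validate_spectrum(out)
  out
}
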