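#' Multidrug-resistance reversal fold
#'
#' `RF = IC50(cytotoxic drug alone) / IC50(drug + modulator)`: the
#' fold-sensitisation of a resistant cell line by a candidate reversal
#' agent. Vectorised over the combination IC50s.
#'
#' @param ic50_alone IC50 of the cytotoxic drug alone, in uM (> 0).
#' @param ic50_combo IC50 in the presence of the modulator, same units.
#' @return Reversal fold (unitless).
#' @export
reversal_fold <- function(ic50_alone, ic50_combo) {
  if (any(ic50_alone <= 0) || any(ic50_combo <= 0))
    stop("IC50 values must be > 0", call. = FALSE)
  ic50_alone / ic50_combo
}

#' Reversal folds for a table of IC50 summaries
#'
#' @param table Data frame with columns `label`, `ic50_alone_uM` and
#'   `ic50_combo_uM`.
#' @return The input with an `rf` column appended (rounded to 2 decimals in
#'   the printed representation only; the column itself is exact).
#' @export
reversal_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("label", "ic50_alone_uM", "ic50_combo_uM") %in%
                  names(table)))
  table$rf <- reversal_fold(table$ic50_alone_uM, table$ic50_combo_uM)
  table
}
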