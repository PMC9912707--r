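#' Published reference confusion counts
#'
#' Turn-level TP/FP/TN/FN counts published for a 1320-term PRO-CTCAE
#' symptom keyword library evaluated on transcribed outpatient oncology
#' conversations: a validation sample (21,225 turns; preliminary testing
#' of the 1171-term draft library) and a test sample (14,674 turns; final
#' library), each against both the broad and the PRO-CTCAE-focused gold
#' standard. Useful as input to [performance_metrics()] to reproduce the
#' published metric table, and as a realistic scale reference.
#'
#' @return tibble with columns `sample` (`validation`/`test`), `standard`
#'   (`broad`/`proctcae`), `tp`, `fp`, `tn`, `fn`.
#' @examples
#' rc <- reference_confusion_counts()
#' performance_metrics(confusion_counts(rc$tp[4], rc$fp[4],
#'                                      rc$tn[4], rc$fn[4]))
#' @export
reference_confusion_counts <- function() {
  path <- system.file("extdata", "reference_confusion_counts.csv",
                      package = "symtalk", mustWork = TRUE)
  readr::read_csv(path, comment = "#",
                  col_types = readr::cols(
                    sample = "c", standard = "c", tp = "i", fp = "i",
                    tn = "i", fn = "i"),
                  progress = FALSE)
}
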