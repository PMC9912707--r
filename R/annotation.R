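#' Read turn-level coder scores
#'
#' Annotation files are delimiter-separated with columns
#' `conversation_id`, `turn_index`, `coder_id`, `score` (integer 0-3,
#' where 3 means certain relevance to symptoms). `#`-comment lines are
#' ignored.
#'
#' @param path annotation file (`.csv` or `.tsv`).
#' @return tibble of coder scores.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_io("Annotation file not found: %s", path)
  tab <- readr::read_delim(path, delim = guess_delim(path), comment = "#",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("conversation_id", "turn_index", "coder_id", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_validation("Annotation file %s lacks column(s): %s.",
                    path, toString(miss))
  }
  validate_scores(tibble::tibble(
    conversation_id = tab$conversation_id,
    turn_index = as.integer(tab$turn_index),
    coder_id = tab$coder_id,
    score = as.integer(tab$score)))
}

validate_scores <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (nrow(scores) == 0) stop_validation("No coder scores provided.")
  if (anyNA(scores$score) || !all(scores$score %in% 0:3)) {
    stop_validation("Scores must be integers in 0..3.")
  }
  key <- paste(turn_key(scores$conversation_id, scores$turn_index),
               scores$coder_id)
  if (anyDuplicated(key)) {
    stop_validation("Multiple scores for the same (turn, coder): %s.",
                    toString(head(unique(key[duplicated(key)]), 3)))
  }
  scores
}

#' Build the broad gold standard
#'
#' Each turn's coder scores (0-3 relevance to symptom talk) are averaged
#' over the coders who scored it; a mean of 2 or higher marks the turn as
#' containing symptom content. The bound is closed: a mean of exactly 2.0
#' is positive. The PRO-CTCAE-focused label starts equal to the broad label
#' and is refined with [apply_proctcae_overrides()].
#'
#' @param scores tibble of coder scores (`conversation_id`, `turn_index`,
#'   `coder_id`, `score`); single-coded turns are allowed.
#' @param turns optional tibble of (`conversation_id`, `turn_index`) that
#'   must all be scored; unscored turns in it raise an error listing them.
#' @return gold-label tibble: `conversation_id`, `turn_index`,
#'   `mean_score`, `broad_positive`, `proctcae_positive` (initially equal
#'   to `broad_positive`), `override_source` (`"none"`).
#' @export
build_broad_gold <- function(scores, turns = NULL) {
  scores <- validate_scores(scores)
  gold <- scores |>
    dplyr::group_by(.data$conversation_id, .data$turn_index) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop") |>
    dplyr::mutate(broad_positive = .data$mean_score >= 2,
                  proctcae_positive = .data$mean_score >= 2,
                  override_source = "none") |>
    dplyr::arrange(.data$conversation_id, .data$turn_index)
  if (!is.null(turns)) {
    missing <- setdiff(turn_key(turns$conversation_id, turns$turn_index),
                       turn_key(gold$conversation_id, gold$turn_index))
    if (length(missing)) {
      stop_validation("Turn(s) with zero coder scores: %s.",
                      toString(head(gsub("\r", ":", missing), 10)))
    }
  }
  gold
}

#' Apply manual PRO-CTCAE overrides to gold labels
#'
#' The broad gold standard targets all symptom talk; the library targets
#' PRO-CTCAE-framework symptoms specifically. A second, focused gold
#' standard is produced by manually overriding individual turns — e.g.
#' downgrading symptom talk outside the framework, or upgrading turns where
#' annotators missed symptom-relevant medications. Overrides are kept as an
#' explicit sidecar table so the focused standard stays reproducible and
#' auditable. Applying the same overrides twice is a no-op.
#'
#' @param gold output of [build_broad_gold()].
#' @param overrides tibble with columns `conversation_id`, `turn_index`,
#'   `proctcae_positive` (logical) and optional `note`. Every key must
#'   exist in `gold`.
#' @return `gold` with `proctcae_positive` replaced on overridden turns and
#'   `override_source` set to `"manual"` there.
#' @export
apply_proctcae_overrides <- function(gold, overrides) {
  if (is.null(overrides) || nrow(overrides) == 0) return(gold)
  overrides <- tibble::as_tibble(overrides)
  idx <- match(turn_key(overrides$conversation_id, overrides$turn_index),
               turn_key(gold$conversation_id, gold$turn_index))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop_validation("Override(s) for unknown turn(s): %s.",
                    toString(head(paste0(overrides$conversation_id[bad], ":",
                                         overrides$turn_index[bad]), 10)))
  }
  gold$proctcae_positive[idx] <- as.logical(overrides$proctcae_positive)
  gold$override_source[idx] <- "manual"
  gold
}

#' Read a PRO-CTCAE override sidecar file
#'
#' Columns: `conversation_id`, `turn_index`, `proctcae_positive`,
#' optional `note`.
#'
#' @param path sidecar file (`.csv`/`.tsv`).
#' @return override tibble for [apply_proctcae_overrides()].
#' @export
read_overrides <- function(path) {
  if (!file.exists(path)) stop_io("Override file not found: %s", path)
  tab <- readr::read_delim(path, delim = guess_delim(path), comment = "#",
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("conversation_id", "turn_index", "proctcae_positive")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_validation("Override file %s lacks column(s): %s.", path,
                    toString(miss))
  }
  tibble::tibble(
    conversation_id = tab$conversation_id,
    turn_index = as.integer(tab$turn_index),
    proctcae_positive = tolower(tab$proctcae_positive) %in%
      c("true", "t", "1", "yes"),
    note = (tab[["note"]] %||% rep("", nrow(tab))) %|na|% "")
}
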