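#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)}, where
#' \eqn{p_o} is observed agreement and \eqn{p_e} the agreement expected
#' from the raters' marginal label frequencies. When both raters use a
#' single identical label throughout, \eqn{p_e = 1} and kappa is undefined;
#' `NaN` is returned with a warning.
#'
#' @param a,b equal-length label vectors (any atomic type) from two raters
#'   on the same items.
#' @return kappa in `[-1, 1]`, or `NaN` when undefined.
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0)) # 0.5
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0) {
    stop_validation("`a` and `b` must be non-empty and the same length.")
  }
  a <- as.character(a)
  b <- as.character(b)
  levels <- union(a, b)
  po <- mean(a == b)
  pe <- sum(vapply(levels, function(l) mean(a == l) * mean(b == l), 0))
  if (isTRUE(all.equal(pe, 1))) {
    warn("Both raters constant and identical: chance agreement is 1, kappa undefined.")
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for multiple raters
#'
#' Standard Fleiss computation on an items-by-categories count matrix with
#' a constant number of ratings per item.
#'
#' @param counts integer matrix: `counts[i, j]` is the number of raters
#'   assigning item `i` to category `j`; all row sums must be equal and
#'   >= 2.
#' @return kappa in `[-1, 1]`, or `NaN` when chance agreement is 1.
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  n <- unique(rowSums(counts))
  if (length(n) != 1 || n < 2) {
    stop_validation("All items need the same number of ratings (>= 2).")
  }
  N <- nrow(counts)
  p_j <- colSums(counts) / (N * n)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  P_bar <- mean(P_i)
  P_e <- sum(p_j^2)
  if (isTRUE(all.equal(P_e, 1))) {
    warn("All ratings in one category: chance agreement is 1, kappa undefined.")
    return(NaN)
  }
  (P_bar - P_e) / (1 - P_e)
}

#' Inter-rater reliability on coder scores
#'
#' Computes chance-corrected agreement among coders after binarizing the
#' 0-3 relevance scores at a threshold (default 2, matching the broad
#' gold standard's positivity rule). Two statistics are available:
#' `"fleiss"` (the default) requires the included turns to be fully
#' crossed — scored by every included coder — and turns that are not are
#' dropped; `"cohen-pairwise-mean"` computes Cohen's kappa for every coder
#' pair on the turns they both scored and averages the defined values.
#'
#' @param scores coder-score tibble (see [read_annotations()]).
#' @param binarize_at scores `>= binarize_at` count as positive.
#' @param kind `"fleiss"` or `"cohen-pairwise-mean"`.
#' @return list of class `reliability_report`: `n_conversations`,
#'   `n_turns` (turns entering the statistic), `n_coders`,
#'   `kappa_statistic`, `kappa_kind`.
#' @export
interrater_kappa <- function(scores, binarize_at = 2,
                             kind = c("fleiss", "cohen-pairwise-mean")) {
  kind <- match.arg(kind)
  scores <- validate_scores(scores)
  coders <- sort(unique(scores$coder_id))
  if (length(coders) < 2) {
    stop_validation("Reliability needs >= 2 coders; found %d.",
                    length(coders))
  }
  scores$key <- turn_key(scores$conversation_id, scores$turn_index)
  scores$pos <- scores$score >= binarize_at

  if (kind == "fleiss") {
    per_turn <- table(scores$key)
    crossed <- names(per_turn)[per_turn == length(coders)]
    if (length(crossed) == 0) {
      stop_validation("No turn is scored by all %d coders; Fleiss needs fully crossed turns.",
                      length(coders))
    }
    sub <- scores[scores$key %in% crossed, ]
    counts <- table(sub$key, factor(sub$pos, levels = c(FALSE, TRUE)))
    kappa <- fleiss_kappa(unclass(counts))
    used <- sub
  } else {
    wide <- tidyr::pivot_wider(scores[, c("key", "coder_id", "pos")],
                               names_from = "coder_id",
                               values_from = "pos")
    pairs <- utils::combn(coders, 2, simplify = FALSE)
    kappas <- vapply(pairs, function(p) {
      both <- !is.na(wide[[p[1]]]) & !is.na(wide[[p[2]]])
      if (!any(both)) return(NA_real_)
      suppressWarnings(cohen_kappa(wide[[p[1]]][both], wide[[p[2]]][both]))
    }, 0)
    kappas <- kappas[is.finite(kappas)]
    if (length(kappas) == 0) {
      warn("No coder pair yields a defined kappa.")
      kappa <- NaN
    } else {
      kappa <- mean(kappas)
    }
    used <- scores
  }
  structure(list(
    n_conversations = length(unique(used$conversation_id)),
    n_turns = length(unique(used$key)),
    n_coders = length(coders),
    kappa_statistic = kappa,
    kappa_kind = kind), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    "<reliability_report>: kappa = %s (%s), %d coders, %d turns in %d conversations\n",
    format(round_half_up(x$kappa_statistic, 2)), x$kappa_kind, x$n_coders,
    x$n_turns, x$n_conversations))
  invisible(x)
}
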