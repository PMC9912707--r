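#' Confusion counts for turn-level detection
#'
#' Crosses per-turn detector output with gold labels: TP = detected and
#' positive, FP = detected and negative, FN = undetected and positive,
#' TN = undetected and negative. Detections and gold must cover exactly
#' the same turn set.
#'
#' @param detections output of [detect_corpus()] (needs columns
#'   `conversation_id`, `turn_index`, `detected`).
#' @param gold gold-label tibble from [build_broad_gold()] /
#'   [apply_proctcae_overrides()].
#' @param standard `"broad"` (all symptom talk) or `"proctcae"`
#'   (framework-focused, i.e. the manually overridden labels).
#' @return object of class `confusion_counts` with integer fields `tp`,
#'   `fp`, `tn`, `fn`, `total`.
#' @export
confusion <- function(detections, gold, standard = c("broad", "proctcae")) {
  standard <- match.arg(standard)
  dk <- turn_key(detections$conversation_id, detections$turn_index)
  gk <- turn_key(gold$conversation_id, gold$turn_index)
  only_d <- setdiff(dk, gk)
  only_g <- setdiff(gk, dk)
  if (length(only_d) || length(only_g)) {
    stop_validation(
      "Detections and gold labels cover different turns. In detections only: %s. In gold only: %s.",
      toString(head(gsub("\r", ":", only_d), 5)),
      toString(head(gsub("\r", ":", only_g), 5)))
  }
  pos <- if (standard == "broad") gold$broad_positive else
    gold$proctcae_positive
  pos <- pos[match(dk, gk)]
  det <- detections$detected
  confusion_counts(tp = sum(det & pos), fp = sum(det & !pos),
                   tn = sum(!det & !pos), fn = sum(!det & pos))
}

#' @rdname confusion
#' @param tp,fp,tn,fn non-negative integer counts (for building the object
#'   directly, e.g. from a published table).
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (anyNA(counts) || any(counts < 0)) {
    stop_validation("Confusion counts must be non-negative.")
  }
  structure(as.list(c(counts, total = sum(counts))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts>: TP %d  FP %d  TN %d  FN %d  (total %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$total))
  invisible(x)
}

#' Detection performance metrics
#'
#' The five turn-level metrics:
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total` and F1 `2TP/(2TP+FP+FN)`.
#' A metric with a zero denominator is undefined and reported as `NA`
#' (never an exception and never silently 0 — strata with tiny counts
#' would otherwise bias summaries). The print method shows values rounded
#' half-up to 2 decimals, the convention of published performance tables;
#' raw values are kept in the object.
#'
#' @param counts a `confusion_counts` object.
#' @return list of class `metric_set` with fields `sensitivity`,
#'   `specificity`, `precision`, `accuracy`, `f1`.
#' @examples
#' performance_metrics(confusion_counts(tp = 1045, fp = 191,
#'                                      tn = 13157, fn = 281))
#' @export
performance_metrics <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    stop_validation("`counts` must be a confusion_counts object.")
  }
  if (counts$total == 0) stop_validation("No evaluated turns (total = 0).")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    sensitivity = safe_div(counts$tp, counts$tp + counts$fn),
    specificity = safe_div(counts$tn, counts$tn + counts$fp),
    precision = safe_div(counts$tp, counts$tp + counts$fp),
    accuracy = safe_div(counts$tp + counts$tn, counts$total),
    f1 = safe_div(2 * counts$tp, 2 * counts$tp + counts$fp + counts$fn)),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x)
  cat("<metric_set> (2 dp display, raw values retained)\n")
  for (nm in names(v)) {
    cat(sprintf("  %-11s %s\n", nm,
                if (is.na(v[[nm]])) "undefined" else
                  sprintf("%.2f", round_half_up(v[[nm]], 2))))
  }
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Evaluation report, optionally stratified
#'
#' Computes overall confusion counts and metrics, and optionally repeats
#' them per stratum of a conversation-level metadata key (e.g. patient
#' self-reported race). Stratum membership is a conversation/patient
#' attribute, so every turn of a conversation falls in the same stratum
#' and strata partition the evaluated turns: per-stratum counts always sum
#' to the overall counts. Conversations lacking the key fall in stratum
#' `"Missing"`.
#'
#' @param detections output of [detect_corpus()].
#' @param gold gold-label tibble.
#' @param corpus the evaluated `symtalk_corpus` (needed for metadata;
#'   may be `NULL` when `stratify_by` is `NULL`).
#' @param standard `"broad"` or `"proctcae"`.
#' @param stratify_by metadata key, or `NULL` for no stratification.
#' @return object of class `evaluation_report`: `gold_standard_label`,
#'   `counts`, `metrics`, and `strata` (tibble with per-stratum counts and
#'   metrics, or `NULL`).
#' @export
stratified_report <- function(detections, gold, corpus = NULL,
                              standard = c("broad", "proctcae"),
                              stratify_by = NULL) {
  standard <- match.arg(standard)
  overall <- confusion(detections, gold, standard)
  strata <- NULL
  if (!is.null(stratify_by)) {
    if (is.null(corpus)) {
      stop_validation("Stratified evaluation needs the corpus for metadata.")
    }
    sv <- conversation_strata(corpus, stratify_by)
    stratum <- unname(sv[detections$conversation_id])
    if (anyNA(stratum)) {
      stop_validation("Detections reference conversation(s) absent from the corpus.")
    }
    strata <- dplyr::bind_rows(lapply(sort(unique(stratum)), function(s) {
      keep <- stratum == s
      cc <- confusion(detections[keep, ], gold[
        turn_key(gold$conversation_id, gold$turn_index) %in%
          turn_key(detections$conversation_id[keep],
                   detections$turn_index[keep]), ], standard)
      m <- performance_metrics(cc)
      tibble::tibble(stratum = s,
                     n_conversations = length(unique(
                       detections$conversation_id[keep])),
                     tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
                     sensitivity = m$sensitivity,
                     specificity = m$specificity,
                     precision = m$precision, accuracy = m$accuracy,
                     f1 = m$f1)
    }))
  }
  structure(list(gold_standard_label = standard, counts = overall,
                 metrics = performance_metrics(overall), strata = strata),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> vs %s gold standard\n",
              x$gold_standard_label))
  print(x$counts)
  print(x$metrics)
  if (!is.null(x$strata)) {
    cat("Strata:\n")
    disp <- x$strata
    for (cl in c("sensitivity", "specificity", "precision", "accuracy",
                 "f1")) {
      disp[[cl]] <- round_half_up(disp[[cl]], 2)
    }
    print(as.data.frame(disp), row.names = FALSE)
  }
  invisible(x)
}

#' Sample classified turns for qualitative review
#'
#' Draws a reproducible random sample of misclassified (FP and FN) and
#' properly classified (TP) turns for human content analysis. The draw is
#' filtered for even proportions across dataset labels (validation/test)
#' as far as pool sizes allow, and a per-patient cap keeps the sample from
#' being dominated by a few patients.
#'
#' @param detections output of [detect_corpus()].
#' @param gold gold-label tibble.
#' @param corpus the evaluated corpus (for dataset labels and patient ids).
#' @param standard `"broad"` or `"proctcae"`.
#' @param n_misclassified number of FP+FN turns to draw.
#' @param n_tp number of TP turns to draw.
#' @param seed integer seed; fixed seed gives an identical sample.
#' @param max_per_patient cap on turns per patient (default unlimited).
#' @return object of class `review_sample`: tibble `turns`
#'   (`conversation_id`, `turn_index`, `class`, `dataset_label`,
#'   `patient_id`), the `seed`, and achieved per-class / per-dataset /
#'   unique-patient tallies.
#' @export
sample_for_review <- function(detections, gold, corpus,
                              standard = c("broad", "proctcae"),
                              n_misclassified = 300, n_tp = 150,
                              seed = 1, max_per_patient = Inf) {
  standard <- match.arg(standard)
  dk <- turn_key(detections$conversation_id, detections$turn_index)
  gk <- turn_key(gold$conversation_id, gold$turn_index)
  pos <- (if (standard == "broad") gold$broad_positive else
    gold$proctcae_positive)[match(dk, gk)]
  if (anyNA(pos)) stop_validation("Gold labels do not cover all detections.")
  cls <- dplyr::case_when(
    detections$detected & pos ~ "TP",
    detections$detected & !pos ~ "FP",
    !detections$detected & pos ~ "FN",
    TRUE ~ "TN")
  info <- corpus$conversations[
    match(detections$conversation_id, corpus$conversations$conversation_id), ]
  pool <- tibble::tibble(
    conversation_id = detections$conversation_id,
    turn_index = detections$turn_index,
    class = cls,
    dataset_label = info$dataset_label,
    patient_id = info$patient_id)

  with_private_seed(seed, {
    picked <- list(
      misclassified = draw_balanced(pool[pool$class %in% c("FP", "FN"), ],
                                    n_misclassified, "misclassified"),
      tp = draw_balanced(pool[pool$class == "TP", ], n_tp, "TP"))
    sample_turns <- dplyr::bind_rows(picked)
  })
  # enforce the per-patient cap jointly across both class pools
  if (is.finite(max_per_patient)) {
    with_private_seed(seed + 1, {
      sample_turns <- enforce_patient_cap(sample_turns, pool, max_per_patient,
                                          n_misclassified, n_tp)
    })
  }
  structure(list(
    turns = sample_turns[, c("conversation_id", "turn_index", "class",
                             "dataset_label", "patient_id")],
    seed = seed,
    achieved = list(
      per_class = table(sample_turns$class),
      per_dataset = table(sample_turns$dataset_label),
      unique_patients = length(unique(sample_turns$patient_id)))),
    class = "review_sample")
}

# even allocation across dataset labels by water-filling, then a uniform
# draw within each label's pool
draw_balanced <- function(pool, n, what) {
  if (nrow(pool) < n) {
    stop_validation(
      "Requested %d %s turns but only %d are available.", n, what,
      nrow(pool))
  }
  if (n == 0) return(pool[0, ])
  groups <- split(seq_len(nrow(pool)), pool$dataset_label)
  avail <- vapply(groups, length, 0L)
  take <- setNames(rep(0L, length(groups)), names(groups))
  remaining <- n
  while (remaining > 0) {
    open <- names(which(take < avail))
    share <- remaining %/% length(open)
    if (share == 0) {
      # distribute the remainder one by one, most headroom first
      order_open <- open[order(avail[open] - take[open], decreasing = TRUE)]
      bump <- order_open[seq_len(remaining)]
      take[bump] <- take[bump] + 1L
      remaining <- 0
    } else {
      add <- pmin(share, avail[open] - take[open])
      take[open] <- take[open] + add
      remaining <- remaining - sum(add)
    }
  }
  idx <- unlist(lapply(names(groups), function(g) {
    sample(groups[[g]], take[[g]])
  }))
  pool[sort(idx), ]
}

enforce_patient_cap <- function(sample_turns, pool, cap, n_misclassified,
                                n_tp) {
  over <- function(df) {
    tab <- table(df$patient_id)
    names(tab)[tab > cap]
  }
  guard <- 0
  while (length(bad <- over(sample_turns)) > 0 && guard < 1000) {
    guard <- guard + 1
    # drop one random excess turn of the worst offender, refill from the
    # unused pool of the same class group
    worst <- bad[1]
    rows <- which(sample_turns$patient_id == worst)
    drop <- sample(rows, 1)
    cls_group <- if (sample_turns$class[drop] %in% c("FP", "FN"))
      c("FP", "FN") else "TP"
    sample_turns <- sample_turns[-drop, ]
    used <- turn_key(sample_turns$conversation_id, sample_turns$turn_index)
    cand <- pool[pool$class %in% cls_group &
                   !turn_key(pool$conversation_id, pool$turn_index) %in%
                   used, ]
    patient_load <- table(sample_turns$patient_id)
    cand <- cand[is.na(match(cand$patient_id, names(patient_load))) |
                   patient_load[cand$patient_id] < cap, ]
    if (nrow(cand) == 0) {
      stop_validation(
        "Per-patient cap of %d is infeasible for the requested sample sizes (binding constraint: pool exhausted while rebalancing patient %s).",
        cap, worst)
    }
    sample_turns <- dplyr::bind_rows(sample_turns, cand[sample(nrow(cand), 1), ])
  }
  if (guard >= 1000) {
    stop_validation("Per-patient cap of %d could not be satisfied.", cap)
  }
  sample_turns
}

#' @export
print.review_sample <- function(x, ...) {
  cat(sprintf("<review_sample>: %d turns (seed %s)\n", nrow(x$turns),
              format(x$seed)))
  cat("  per class:  ",
      paste(names(x$achieved$per_class), as.integer(x$achieved$per_class),
            sep = "=", collapse = "  "), "\n")
  cat("  per dataset:",
      paste(names(x$achieved$per_dataset),
            as.integer(x$achieved$per_dataset), sep = "=", collapse = "  "),
      "\n")
  cat("  unique patients:", x$achieved$unique_patients, "\n")
  invisible(x)
}
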