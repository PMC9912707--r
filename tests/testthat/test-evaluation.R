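mk_det <- function(detected, cid = "c1") {
  tibble::tibble(conversation_id = cid,
                 turn_index = seq_along(detected) - 1L,
                 detected = detected)
}
mk_gold <- function(pos, cid = "c1") {
  tibble::tibble(conversation_id = cid,
                 turn_index = seq_along(pos) - 1L,
                 mean_score = ifelse(pos, 3, 0),
                 broad_positive = pos, proctcae_positive = pos,
                 override_source = "none")
}

test_that("confusion counts cross detection with gold labels correctly", {
  cc <- confusion(mk_det(rep(TRUE, 7)), mk_gold(rep(TRUE, 7)))
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(7, 0, 0, 0))

  # 10-turn fixture enumerated by hand
  det <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  pos <- c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  cc2 <- confusion(mk_det(det), mk_gold(pos))
  expect_equal(c(cc2$tp, cc2$fp, cc2$tn, cc2$fn), c(3, 2, 3, 2))
  expect_equal(cc2$total, 10)

  expect_error(confusion(mk_det(c(TRUE, FALSE)), mk_gold(TRUE)),
               "different turns")
})

test_that("the five metrics follow the printed formulas with NA for 0/0", {
  m <- performance_metrics(confusion_counts(3, 2, 3, 2))
  expect_equal(m$sensitivity, 3 / 5)
  expect_equal(m$specificity, 3 / 5)
  expect_equal(m$precision, 3 / 5)
  expect_equal(m$accuracy, 6 / 10)
  expect_equal(m$f1, 6 / 10)

  perfect <- performance_metrics(confusion_counts(5, 0, 0, 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  expect_true(is.na(perfect$specificity))

  expect_error(performance_metrics(confusion_counts(0, 0, 0, 0)),
               "total = 0")
  expect_error(performance_metrics(confusion_counts(-1, 0, 1, 0)),
               "non-negative")
})

test_that("metric identities hold over random count vectors (property)", {
  set.seed(51)
  for (i in 1:500) {
    v <- sample(0:200, 4, replace = TRUE)
    if (sum(v) == 0) next
    m <- performance_metrics(confusion_counts(v[1], v[2], v[3], v[4]))
    expect_equal(m$accuracy, (v[1] + v[3]) / sum(v))
    if (!is.na(m$precision) && !is.na(m$sensitivity) && !is.na(m$f1) &&
        (m$precision + m$sensitivity) > 0) {
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                     (m$precision + m$sensitivity), tolerance = 1e-12)
    }
  }
})

test_that("display rounding is half-up at two decimals", {
  expect_equal(round_half_up(0.615, 2), 0.62)
  expect_equal(round_half_up(0.625, 2), 0.63)  # banker's would give 0.62
  expect_equal(round_half_up(0.5819, 2), 0.58)
  expect_equal(round_half_up(-0.625, 2), -0.63)
})

strat_fixture <- function() {
  cfg <- generator_config(
    n_conversations = 12, turns_per_conversation = c(60, 80),
    symptom_prevalence = 0.25, colloquial_rate = 0.2,
    ambiguity_rate = 0.05, coder_noise = 0, n_coders = 1,
    strata = c(hard = 0.5, easy = 0.5),
    stratum_colloquial_multiplier = c(hard = 4, easy = 0),
    seed = 99)
  generate_corpus(cfg)
}

test_that("stratified reports partition the turns and expose planted difficulty", {
  syn <- strat_fixture()
  det <- detect_corpus(syn$corpus, seed_lexicon())
  gold <- build_broad_gold(syn$scores)

  rep1 <- stratified_report(det, gold, syn$corpus, standard = "broad",
                            stratify_by = "race")
  expect_equal(sum(rep1$strata$tp), rep1$counts$tp)
  expect_equal(sum(rep1$strata$fp), rep1$counts$fp)
  expect_equal(sum(rep1$strata$tn), rep1$counts$tn)
  expect_equal(sum(rep1$strata$fn), rep1$counts$fn)

  f1 <- setNames(rep1$strata$f1, rep1$strata$stratum)
  expect_lt(f1[["hard"]], f1[["easy"]])

  # single-stratum corpus: stratum metrics equal overall metrics
  one <- which(det$conversation_id %in%
                 syn$corpus$conversations$conversation_id[1])
  det1 <- det[one, ]
  gold1 <- gold[one, ]
  rep2 <- stratified_report(det1, gold1, syn$corpus, standard = "broad",
                            stratify_by = "race")
  expect_equal(nrow(rep2$strata), 1)
  expect_equal(rep2$strata$f1, rep2$metrics$f1)
})

test_that("review sampling is seeded, class-correct, balanced and capped", {
  syn <- strat_fixture()
  det <- detect_corpus(syn$corpus, seed_lexicon())
  gold <- build_broad_gold(syn$scores)

  s1 <- sample_for_review(det, gold, syn$corpus, n_misclassified = 20,
                          n_tp = 10, seed = 5)
  s2 <- sample_for_review(det, gold, syn$corpus, n_misclassified = 20,
                          n_tp = 10, seed = 5)
  expect_identical(s1$turns, s2$turns)
  expect_equal(nrow(s1$turns), 30)
  expect_false(any(duplicated(s1$turns[, c("conversation_id",
                                           "turn_index")])))

  # sampled classes match a recomputation from detections and gold
  key <- paste(s1$turns$conversation_id, s1$turns$turn_index)
  dkey <- paste(det$conversation_id, det$turn_index)
  det_s <- det$detected[match(key, dkey)]
  pos_s <- gold$broad_positive[match(key, dkey)]
  want <- ifelse(det_s & pos_s, "TP", ifelse(det_s, "FP", "FN"))
  expect_identical(s1$turns$class, want)
  expect_equal(sum(s1$turns$class == "TP"), 10)
  expect_equal(sum(s1$turns$class %in% c("FP", "FN")), 20)

  expect_error(
    sample_for_review(det, gold, syn$corpus, n_misclassified = 10000,
                      n_tp = 10, seed = 5),
    "available")

  s3 <- sample_for_review(det, gold, syn$corpus, n_misclassified = 12,
                          n_tp = 6, seed = 5, max_per_patient = 4)
  expect_true(all(table(s3$turns$patient_id) <= 4))
  expect_equal(nrow(s3$turns), 18)
})

test_that("dataset-label balance is as even as the pools allow", {
  # two datasets with ample pools in each: an even 10/10 split is forced
  corpus <- as_corpus(c(
    purrr::map(1:20, function(i) conversation(
      sprintf("v%02d", i), sprintf("pv%02d", i),
      tibble::tibble(speaker_role = "patient", text = "the pain is bad"),
      dataset_label = "validation")),
    purrr::map(1:20, function(i) conversation(
      sprintf("t%02d", i), sprintf("pt%02d", i),
      tibble::tibble(speaker_role = "patient", text = "the pain is bad"),
      dataset_label = "test"))))
  det <- detect_corpus(corpus, seed_lexicon())
  gold <- mk_gold(rep(TRUE, 40))
  gold$conversation_id <- det$conversation_id
  gold$turn_index <- det$turn_index
  s <- sample_for_review(det, gold, corpus, n_misclassified = 0,
                         n_tp = 20, seed = 3)
  expect_equal(unname(as.integer(s$achieved$per_dataset)), c(10, 10))
})
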