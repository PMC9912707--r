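scores_tbl <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(conversation_id = r[[1]], turn_index = as.integer(r[[2]]),
                   coder_id = r[[3]], score = as.integer(r[[4]]))
  }))
}

test_that("broad gold standard thresholds the mean score at exactly 2", {
  sc <- scores_tbl(
    list("c1", 0, "a", 2), list("c1", 0, "b", 2), list("c1", 0, "c", 2),
    list("c1", 1, "a", 1), list("c1", 1, "b", 2), list("c1", 1, "c", 2),
    list("c1", 2, "a", 3),
    list("c1", 3, "a", 1), list("c1", 3, "b", 3))  # mean exactly 2.0
  gold <- build_broad_gold(sc)
  expect_equal(gold$broad_positive, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(gold$mean_score[2], 5 / 3)
  expect_equal(gold$proctcae_positive, gold$broad_positive)
  expect_equal(unique(gold$override_source), "none")
})

test_that("randomized coder matrices agree with a brute-force mean rule", {
  set.seed(21)
  for (i in 1:30) {
    n_turns <- sample(5:20, 1)
    n_coders <- sample(1:4, 1)
    sc <- expand.grid(turn_index = seq_len(n_turns) - 1L,
                      coder_id = letters[seq_len(n_coders)])
    sc$conversation_id <- "cv"
    sc$score <- sample(0:3, nrow(sc), replace = TRUE)
    gold <- build_broad_gold(sc)
    want <- tapply(sc$score, sc$turn_index, mean)
    expect_identical(gold$broad_positive,
                     as.vector(want[as.character(gold$turn_index)] >= 2))
  }
})

test_that("score validation rejects bad values, duplicates and uncovered turns", {
  expect_error(build_broad_gold(scores_tbl(list("c1", 0, "a", 4))), "0..3")
  expect_error(
    build_broad_gold(scores_tbl(list("c1", 0, "a", 2),
                                list("c1", 0, "a", 3))),
    "same \\(turn, coder\\)")
  expect_error(
    build_broad_gold(scores_tbl(list("c1", 0, "a", 2)),
                     turns = tibble::tibble(conversation_id = "c1",
                                            turn_index = 0:1)),
    "zero coder scores.*c1:1")
})

test_that("overrides rewrite only targeted turns and are idempotent", {
  gold <- build_broad_gold(scores_tbl(
    list("c1", 0, "a", 3), list("c1", 1, "a", 0), list("c1", 2, "a", 2)))
  expect_equal(gold$proctcae_positive, gold$broad_positive)

  ov <- tibble::tibble(conversation_id = c("c1", "c1"),
                       turn_index = c(0L, 1L),
                       proctcae_positive = c(FALSE, TRUE))
  g1 <- apply_proctcae_overrides(gold, ov)
  expect_equal(g1$proctcae_positive, c(FALSE, TRUE, TRUE))
  expect_equal(g1$broad_positive, gold$broad_positive)
  expect_equal(g1$override_source, c("manual", "manual", "none"))
  expect_identical(apply_proctcae_overrides(g1, ov), g1)

  expect_error(
    apply_proctcae_overrides(gold, tibble::tibble(
      conversation_id = "cX", turn_index = 9L, proctcae_positive = TRUE)),
    "unknown turn")
})

test_that("Cohen's kappa matches hand computations and edge cases", {
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.5)
  expect_equal(cohen_kappa(c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1)), 1)
  expect_warning(k <- cohen_kappa(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_true(is.nan(k))
})

test_that("Fleiss' kappa matches an independent closed-form implementation", {
  set.seed(31)
  for (i in 1:20) {
    n_items <- sample(8:30, 1)
    n_raters <- sample(2:5, 1)
    n_cat <- sample(2:4, 1)
    ratings <- matrix(sample(seq_len(n_cat), n_items * n_raters,
                             replace = TRUE), n_items)
    counts <- t(apply(ratings, 1, function(r) {
      tabulate(r, nbins = n_cat)
    }))
    expect_equal(fleiss_kappa(counts), oracle_fleiss(counts),
                 tolerance = 1e-12)
  }
})

test_that("interrater_kappa binarizes, filters to crossed turns and is coder-order invariant", {
  sc <- scores_tbl(
    list("c1", 0, "a", 3), list("c1", 0, "b", 2), list("c1", 0, "c", 3),
    list("c1", 1, "a", 0), list("c1", 1, "b", 1), list("c1", 1, "c", 0),
    list("c1", 2, "a", 2), list("c1", 2, "b", 0), list("c1", 2, "c", 3),
    list("c2", 0, "a", 1))  # not fully crossed: dropped by fleiss
  rep_f <- interrater_kappa(sc, kind = "fleiss")
  expect_equal(rep_f$n_turns, 3)
  expect_equal(rep_f$n_coders, 3)
  expect_true(rep_f$kappa_statistic >= -1 && rep_f$kappa_statistic <= 1)

  # relabeling coders leaves kappa unchanged
  relabeled <- dplyr::mutate(sc, coder_id = c(a = "z", b = "y", c = "x")[coder_id])
  expect_equal(interrater_kappa(relabeled, kind = "fleiss")$kappa_statistic,
               rep_f$kappa_statistic)

  rep_c <- interrater_kappa(sc, kind = "cohen-pairwise-mean")
  expect_equal(rep_c$kappa_kind, "cohen-pairwise-mean")
  expect_true(abs(rep_c$kappa_statistic) <= 1)

  expect_error(interrater_kappa(scores_tbl(list("c1", 0, "a", 1))),
               ">= 2 coders")
})

test_that("perfect agreement gives kappa 1; independent coders drift to 0", {
  sc <- scores_tbl(
    list("c1", 0, "a", 3), list("c1", 0, "b", 3),
    list("c1", 1, "a", 0), list("c1", 1, "b", 0),
    list("c1", 2, "a", 3), list("c1", 2, "b", 3))
  expect_equal(interrater_kappa(sc, kind = "fleiss")$kappa_statistic, 1)
  expect_equal(
    interrater_kappa(sc, kind = "cohen-pairwise-mean")$kappa_statistic, 1)

  set.seed(41)
  n <- 4000
  sc2 <- tibble::tibble(
    conversation_id = "cv",
    turn_index = rep(seq_len(n) - 1L, 2),
    coder_id = rep(c("a", "b"), each = n),
    score = sample(0:3, 2 * n, replace = TRUE))
  expect_lt(abs(interrater_kappa(sc2, kind = "fleiss")$kappa_statistic),
            0.08)
})
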