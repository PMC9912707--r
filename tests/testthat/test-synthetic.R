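small_cfg <- function(...) {
  generator_config(n_conversations = 6, turns_per_conversation = c(40, 60),
                   seed = 17, ...)
}

test_that("config validation enforces rate ranges", {
  expect_error(generator_config(symptom_prevalence = 1.2), "\\[0, 1\\]")
  expect_error(generator_config(coder_noise = 0.6), "\\[0, 0.5\\]")
  expect_error(generator_config(turns_per_conversation = c(5, 2)),
               "range")
  expect_error(generator_config(strata = c(a = 0.5, b = 0.2)), "sum to 1")
})

test_that("boundary prevalences force the planted truth", {
  syn0 <- generate_corpus(small_cfg(symptom_prevalence = 0))
  expect_false(any(syn0$truth$positive))
  expect_true(all(syn0$truth$mechanism %in% c("decoy", "filler")))

  syn1 <- generate_corpus(small_cfg(symptom_prevalence = 1,
                                    colloquial_rate = 0))
  expect_true(all(syn1$truth$positive))
  det <- detect_corpus(syn1$corpus, seed_lexicon())
  expect_true(all(det$detected))  # every turn carries a lexicon term
})

test_that("the generator is deterministic under a fixed seed", {
  a <- generate_corpus(small_cfg())
  b <- generate_corpus(small_cfg())
  expect_identical(a$corpus$turns, b$corpus$turns)
  expect_identical(a$truth, b$truth)
  expect_identical(a$scores, b$scores)
  expect_identical(a$overrides, b$overrides)
  c2 <- generate_corpus(generator_config(n_conversations = 6,
                                         turns_per_conversation = c(40, 60),
                                         seed = 18))
  expect_false(identical(a$corpus$turns, c2$corpus$turns))
})

test_that("planted mechanisms honour their lexical guarantees", {
  syn <- generate_corpus(small_cfg(symptom_prevalence = 0.3,
                                   colloquial_rate = 0.4,
                                   ambiguity_rate = 0.3))
  det <- detect_corpus(syn$corpus, seed_lexicon())
  stopifnot(identical(det$turn_index, syn$truth$turn_index))
  # lexical positives always contain a lexicon term
  expect_true(all(det$detected[syn$truth$mechanism == "lexical"]))
  # colloquial positives and decoys never do (disjoint default lists)
  expect_false(any(det$detected[syn$truth$mechanism == "colloquial"]))
  expect_false(any(det$detected[syn$truth$mechanism == "decoy"]))
  # decoy turns contain a decoy phrase
  decoy_texts <- syn$corpus$turns$text[syn$truth$mechanism == "decoy"]
  expect_true(all(decoy_texts %in% decoy_phrases()))
})

test_that("noiseless coder scores binarize back to the planted truth", {
  syn <- generate_corpus(small_cfg(coder_noise = 0, n_coders = 3))
  gold <- build_broad_gold(syn$scores)
  key_g <- paste(gold$conversation_id, gold$turn_index)
  key_t <- paste(syn$truth$conversation_id, syn$truth$turn_index)
  expect_identical(gold$broad_positive[match(key_t, key_g)],
                   syn$truth$positive)

  # overrides mark exactly the PRO-CTCAE-irrelevant colloquial turns
  focused <- apply_proctcae_overrides(gold, syn$overrides)
  expect_identical(focused$proctcae_positive[match(key_t, key_g)],
                   syn$truth$proctcae_relevant)
})

test_that("noisy coders disagree but stay within the score range", {
  syn <- generate_corpus(small_cfg(coder_noise = 0.3, n_coders = 3))
  expect_true(all(syn$scores$score %in% 0:3))
  wide <- tidyr::pivot_wider(syn$scores,
                             names_from = "coder_id",
                             values_from = "score")
  expect_gt(sum(wide$coder01 != wide$coder02), 0)
})

test_that("expected performance matches the generative closed form", {
  cfg <- small_cfg(colloquial_rate = 0.3)
  m <- expected_performance(cfg)
  expect_equal(m$sensitivity, 0.7)
  expect_equal(m$precision, 1)

  m0 <- expected_performance(small_cfg(colloquial_rate = 0))
  expect_equal(m0$sensitivity, 1)

  # decoys inside the lexicon push expected specificity below 1
  leaky <- expected_performance(small_cfg(colloquial_rate = 0.3),
                                decoys = c("don't worry", "deep pain"))
  expect_lt(leaky$specificity, 1)
  expect_lt(leaky$precision, 1)
})

test_that("an empty or leaking lexicon is rejected up front", {
  expect_error(generate_corpus(small_cfg(), lexicon = "x"), "keyword_library")
  leak <- keyword_library(tibble::tibble(term = c("nausea", "visit"),
                                         categories = list("gi", "other")))
  expect_error(generate_corpus(small_cfg(), lexicon = leak),
               "template text contains")
  bad_para <- paraphrase_phrases()
  bad_para$phrase[1] <- "the pain ran through"
  expect_error(generate_corpus(small_cfg(), paraphrases = bad_para),
               "cannot model misses")
})

test_that("synthetic output files round-trip through the standard readers", {
  syn <- generate_corpus(small_cfg(n_coders = 2))
  dir <- withr::local_tempdir()
  write_synthetic(syn, dir)
  corpus <- read_corpus(file.path(dir, "transcripts"))
  expect_equal(corpus$turns, syn$corpus$turns)
  sc <- read_annotations(file.path(dir, "annotations.csv"))
  expect_equal(nrow(sc), nrow(syn$scores))
  if (nrow(syn$overrides)) {
    ov <- read_overrides(file.path(dir, "overrides.csv"))
    expect_equal(ov$turn_index, syn$overrides$turn_index)
    expect_false(any(ov$proctcae_positive))
  }
})
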