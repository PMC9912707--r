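test_that("a small library file loads with entries and exclusions separated", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "type,term,categories,is_medication",
    "keyword,nausea,gi,FALSE",
    "keyword,ativan,mood_anxiety,TRUE",
    "exclusion,deep breath,,"), path)
  lib <- suppressMessages(read_keyword_library(path))
  expect_equal(term_count(lib), 2)
  expect_equal(lib$exclusions$phrase, "deep breath")
  expect_true(lib$entries$is_medication[lib$entries$term == "ativan"])
  expect_equal(lib$entries$categories[[match("nausea", lib$entries$term)]],
               "gi")
})

test_that("degenerate and malformed library files raise informative errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("type,term,categories", empty)
  expect_error(suppressMessages(read_keyword_library(empty)), "no entries")

  missing <- file.path(tempdir(), "does-not-exist-lib.csv")
  expect_error(read_keyword_library(missing), class = "symtalk_io_error")

  badcat <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term,categories", "nausea,stomachy"), badcat)
  expect_error(suppressMessages(read_keyword_library(badcat)),
               "Allowed vocabulary.*pain")

  malformed <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term,categories", "nausea,gi", ",gi"), malformed)
  expect_error(suppressMessages(read_keyword_library(malformed)),
               "line|row")
})

test_that("duplicate terms collapse to one entry with the category union", {
  expect_warning(
    lib <- keyword_library(tibble::tibble(
      term = c("nausea", "Nausea "),
      categories = list("gi", "other"))),
    "Duplicate")
  expect_equal(term_count(lib), 1)
  expect_setequal(lib$entries$categories[[1]], c("gi", "other"))
})

test_that("save/load round-trip is the identity in both dialects", {
  lib <- keyword_library(
    tibble::tibble(
      term = c("fuzzy brain", "painkiller", "breathless", "nausea",
               "stool softeners"),
      categories = list("neurological", "pain", "respiratory", "gi", "gi"),
      is_medication = c(FALSE, TRUE, FALSE, FALSE, TRUE),
      is_clinician_authored = c(FALSE, FALSE, FALSE, TRUE, FALSE),
      is_symptom_specific = c(FALSE, FALSE, TRUE, FALSE, FALSE),
      source = c("validation-adjustment", "validation-adjustment",
                 "validation-adjustment", "a-priori", "development-corpus")),
    exclusions = tibble::tibble(phrase = c("deep breath", "deep breaths"),
                                rationale = "exam context"),
    version_label = "rt-1")
  for (ext in c(".csv", ".yml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_keyword_library(lib, path)
    back <- suppressMessages(read_keyword_library(path))
    expect_identical(back$entries, lib$entries)
    expect_identical(back$exclusions, lib$exclusions)
    expect_identical(back$version_label, lib$version_label)
    expect_identical(back$category_vocabulary, lib$category_vocabulary)
  }
})

test_that("diffs capture additions, removals and recategorizations exactly", {
  mk <- function(terms, label = "v") {
    keyword_library(tibble::tibble(term = terms,
                                   categories = list("other")),
                    version_label = label)
  }
  a <- mk(c("x", "y"), "a")
  b <- mk(c("x", "z"), "b")
  d <- diff_libraries(a, b)
  expect_equal(d$added$term, "z")
  expect_equal(d$removed$term, "y")
  expect_equal(term_count(b),
               term_count(a) + nrow(d$added) - nrow(d$removed))

  d_id <- diff_libraries(a, a)
  expect_equal(nrow(d_id$added) + nrow(d_id$removed) +
                 nrow(d_id$recategorized) + nrow(d_id$exclusions_added) +
                 nrow(d_id$exclusions_removed), 0)
})

test_that("applying a diff reconstructs the target library (property)", {
  set.seed(42)
  vocab <- c("ache", "sore", "numb", "itch", "burn", "throb", "raw",
             "stiff", "weak", "swollen")
  for (rep in 1:25) {
    a <- random_library(vocab, sample(3:8, 1), n_excl = sample(0:2, 1))
    b <- random_library(vocab, sample(3:8, 1), n_excl = sample(0:2, 1))
    d <- diff_libraries(a, b)
    rebuilt <- apply_library_diff(a, d)
    expect_identical(rebuilt$entries, b$entries)
    expect_identical(rebuilt$exclusions, b$exclusions)
    expect_equal(term_count(b),
                 term_count(a) + nrow(d$added) - nrow(d$removed))
  }
})

test_that("flag filters drop exactly the flagged entries", {
  lib <- keyword_library(tibble::tibble(
    term = c("ativan", "nausea"),
    categories = list("mood_anxiety", "gi"),
    is_medication = c(TRUE, FALSE)))
  kept <- filter_library(lib, drop_medication = TRUE)
  expect_equal(kept$entries$term, "nausea")
  expect_identical(filter_library(lib)$entries, lib$entries)

  all_med <- keyword_library(tibble::tibble(
    term = "ativan", categories = list("mood_anxiety"),
    is_medication = TRUE))
  expect_error(filter_library(all_med, drop_medication = TRUE),
               "every entry")
})

test_that("the seed lexicon is valid and covers all category groups", {
  lib <- seed_lexicon()
  expect_s3_class(validate_library(lib), "keyword_library")
  expect_setequal(unique(unlist(lib$entries$categories)),
                  default_categories())
  expect_true(all(c("deep breath", "deep breaths") %in%
                    lib$exclusions$phrase))
})
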