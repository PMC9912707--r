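#' Seed symptom keyword lexicon
#'
#' A small, format-complete starter library for turn-level symptom
#' detection in oncology conversations. It combines colloquial terms heard
#' in patient-clinician talk (e.g. "fuzzy brain", "painkiller",
#' "breathless", "stool softener"), medication names used to treat relevant
#' symptoms (e.g. "ativan"), and a-priori anchor terms for each PRO-CTCAE
#' system category so that every category group is represented. It ships
#' with the exam-context exclusion "deep breath"/"deep breaths": a matched
#' keyword fully contained in that phrase is suppressed, because clinicians
#' instructing a patient to take deep breaths are not discussing a symptom.
#'
#' This is a seed, not a finished instrument: a deployed library is
#' expected to be grown from local transcripts with the mining loop
#' ([enumerate_candidates()], [apply_triage()]) and re-validated. A
#' full-scale curated library in the supported file formats can be loaded
#' with [read_keyword_library()].
#'
#' @return a [keyword_library()] (version label `"seed-0.1"`).
#' @examples
#' seed_lexicon()
#' @export
seed_lexicon <- function() {
  dev <- "development-corpus"
  ap <- "a-priori"
  va <- "validation-adjustment"
  e <- function(term, categories, source, med = FALSE) {
    tibble::tibble(term = term, categories = list(categories),
                   is_medication = med, source = source)
  }
  entries <- dplyr::bind_rows(
    # colloquial / conversational terms observed in clinic talk
    e("pain", "pain", dev),            e("pains", "pain", dev),
    e("painful", "pain", dev),         e("ache", "pain", dev),
    e("appetite", "gi", dev),          e("bowels", "gi", dev),
    e("worry", "mood_anxiety", dev),   e("worried", "mood_anxiety", dev),
    e("red", "cutaneous", dev),        e("tired", "sleep_wake", dev),
    e("vomiting", "gi", dev),          e("fatigue", "other", dev),
    # medications used to treat relevant symptoms
    e("ativan", "mood_anxiety", dev, med = TRUE),
    e("stool softener", "gi", dev, med = TRUE),
    e("stool softeners", "gi", dev, med = TRUE),
    # later-round additions after validation against annotated transcripts
    e("breathless", "respiratory", va),
    e("fuzzy brain", "neurological", va),
    e("painkiller", "pain", va, med = TRUE),
    e("painkillers", "pain", va, med = TRUE),
    # a-priori PRO-CTCAE category anchors
    e("nausea", "gi", ap),             e("nauseous", "gi", ap),
    e("diarrhea", "gi", ap),           e("constipation", "gi", ap),
    e("insomnia", "sleep_wake", ap),   e("drowsy", "sleep_wake", ap),
    e("numbness", "neurological", ap),
    e("dizziness", "neurological", ap),
    e("headache", c("neurological", "pain"), ap),
    e("rash", "cutaneous", ap),        e("itching", "cutaneous", ap),
    e("anxiety", "mood_anxiety", ap),  e("anxious", "mood_anxiety", ap),
    e("depressed", "mood_anxiety", ap),
    e("cough", "respiratory", ap),
    e("wheezing", "respiratory", ap),
    e("mouth sores", "oral", ap),      e("dry mouth", "oral", ap),
    e("libido", "sexual", ap),
    e("swelling", "other", ap),        e("fever", "other", ap),
    e("chills", "other", ap))
  keyword_library(
    entries,
    exclusions = tibble::tibble(
      phrase = c("deep breath", "deep breaths"),
      rationale = "physical-exam instruction, not a symptom description"),
    version_label = "seed-0.1")
}

#' Default decoy phrases for the synthetic generator
#'
#' Decoys are phrases that superficially resemble symptom talk but are not:
#' exam instructions, conversational idioms, topic-introduction phrases.
#' The default list is disjoint from [seed_lexicon()] — no decoy contains a
#' seed term at token boundaries — so synthetic corpora built from the
#' defaults plant no false positives. To exercise the false-positive path,
#' pass decoys that do overlap the lexicon (e.g. `"don't worry"` against a
#' lexicon containing `"worry"`).
#'
#' @return character vector of lowercase phrases.
#' @export
decoy_phrases <- function() {
  c("take a few deep breaths for me",
    "deep breaths now",
    "is that bothering you schedule-wise",
    "take your time",
    "no rush at all today")
}

#' Default colloquial paraphrases for the synthetic generator
#'
#' Paraphrases are symptom expressions a keyword library will miss:
#' colloquialisms, numeric severity ratings, and descriptions spread over
#' everyday words. Each carries the symptom category it stands for. None
#' contains a [seed_lexicon()] term, so a planted paraphrase turn is a
#' guaranteed false negative for the seed library.
#'
#' @return tibble with columns `phrase` and `category`.
#' @export
paraphrase_phrases <- function() {
  tibble::tibble(
    phrase = c("things will just run through",
               "it is about a seven and three quarters",
               "i can't keep anything down",
               "my head is in a fog all day",
               "i was tossing and turning all night",
               "everything tastes like metal",
               "i have been on edge all the time"),
    category = c("gi", "pain", "gi", "neurological", "sleep_wake",
                 "oral", "mood_anxiety"))
}

#' Generate a synthetic full-scale keyword library
#'
#' Expands the seed lexicon to an arbitrary term count by generating
#' distinct synthetic variant terms (`"<term> v<k>"`). The result is
#' synthetic filler — useful for exercising the loader, differ and matcher
#' at the scale of a real curated library (around a thousand terms or
#' more), not a linguistic resource.
#'
#' @param n_terms target term count (must be >= the seed term count).
#' @param base library to expand; defaults to [seed_lexicon()].
#' @return a `keyword_library` with exactly `n_terms` entries, version
#'   label `"synthetic-<n_terms>"`.
#' @export
synthetic_library <- function(n_terms, base = seed_lexicon()) {
  validate_is_library(base)
  n0 <- term_count(base)
  if (n_terms < n0) {
    stop_validation("n_terms (%d) is below the base library size (%d).",
                    n_terms, n0)
  }
  extra <- n_terms - n0
  if (extra == 0) return(base)
  i <- seq_len(extra)
  src_idx <- ((i - 1) %% n0) + 1
  variant <- tibble::tibble(
    term = paste0(base$entries$term[src_idx], " v", ((i - 1) %/% n0) + 1),
    categories = base$entries$categories[src_idx],
    is_medication = base$entries$is_medication[src_idx],
    source = "user")
  keyword_library(
    dplyr::bind_rows(base$entries, variant),
    base$exclusions,
    version_label = sprintf("synthetic-%d", n_terms),
    category_vocabulary = base$category_vocabulary)
}
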