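# Template sentences for planted turns. None of the slot-free words below
# matches a seed-lexicon term at token boundaries; generate_corpus()
# verifies this against whatever lexicon it is given and errors on
# contamination, so planted mechanisms stay exact ground truth.
lexical_templates <- function() {
  c("i have been having a lot of %s this week",
    "the %s has been worse since the last visit",
    "any %s since we changed the dose",
    "do you need any more %s",
    "she mentioned some %s over the weekend",
    "my %s is back again")
}

filler_sentences <- function() {
  c("we will see you in two weeks then",
    "let me pull up your chart first",
    "thanks for coming in today",
    "my daughter drove me over this morning",
    "the parking was easier this visit",
    "we can go over the plan at the next visit",
    "that sounds good to me",
    "could you repeat the second part",
    "the scheduling desk will call you",
    "i brought the forms you asked about")
}

#' Configuration for the synthetic conversation generator
#'
#' Defaults emulate a test-scale evaluation corpus of outpatient oncology
#' visits: 31 conversations of several hundred turns each (roughly 15k
#' turns in total), with about 12% of turns containing symptom talk.
#' `colloquial_rate` is the probability that a positive turn phrases its
#' symptom as a colloquial paraphrase absent from the lexicon (a planted
#' false negative); its default 0.49 mirrors a regime where a keyword
#' library catches only about half of broad-standard symptom talk.
#' `proctcae_irrelevant_rate` is the share of those colloquial turns whose
#' content falls outside the PRO-CTCAE framework and is therefore
#' overridden to negative in the focused gold standard (default 0.72).
#' `ambiguity_rate` is the probability that a negative turn carries a
#' decoy phrase superficially resembling symptom language (exam
#' instructions, idioms). `coder_noise` perturbs each coder's 0-3 score by
#' +/-1 with the given probability (truncated to 0..3); at 0, scores
#' binarize exactly back to truth.
#'
#' @param n_conversations number of conversations.
#' @param turns_per_conversation length-2 integer range, turns drawn
#'   uniformly per conversation.
#' @param symptom_prevalence probability a turn is symptom-positive.
#' @param colloquial_rate probability a positive turn uses an
#'   out-of-lexicon paraphrase.
#' @param proctcae_irrelevant_rate share of colloquial positives overridden
#'   to negative in the focused gold standard.
#' @param ambiguity_rate probability a negative turn contains a decoy.
#' @param coder_noise per-coder score perturbation probability (0 to 0.5).
#' @param n_coders number of simulated coders.
#' @param strata named probability vector for patient-level stratum
#'   assignment (metadata key `race`), mirroring an enriched test sample.
#' @param stratum_colloquial_multiplier optional named vector scaling
#'   `colloquial_rate` per stratum (for planting differential difficulty).
#' @param seed integer seed fixing the full output.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_conversations = 31,
                             turns_per_conversation = c(350, 600),
                             symptom_prevalence = 0.12,
                             colloquial_rate = 0.49,
                             proctcae_irrelevant_rate = 0.72,
                             ambiguity_rate = 0.10,
                             coder_noise = 0,
                             n_coders = 1,
                             strata = c(black = 10, other = 2, white = 1,
                                        more_than_one = 1, missing = 1) / 15,
                             stratum_colloquial_multiplier = NULL,
                             seed = 1) {
  rates <- c(symptom_prevalence = symptom_prevalence,
             colloquial_rate = colloquial_rate,
             proctcae_irrelevant_rate = proctcae_irrelevant_rate,
             ambiguity_rate = ambiguity_rate)
  if (any(rates < 0 | rates > 1)) {
    stop_validation("All rates must lie in [0, 1].")
  }
  if (coder_noise < 0 || coder_noise > 0.5) {
    stop_validation("coder_noise must lie in [0, 0.5].")
  }
  if (length(turns_per_conversation) != 2 ||
      any(turns_per_conversation < 1) ||
      turns_per_conversation[1] > turns_per_conversation[2]) {
    stop_validation("turns_per_conversation must be an increasing range >= 1.")
  }
  if (n_conversations < 1) stop_validation("Need >= 1 conversation.")
  if (abs(sum(strata) - 1) > 1e-8) {
    stop_validation("Stratum probabilities must sum to 1.")
  }
  structure(list(
    n_conversations = as.integer(n_conversations),
    turns_per_conversation = as.integer(turns_per_conversation),
    symptom_prevalence = symptom_prevalence,
    colloquial_rate = colloquial_rate,
    proctcae_irrelevant_rate = proctcae_irrelevant_rate,
    ambiguity_rate = ambiguity_rate,
    coder_noise = coder_noise,
    n_coders = as.integer(n_coders),
    strata = strata,
    stratum_colloquial_multiplier = stratum_colloquial_multiplier,
    seed = seed), class = "generator_config")
}

# fraction of phrases in `phrases` that the lexicon would match
phrase_hit_fraction <- function(phrases, cl) {
  if (length(phrases) == 0) return(0)
  mean(vapply(phrases, function(p) detect_turn(p, cl)$detected, NA))
}

#' Generate a synthetic conversation corpus with planted ground truth
#'
#' Builds template-based conversations in which every turn's mechanism is
#' known: `lexical` positives embed a lexicon term, `colloquial` positives
#' embed a paraphrase containing no lexicon term (a guaranteed miss),
#' `decoy` negatives embed a phrase that merely resembles symptom language,
#' and `filler` negatives are ordinary clinic talk. Coder score files and
#' PRO-CTCAE override sidecars consistent with the truth (under the noise
#' model) are generated alongside, so every downstream module — matcher,
#' gold-standard builder, evaluator — can be exercised end to end with
#' known expected behaviour. Text is deliberately schematic, not
#' linguistically realistic.
#'
#' The generator refuses lexicons whose terms leak into its filler or
#' template text, and records which decoys/paraphrases overlap the lexicon
#' (the default lists are disjoint from [seed_lexicon()]).
#'
#' @param config a [generator_config()].
#' @param lexicon the `keyword_library` that defines "lexical" positives.
#' @param decoys character vector of decoy phrases.
#' @param paraphrases tibble `phrase`/`category` of colloquial paraphrases.
#' @return list of class `synthetic_corpus`: `corpus` (a
#'   `symtalk_corpus`), `truth` (per-turn tibble: `positive`, `mechanism`,
#'   `category`, `proctcae_relevant`), `scores` (coder-score tibble),
#'   `overrides` (focused-standard sidecar tibble), and the `config`.
#' @export
generate_corpus <- function(config,
                            lexicon = seed_lexicon(),
                            decoys = decoy_phrases(),
                            paraphrases = paraphrase_phrases()) {
  if (!inherits(config, "generator_config")) {
    stop_validation("`config` must come from generator_config().")
  }
  validate_is_library(lexicon)
  if (term_count(lexicon) == 0) stop_validation("Empty lexicon.")
  cl <- compile_library(lexicon)

  contaminated <- c(
    filler_sentences()[vapply(filler_sentences(),
                              function(s) detect_turn(s, cl)$detected, NA)],
    lexical_templates()[vapply(sprintf(lexical_templates(), "zzz"),
                               function(s) detect_turn(s, cl)$detected, NA)])
  if (length(contaminated)) {
    stop_validation("Generator template text contains lexicon term(s): %s.",
                    toString(head(contaminated, 3)))
  }
  para_bad <- vapply(paraphrases$phrase,
                     function(p) detect_turn(p, cl)$detected, NA)
  if (any(para_bad)) {
    stop_validation("Paraphrase(s) contain lexicon terms and cannot model misses: %s.",
                    toString(paraphrases$phrase[para_bad]))
  }
  decoy_hits <- vapply(decoys, function(p) detect_turn(p, cl)$detected, NA)

  # single-word and short lexicon terms usable in slot templates
  slot_terms <- lexicon$entries

  with_private_seed(config$seed, {
    stratum_names <- names(config$strata)
    convs <- vector("list", config$n_conversations)
    truth <- vector("list", config$n_conversations)
    n_patients <- max(1L, round(config$n_conversations / 2))
    patient_ids <- sprintf("pt%03d", seq_len(n_patients))
    patient_stratum <- sample(stratum_names, n_patients, replace = TRUE,
                              prob = config$strata)
    for (i in seq_len(config$n_conversations)) {
      cid <- sprintf("conv%03d", i)
      pid <- patient_ids[((i - 1) %% n_patients) + 1]
      stratum <- patient_stratum[((i - 1) %% n_patients) + 1]
      c_eff <- config$colloquial_rate
      if (!is.null(config$stratum_colloquial_multiplier) &&
          stratum %in% names(config$stratum_colloquial_multiplier)) {
        c_eff <- min(1, c_eff *
                       config$stratum_colloquial_multiplier[[stratum]])
      }
      nt <- sample(seq(config$turns_per_conversation[1],
                       config$turns_per_conversation[2]), 1)
      is_pos <- runif(nt) < config$symptom_prevalence
      is_coll <- is_pos & runif(nt) < c_eff
      is_decoy <- !is_pos & runif(nt) < config$ambiguity_rate
      mech <- ifelse(is_pos, ifelse(is_coll, "colloquial", "lexical"),
                     ifelse(is_decoy, "decoy", "filler"))
      text <- character(nt)
      categ <- rep(NA_character_, nt)
      for (t in seq_len(nt)) {
        text[t] <- switch(
          mech[t],
          lexical = {
            j <- sample(nrow(slot_terms), 1)
            categ[t] <- slot_terms$categories[[j]][1]
            sprintf(sample(lexical_templates(), 1), slot_terms$term[j])
          },
          colloquial = {
            j <- sample(nrow(paraphrases), 1)
            categ[t] <- paraphrases$category[j]
            paraphrases$phrase[j]
          },
          decoy = sample(decoys, 1),
          filler = sample(filler_sentences(), 1))
      }
      speaker <- rep(c("clinician", "patient"), length.out = nt)
      speaker[mech %in% c("lexical", "colloquial") &
                runif(nt) < 0.7] <- "patient"
      md <- if (stratum == "missing") list() else list(race = stratum)
      convs[[i]] <- conversation(
        cid, pid,
        tibble::tibble(speaker_role = speaker, text = text),
        dataset_label = "user", metadata = md)
      truth[[i]] <- tibble::tibble(
        conversation_id = cid, turn_index = seq_len(nt) - 1L,
        positive = is_pos, mechanism = mech, category = categ)
    }
    truth <- dplyr::bind_rows(truth)

    # PRO-CTCAE relevance: colloquial positives fall outside the framework
    # with the configured probability; everything else keeps its label
    irrelevant <- truth$mechanism == "colloquial" &
      runif(nrow(truth)) < config$proctcae_irrelevant_rate
    truth$proctcae_relevant <- truth$positive & !irrelevant
    overrides <- tibble::tibble(
      conversation_id = truth$conversation_id[irrelevant],
      turn_index = truth$turn_index[irrelevant],
      proctcae_positive = FALSE,
      note = "outside PRO-CTCAE framework (synthetic)")

    base_score <- ifelse(truth$positive, 3L,
                         ifelse(truth$mechanism == "decoy", 1L, 0L))
    scores <- dplyr::bind_rows(lapply(seq_len(config$n_coders), function(cd) {
      s <- base_score
      flip <- runif(length(s)) < config$coder_noise
      s[flip] <- pmin(3L, pmax(0L, s[flip] +
                                 sample(c(-1L, 1L), sum(flip),
                                        replace = TRUE)))
      tibble::tibble(conversation_id = truth$conversation_id,
                     turn_index = truth$turn_index,
                     coder_id = sprintf("coder%02d", cd),
                     score = s)
    }))
  })

  structure(list(corpus = as_corpus(convs), truth = truth,
                 scores = scores, overrides = overrides,
                 decoy_hit_fraction = mean(decoy_hits),
                 config = config),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(
    "<synthetic_corpus>: %d conversations, %d turns (%.1f%% positive), seed %s\n",
    nrow(x$corpus$conversations), nrow(x$truth),
    100 * mean(x$truth$positive), format(x$config$seed)))
  print(table(x$truth$mechanism))
  invisible(x)
}

#' Expected detector performance under the generative model
#'
#' Closed-form expectation of the five metrics for a noiseless
#' (`coder_noise = 0`) synthetic corpus: lexical positives are always
#' detected, colloquial positives never, and false positives arise only
#' from decoys that overlap the lexicon. With prevalence `p`, colloquial
#' rate `c`, ambiguity rate `a` and decoy-overlap fraction `d`:
#' expected sensitivity is `1 - c` under the broad standard and
#' `(1-c)/(1-cq)` under the focused standard (where `q` is the
#' PRO-CTCAE-irrelevant rate), expected FP mass is `(1-p)·a·d` — zero, and
#' hence precision 1, for a decoy list disjoint from the lexicon.
#'
#' @param config a [generator_config()].
#' @param lexicon,decoys as passed to [generate_corpus()].
#' @param standard `"broad"` or `"proctcae"`.
#' @return a `metric_set` of expected values.
#' @export
expected_performance <- function(config,
                                 lexicon = seed_lexicon(),
                                 decoys = decoy_phrases(),
                                 standard = c("broad", "proctcae")) {
  standard <- match.arg(standard)
  if (!inherits(config, "generator_config")) {
    stop_validation("`config` must come from generator_config().")
  }
  cl <- compile_library(lexicon)
  d <- phrase_hit_fraction(decoys, cl)
  p <- config$symptom_prevalence
  cc <- config$colloquial_rate
  if (!is.null(config$stratum_colloquial_multiplier)) {
    mult <- vapply(names(config$strata), function(s) {
      m <- config$stratum_colloquial_multiplier[[s]]
      if (is.null(m)) 1 else m
    }, 0)
    cc <- min(1, sum(config$strata * pmin(1, cc * mult)))
  }
  a <- config$ambiguity_rate
  q <- config$proctcae_irrelevant_rate

  tp <- p * (1 - cc)
  fn <- if (standard == "broad") p * cc else p * cc * (1 - q)
  fp <- (1 - p) * a * d
  tn_base <- if (standard == "broad") 1 - p else 1 - p + p * cc * q
  tn <- tn_base - fp
  safe <- function(num, den) if (den <= 0) NA_real_ else num / den
  total <- tp + fp + tn + fn
  structure(list(
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    accuracy = safe(tp + tn, total),
    f1 = safe(2 * tp, 2 * tp + fp + fn)), class = "metric_set")
}

#' Write a synthetic corpus to disk
#'
#' Writes transcripts (YAML dialect), the coder-score file, the override
#' sidecar and the truth table into a directory, in the package's standard
#' formats.
#'
#' @param x a `synthetic_corpus`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(x, dir) {
  if (!inherits(x, "synthetic_corpus")) {
    stop_validation("`x` must be a synthetic_corpus.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(x$corpus, file.path(dir, "transcripts"))
  readr::write_csv(x$scores, file.path(dir, "annotations.csv"))
  readr::write_csv(x$overrides, file.path(dir, "overrides.csv"))
  readr::write_csv(x$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
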