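#' Extract symptom-positive turns
#'
#' The first step of the library-development loop: pull every turn labeled
#' positive under the chosen gold standard, so its vocabulary can be mined
#' for candidate terms.
#'
#' @param corpus a `symtalk_corpus`.
#' @param gold gold-label tibble covering the corpus.
#' @param standard `"broad"` or `"proctcae"`.
#' @return tibble of turns (`conversation_id`, `turn_index`,
#'   `speaker_role`, `text`) with a positive label.
#' @export
extract_positive_turns <- function(corpus, gold,
                                   standard = c("broad", "proctcae")) {
  standard <- match.arg(standard)
  gk <- turn_key(gold$conversation_id, gold$turn_index)
  tk <- turn_key(corpus$turns$conversation_id, corpus$turns$turn_index)
  pos <- (if (standard == "broad") gold$broad_positive else
    gold$proctcae_positive)[match(tk, gk)]
  corpus$turns[!is.na(pos) & pos, ]
}

#' Default stoplist for single-word candidates
#'
#' Function words excluded from single-word candidate enumeration. Phrases
#' are never stoplisted: a function word inside a phrase ("don't have the
#' appetite") can carry the symptom sense.
#'
#' @return character vector of lowercase words.
#' @export
default_stoplist <- function() {
  c("the", "a", "an", "and", "or", "but", "i", "you", "he", "she", "it",
    "we", "they", "is", "are", "was", "were", "be", "been", "being", "am",
    "do", "does", "did", "done", "have", "has", "had", "my", "your", "his",
    "her", "its", "our", "their", "me", "him", "them", "us", "to", "of",
    "in", "on", "at", "for", "with", "about", "from", "up", "down", "out",
    "as", "that", "this", "these", "those", "there", "here", "not", "no",
    "yes", "yeah", "so", "if", "then", "than", "just", "very", "really",
    "what", "when", "where", "who", "how", "why", "which", "can", "could",
    "will", "would", "should", "may", "might", "must", "going", "go",
    "get", "got", "know", "like", "well", "okay", "ok", "oh", "um", "uh",
    "right", "don't", "i'm", "it's", "you're", "that's", "he's", "she's",
    "we're", "they're", "all", "some", "any", "more", "now", "been")
}

#' Enumerate candidate terms from positive turns
#'
#' Counts every word and n-gram (up to `ngram_max` tokens) occurring in
#' symptom-positive turns, keeping those seen at least `min_freq` times
#' that are not already library terms and (for single words) not in the
#' stoplist. Each candidate carries up to `k_contexts` keyword-in-context
#' example lines for human triage, and starts in status `"pending"`.
#'
#' @param positive_turns tibble of turns (from
#'   [extract_positive_turns()]).
#' @param lib existing [keyword_library()]; its terms are not re-proposed.
#' @param ngram_max maximum phrase length in tokens (default 3).
#' @param min_freq minimum occurrence count (default 1: review everything).
#' @param stoplist words excluded as single-word candidates.
#' @param k_contexts example contexts to keep per candidate.
#' @return candidate tibble sorted by descending frequency then
#'   alphabetically: `surface`, `n` (tokens), `frequency`, `status`,
#'   `contexts` (list of KWIC tibbles).
#' @export
enumerate_candidates <- function(positive_turns, lib, ngram_max = 3,
                                 min_freq = 1,
                                 stoplist = default_stoplist(),
                                 k_contexts = 3) {
  validate_is_library(lib)
  if (ngram_max < 1) stop_validation("`ngram_max` must be >= 1.")
  tok_lists <- lapply(positive_turns$text,
                      function(x) tokenize_text(x)$token)
  grams <- list()
  for (toks in tok_lists) {
    nt <- length(toks)
    for (k in seq_len(min(ngram_max, nt))) {
      if (nt - k + 1 <= 0) next
      starts <- seq_len(nt - k + 1)
      surf <- vapply(starts, function(s) {
        paste(toks[s:(s + k - 1)], collapse = " ")
      }, "")
      grams[[length(grams) + 1]] <- surf
    }
  }
  if (length(grams) == 0) {
    return(tibble::tibble(surface = character(), n = integer(),
                          frequency = integer(), status = character(),
                          contexts = list()))
  }
  counts <- table(unlist(grams))
  cand <- tibble::tibble(surface = names(counts),
                         frequency = as.integer(counts))
  cand$n <- lengths(strsplit(cand$surface, " ", fixed = TRUE))
  cand <- cand[cand$frequency >= min_freq, ]
  cand <- cand[!(cand$n == 1 & cand$surface %in% stoplist), ]
  cand <- cand[!cand$surface %in% lib$entries$term, ]
  cand <- cand[order(-cand$frequency, cand$surface), ]
  mini <- structure(list(turns = positive_turns), class = "symtalk_corpus")
  cand$status <- "pending"
  cand$contexts <- lapply(cand$surface, function(s) {
    head(kwic(mini, s, window = 5), k_contexts)
  })
  cand[, c("surface", "n", "frequency", "status", "contexts")]
}

#' Apply triage decisions to grow a library
#'
#' Candidate terms are triaged by humans; decisions are recorded in an
#' append-only log so disagreement resolution and the resulting library
#' version stay auditable. Replaying a log is idempotent: candidates
#' already in the library are skipped silently.
#'
#' @param candidates candidate tibble from [enumerate_candidates()].
#' @param log decision tibble with columns `surface`, `status`
#'   (`"included"`/`"excluded"`), `categories` (`;`-joined, required for
#'   inclusions), and optional `rationale`, `decider`.
#' @param lib the [keyword_library()] being grown.
#' @param new_version_label version label for the result (default: keep
#'   `lib`'s label).
#' @return the grown `keyword_library`; included candidates are added with
#'   `source = "user"`, exclusions leave the library unchanged.
#' @export
apply_triage <- function(candidates, log, lib, new_version_label = NULL) {
  validate_is_library(lib)
  log <- tibble::as_tibble(log)
  if (nrow(log) == 0) return(lib)
  if (!all(c("surface", "status") %in% names(log))) {
    stop_validation("Triage log needs columns surface and status.")
  }
  unknown <- setdiff(log$surface, candidates$surface)
  if (length(unknown)) {
    stop_validation("Triage decision(s) for unknown candidate(s): %s.",
                    toString(head(unknown, 5)))
  }
  bad_status <- setdiff(unique(log$status), c("included", "excluded"))
  if (length(bad_status)) {
    stop_validation("Triage status must be included/excluded, got: %s.",
                    toString(bad_status))
  }
  # the last decision for a surface wins (append-only log, replayed in order)
  final <- log[!duplicated(log$surface, fromLast = TRUE), ]
  inc <- final[final$status == "included", ]
  if (nrow(inc) == 0) return(lib)
  cats <- inc[["categories"]] %||% rep(NA_character_, nrow(inc))
  if (any(is.na(cats) | !nzchar(cats))) {
    stop_validation("Included candidate(s) without categories: %s.",
                    toString(inc$surface[is.na(cats) | !nzchar(cats)]))
  }
  new_terms <- !inc$surface %in% lib$entries$term
  if (!any(new_terms)) return(lib)
  keyword_library(
    dplyr::bind_rows(
      lib$entries,
      tibble::tibble(term = inc$surface[new_terms],
                     categories = strsplit(cats[new_terms], ";",
                                           fixed = TRUE),
                     source = "user")),
    lib$exclusions,
    version_label = new_version_label %||% lib$version_label,
    category_vocabulary = lib$category_vocabulary)
}
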