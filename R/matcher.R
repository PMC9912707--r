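# Precompile a library for matching: each term and exclusion phrase becomes
# its token sequence, indexed by first token for fast candidate lookup.
compile_library <- function(lib) {
  validate_is_library(lib)
  term_tokens <- lapply(lib$entries$term, function(t) tokenize_text(t)$token)
  if (any(lengths(term_tokens) == 0)) {
    stop_validation("Library term(s) tokenize to nothing: %s.",
                    toString(lib$entries$term[lengths(term_tokens) == 0]))
  }
  excl_tokens <- lapply(lib$exclusions$phrase,
                        function(t) tokenize_text(t)$token)
  structure(list(lib = lib, term_tokens = term_tokens,
                 excl_tokens = excl_tokens),
            class = "compiled_library")
}

# all start positions where the token sequence `needle` occurs in `tokens`
seq_positions <- function(tokens, needle) {
  n <- length(tokens)
  k <- length(needle)
  if (k == 0 || k > n) return(integer())
  cand <- which(tokens == needle[1])
  cand <- cand[cand + k - 1L <= n]
  if (k == 1 || length(cand) == 0) return(cand)
  keep <- vapply(cand, function(i) {
    all(tokens[i:(i + k - 1L)] == needle)
  }, NA)
  cand[keep]
}

#' Detect symptom talk in one turn
#'
#' The unit of detection is the speaker turn. Every library term is
#' searched in the turn's token sequence: a single-word term matches any
#' equal token, a multi-word phrase matches a contiguous token sequence
#' equal to its word sequence; matching is case-insensitive and at token
#' boundaries only ("red" never matches inside "bothered"). A candidate
#' match fully contained within an occurrence of an exclusion pattern is
#' suppressed and reported separately. The turn is `detected` iff at least
#' one unsuppressed match remains. Terms are literal: no regular
#' expressions, stemming or fuzzy matching.
#'
#' @param text the turn's text (a single string).
#' @param lib a [keyword_library()], or a precompiled library from the
#'   internal compiler (used by [detect_corpus()] to avoid recompiling).
#' @return list of class `detection` with elements `detected` (logical),
#'   `matches` (tibble `term`, `start`, `end`, `categories` list-column)
#'   and `suppressed` (the same plus `exclusion`). Spans are 1-based
#'   inclusive character positions into the normalized turn text.
#' @examples
#' detect_turn("Do you need any more Ativan?", seed_lexicon())
#' @export
detect_turn <- function(text, lib) {
  cl <- if (inherits(lib, "compiled_library")) lib else compile_library(lib)
  toks <- tokenize_text(text)
  empty <- tibble::tibble(term = character(), start = integer(),
                          end = integer(), categories = list())
  if (nrow(toks) == 0) {
    return(structure(list(detected = FALSE, matches = empty,
                          suppressed = dplyr::mutate(
                            empty, exclusion = character())),
                     class = "detection"))
  }
  hits <- list()
  for (i in seq_along(cl$term_tokens)) {
    pos <- seq_positions(toks$token, cl$term_tokens[[i]])
    if (length(pos)) {
      k <- length(cl$term_tokens[[i]])
      hits[[length(hits) + 1]] <- tibble::tibble(
        term = cl$lib$entries$term[i],
        start = toks$start[pos],
        end = toks$end[pos + k - 1L],
        categories = rep(cl$lib$entries$categories[i], length(pos)))
    }
  }
  matches <- if (length(hits)) dplyr::bind_rows(hits) else empty

  excl_spans <- list()
  for (j in seq_along(cl$excl_tokens)) {
    pos <- seq_positions(toks$token, cl$excl_tokens[[j]])
    if (length(pos)) {
      k <- length(cl$excl_tokens[[j]])
      excl_spans[[length(excl_spans) + 1]] <- tibble::tibble(
        exclusion = cl$lib$exclusions$phrase[j],
        start = toks$start[pos],
        end = toks$end[pos + k - 1L])
    }
  }
  suppressed <- dplyr::mutate(empty, exclusion = character())
  if (length(excl_spans) && nrow(matches)) {
    ex <- dplyr::bind_rows(excl_spans)
    sup_by <- rep(NA_character_, nrow(matches))
    for (r in seq_len(nrow(ex))) {
      inside <- matches$start >= ex$start[r] & matches$end <= ex$end[r]
      sup_by[inside & is.na(sup_by)] <- ex$exclusion[r]
    }
    suppressed <- dplyr::mutate(matches[!is.na(sup_by), ],
                                exclusion = sup_by[!is.na(sup_by)])
    matches <- matches[is.na(sup_by), ]
  }
  matches <- matches[order(matches$start, matches$end, matches$term), ]
  structure(list(detected = nrow(matches) > 0, matches = matches,
                 suppressed = suppressed),
            class = "detection")
}

#' @export
print.detection <- function(x, ...) {
  cat(sprintf("<detection>: %s (%d match(es), %d suppressed)\n",
              if (x$detected) "symptom talk" else "no symptom talk",
              nrow(x$matches), nrow(x$suppressed)))
  if (nrow(x$matches)) {
    cat(paste0("  ", x$matches$term, " [",
               vapply(x$matches$categories, paste, "", collapse = ";"),
               "]", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Detect symptom talk across a corpus
#'
#' Runs [detect_turn()] on every turn of every conversation and returns one
#' row per turn, in corpus order. Deterministic: identical inputs always
#' yield identical output.
#'
#' @param corpus a `symtalk_corpus`.
#' @param lib a [keyword_library()].
#' @return tibble with columns `conversation_id`, `turn_index`, `detected`,
#'   `terms` (list of matched terms), `categories` (list of the union of
#'   matched categories), `n_matches`, `n_suppressed`.
#' @export
detect_corpus <- function(corpus, lib) {
  cl <- compile_library(lib)
  res <- lapply(corpus$turns$text, detect_turn, lib = cl)
  tibble::tibble(
    conversation_id = corpus$turns$conversation_id,
    turn_index = corpus$turns$turn_index,
    detected = vapply(res, `[[`, NA, "detected"),
    terms = lapply(res, function(r) r$matches$term),
    categories = lapply(res, function(r)
      sort(unique(unlist(r$matches$categories)))),
    n_matches = vapply(res, function(r) nrow(r$matches), 0L),
    n_suppressed = vapply(res, function(r) nrow(r$suppressed), 0L))
}

#' Keyword-in-context concordance
#'
#' Shows every occurrence of a term with up to `window` tokens of context
#' on each side, truncated at turn boundaries (context never crosses
#' turns). The standard view for human triage of candidate terms.
#'
#' @param corpus a `symtalk_corpus`.
#' @param term word or phrase to look up (matched like a library term:
#'   case-insensitive, token boundaries).
#' @param window maximum context tokens per side (>= 0).
#' @return tibble with columns `conversation_id`, `turn_index`, `left`,
#'   `keyword`, `right`; zero rows if the term never occurs.
#' @export
kwic <- function(corpus, term, window = 5) {
  if (window < 0) stop_validation("`window` must be >= 0.")
  needle <- tokenize_text(term)$token
  if (length(needle) == 0) stop_validation("Empty query term.")
  out <- list()
  for (i in seq_len(nrow(corpus$turns))) {
    toks <- tokenize_text(corpus$turns$text[i])
    pos <- seq_positions(toks$token, needle)
    for (p in pos) {
      lo <- max(1L, p - window)
      hi <- min(nrow(toks), p + length(needle) - 1L + window)
      out[[length(out) + 1]] <- tibble::tibble(
        conversation_id = corpus$turns$conversation_id[i],
        turn_index = corpus$turns$turn_index[i],
        left = if (window == 0 || p == 1) "" else
          paste(toks$token[lo:(p - 1L)], collapse = " "),
        keyword = paste(toks$token[p:(p + length(needle) - 1L)],
                        collapse = " "),
        right = if (window == 0 || p + length(needle) - 1L == nrow(toks)) ""
          else paste(toks$token[(p + length(needle)):hi], collapse = " "))
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(conversation_id = character(), turn_index = integer(),
                   left = character(), keyword = character(),
                   right = character())
}
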