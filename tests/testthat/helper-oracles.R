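# Independent brute-force oracles used to check package implementations.
# These deliberately share no code with the package internals.

# Exhaustive window-scan detector: every token window of every length is
# compared against every library term; exclusion occurrences are found the
# same way and any match whose character span lies inside one is dropped.
oracle_detect <- function(text, lib) {
  norm <- tolower(chartr("‘’“”", "''\"\"", text))
  m <- gregexpr("[[:alnum:]]+(?:['-][[:alnum:]]+)*", norm, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(list(detected = FALSE,
                matches = data.frame(term = character(),
                                     start = integer(), end = integer())))
  }
  tok <- substring(norm, m, m + attr(m, "match.length") - 1L)
  tok_start <- as.integer(m)
  tok_end <- tok_start + attr(m, "match.length") - 1L
  find_all <- function(phrase) {
    words <- strsplit(tolower(phrase), "[^[:alnum:]'-]+")[[1]]
    words <- words[nzchar(words)]
    k <- length(words)
    hits <- data.frame(start = integer(), end = integer())
    if (k == 0 || k > length(tok)) return(hits)
    for (s in 1:(length(tok) - k + 1)) {
      if (all(tok[s:(s + k - 1)] == words)) {
        hits <- rbind(hits, data.frame(start = tok_start[s],
                                       end = tok_end[s + k - 1]))
      }
    }
    hits
  }
  matches <- do.call(rbind, c(list(
    data.frame(term = character(), start = integer(), end = integer())),
    lapply(lib$entries$term, function(tm) {
      h <- find_all(tm)
      if (nrow(h)) cbind(term = tm, h) else NULL
    })))
  excl <- do.call(rbind, c(list(data.frame(start = integer(),
                                           end = integer())),
                           lapply(lib$exclusions$phrase, find_all)))
  if (nrow(matches) && nrow(excl)) {
    keep <- vapply(seq_len(nrow(matches)), function(i) {
      !any(matches$start[i] >= excl$start & matches$end[i] <= excl$end)
    }, NA)
    matches <- matches[keep, ]
  }
  matches <- matches[order(matches$start, matches$end, matches$term), ]
  rownames(matches) <- NULL
  list(detected = nrow(matches) > 0, matches = matches)
}

match_set <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(paste(df$term, df$start, df$end))
}

# Brute-force n-gram occurrence counter over a set of texts.
oracle_ngram_counts <- function(texts, ngram_max) {
  out <- character()
  for (tx in texts) {
    norm <- tolower(tx)
    words <- strsplit(norm, "[^[:alnum:]'-]+")[[1]]
    words <- words[nzchar(words)]
    for (k in seq_len(ngram_max)) {
      if (length(words) < k) next
      for (s in 1:(length(words) - k + 1)) {
        out <- c(out, paste(words[s:(s + k - 1)], collapse = " "))
      }
    }
  }
  table(out)
}

# Fleiss kappa from the closed form, written independently: overall
# agreement is the mean over items of the proportion of agreeing rater
# pairs; chance agreement is the sum of squared marginal proportions.
oracle_fleiss <- function(counts) {
  n <- rowSums(counts)[1]
  N <- nrow(counts)
  agree_pairs <- apply(counts, 1, function(r) sum(choose(r, 2)))
  p_obs <- mean(agree_pairs / choose(n, 2))
  marg <- colSums(counts) / sum(counts)
  p_chance <- sum(marg^2)
  (p_obs - p_chance) / (1 - p_chance)
}

# Random fixtures -------------------------------------------------------

random_library <- function(vocab, n_terms, n_excl = 0,
                           categories = default_categories()) {
  mk_phrase <- function() {
    paste(sample(vocab, sample(1:3, 1), replace = TRUE), collapse = " ")
  }
  terms <- unique(replicate(n_terms, mk_phrase()))
  excl <- if (n_excl > 0) {
    setdiff(unique(replicate(n_excl, mk_phrase())), terms)
  } else character()
  keyword_library(
    tibble::tibble(term = terms,
                   categories = replicate(length(terms),
                                          sample(categories, 1),
                                          simplify = FALSE)),
    exclusions = if (length(excl)) tibble::tibble(phrase = excl) else NULL)
}

random_sentence <- function(vocab, n_tokens) {
  paste(sample(vocab, n_tokens, replace = TRUE), collapse = " ")
}

tiny_corpus <- function(texts, ids = NULL, patient_ids = NULL,
                        dataset_label = "user") {
  ids <- ids %||% sprintf("c%02d", seq_along(texts))
  patient_ids <- patient_ids %||% rep("p1", length(texts))
  as_corpus(purrr::map(seq_along(texts), function(i) {
    conversation(ids[i], patient_ids[i],
                 tibble::tibble(speaker_role = "patient",
                                text = texts[[i]]),
                 dataset_label = dataset_label)
  }))
}

`%||%` <- rlang::`%||%`

conversation_strata_for_test <- function(corpus, key) {
  symtalk:::conversation_strata(corpus, key)
}
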