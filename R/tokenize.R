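#' Normalize turn text
#'
#' Lowercases and maps typographic (Unicode) apostrophes and quotation
#' marks to their ASCII forms. The mapping is one character to one
#' character, so character positions in the normalized text line up exactly
#' with the original.
#'
#' @param text character vector.
#' @return normalized character vector of the same lengths.
#' @export
normalize_text <- function(text) {
  chartr("‘’‚‛“”„‟",
         "''''\"\"\"\"", tolower(text))
}

#' Tokenize turn text with character spans
#'
#' Tokens are maximal runs of letters and digits, with internal apostrophes
#' and hyphens kept token-internal ("don't", "schedule-wise"), over the
#' normalized text. Spans are 1-based inclusive `[start, end]` character
#' positions — the R string convention — and because normalization is
#' positionally exact, `substr(normalize_text(text), start, end)`
#' reproduces each token.
#'
#' @param text a single character string (a turn's text).
#' @return tibble with columns `token`, `start`, `end`; zero rows for empty
#'   or token-free text.
#' @examples
#' tokenize_text("Don’t worry.")
#' @export
tokenize_text <- function(text) {
  stopifnot(length(text) == 1)
  norm <- normalize_text(text)
  if (is.na(norm) || !nzchar(norm)) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  m <- gregexpr("[[:alnum:]]+(?:['-][[:alnum:]]+)*", norm, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(),
                          end = integer()))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  tibble::tibble(token = substring(norm, start, start + len - 1L),
                 start = start, end = start + len - 1L)
}
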