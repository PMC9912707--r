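#' PRO-CTCAE symptom category vocabulary
#'
#' The default category identifiers a keyword library may use. They are the
#' system-level groupings of the PRO-CTCAE framework's clinically relevant
#' symptoms: pain, gastrointestinal, sleep/wake, neurological, cutaneous,
#' mood/anxiety, respiratory, oral, sexual, and a residual "other" class.
#' Categories are nonexclusive: an entry may carry several.
#'
#' @return character vector of category identifiers.
#' @examples
#' default_categories()
#' @export
default_categories <- function() {
  c("pain", "gi", "sleep_wake", "neurological", "cutaneous",
    "mood_anxiety", "respiratory", "oral", "sexual", "other")
}

entry_sources <- function() {
  c("development-corpus", "a-priori", "validation-adjustment", "user")
}

#' Construct a keyword library
#'
#' A keyword library is the unit of rule-based symptom detection: a set of
#' literal lowercase terms (single words or multi-word phrases), each sorted
#' into one or more symptom categories and carrying provenance flags, plus a
#' set of exclusion patterns — phrases whose occurrence suppresses any
#' keyword match fully contained inside them (e.g. the physical-exam
#' instruction "deep breaths" suppressing breath-related symptom terms).
#'
#' Terms are literal strings, not regular expressions; morphological
#' variants (plurals, -ing forms) are separate explicit entries, which keeps
#' matching behaviour auditable. Terms are normalized to squished lowercase;
#' duplicate terms are collapsed to a single entry with the union of their
#' categories (categories are nonexclusive), with a warning.
#'
#' @param entries data frame with columns `term` (non-empty text),
#'   `categories` (list of character vectors, or a single `;`-separated
#'   string per row), and optionally `is_medication`,
#'   `is_clinician_authored`, `is_symptom_specific` (logical, default
#'   `FALSE`) and `source` (one of `"development-corpus"`, `"a-priori"`,
#'   `"validation-adjustment"`, `"user"`; default `"user"`).
#' @param exclusions data frame with columns `phrase` and optionally
#'   `rationale`, or `NULL` for none.
#' @param version_label free-text version tag for the library.
#' @param category_vocabulary allowed category identifiers; every entry's
#'   categories must be a subset.
#' @return an object of class `keyword_library`.
#' @examples
#' lib <- keyword_library(
#'   tibble::tibble(term = c("nausea", "ativan"),
#'                  categories = list("gi", "mood_anxiety"),
#'                  is_medication = c(FALSE, TRUE)),
#'   exclusions = tibble::tibble(phrase = "deep breaths"))
#' lib
#' @export
keyword_library <- function(entries,
                            exclusions = NULL,
                            version_label = "unversioned",
                            category_vocabulary = default_categories()) {
  if (is.null(entries) || nrow(as.data.frame(entries)) == 0) {
    stop_validation("A keyword library must contain at least one entry.")
  }
  entries <- tibble::as_tibble(entries)
  if (!all(c("term", "categories") %in% names(entries))) {
    stop_validation("`entries` needs columns `term` and `categories`.")
  }
  if (is.character(entries$categories)) {
    entries$categories <- strsplit(entries$categories, ";", fixed = TRUE)
  }
  entries$categories <- lapply(entries$categories,
                               function(x) sort(unique(trimws(x))))
  for (flag in c("is_medication", "is_clinician_authored",
                 "is_symptom_specific")) {
    if (is.null(entries[[flag]])) entries[[flag]] <- FALSE
    entries[[flag]] <- as.logical(entries[[flag]]) %|na|% FALSE
  }
  if (is.null(entries[["source"]])) entries$source <- "user"
  entries$term <- stringr::str_squish(tolower(as.character(entries$term)))

  if (any(!nzchar(entries$term))) {
    stop_validation("Library terms must be non-empty text.")
  }
  bad_src <- setdiff(unique(entries$source), entry_sources())
  if (length(bad_src)) {
    stop_validation("Unknown entry source(s): %s. Allowed: %s.",
                    toString(bad_src), toString(entry_sources()))
  }
  cats <- unique(unlist(entries$categories))
  if (length(cats) == 0 || any(lengths(entries$categories) == 0)) {
    stop_validation("Every entry needs at least one category.")
  }
  unknown <- setdiff(cats, category_vocabulary)
  if (length(unknown)) {
    stop_validation("Unknown categor%s: %s. Allowed vocabulary: %s.",
                    if (length(unknown) > 1) "ies" else "y",
                    toString(unknown), toString(category_vocabulary))
  }

  if (anyDuplicated(entries$term)) {
    dups <- unique(entries$term[duplicated(entries$term)])
    warn(sprintf(
      "Duplicate term(s) collapsed with union of categories: %s.",
      toString(dups)))
    entries <- entries |>
      dplyr::group_by(.data$term) |>
      dplyr::summarise(
        categories = list(sort(unique(unlist(.data$categories)))),
        is_medication = any(.data$is_medication),
        is_clinician_authored = any(.data$is_clinician_authored),
        is_symptom_specific = any(.data$is_symptom_specific),
        source = .data$source[1],
        .groups = "drop")
  }
  entries <- entries[order(entries$term),
                     c("term", "categories", "is_medication",
                       "is_clinician_authored", "is_symptom_specific",
                       "source")]

  if (is.null(exclusions) || nrow(as.data.frame(exclusions)) == 0) {
    exclusions <- tibble::tibble(phrase = character(),
                                 rationale = character())
  } else {
    exclusions <- tibble::as_tibble(exclusions)
    if (is.null(exclusions[["rationale"]])) exclusions$rationale <- ""
    exclusions$phrase <-
      stringr::str_squish(tolower(as.character(exclusions$phrase)))
    if (any(!nzchar(exclusions$phrase))) {
      stop_validation("Exclusion phrases must be non-empty text.")
    }
    exclusions <- exclusions[!duplicated(exclusions$phrase),
                             c("phrase", "rationale")]
    exclusions <- exclusions[order(exclusions$phrase), ]
  }

  structure(
    list(entries = entries, exclusions = exclusions,
         version_label = as.character(version_label),
         category_vocabulary = category_vocabulary),
    class = "keyword_library")
}

#' Validate a keyword library
#'
#' Re-runs all construction-time invariants (unique lowercase terms,
#' categories within the vocabulary, valid sources) on an existing object.
#'
#' @param lib a `keyword_library`.
#' @return `lib`, invisibly; errors describe the first violated invariant.
#' @export
validate_library <- function(lib) {
  if (!inherits(lib, "keyword_library")) {
    stop_validation("Not a keyword_library object.")
  }
  keyword_library(lib$entries, lib$exclusions, lib$version_label,
                  lib$category_vocabulary)
  invisible(lib)
}

#' @export
print.keyword_library <- function(x, ...) {
  cat(sprintf(
    "<keyword_library '%s'>: %d terms, %d exclusions, %d categories in use\n",
    x$version_label, nrow(x$entries), nrow(x$exclusions),
    length(unique(unlist(x$entries$categories)))))
  n_med <- sum(x$entries$is_medication)
  if (n_med) cat(sprintf("  medication terms: %d\n", n_med))
  invisible(x)
}

#' Number of terms in a keyword library
#' @param lib a `keyword_library`.
#' @return integer term count (exclusions are not terms).
#' @export
term_count <- function(lib) {
  validate_is_library(lib)
  nrow(lib$entries)
}

validate_is_library <- function(lib) {
  if (!inherits(lib, "keyword_library")) {
    stop_validation("Expected a keyword_library object.")
  }
  invisible(lib)
}

#' Drop flagged entries from a library
#'
#' Library reusers in a new setting may wish to omit medication names,
#' clinician-authored language, or symptom-specific terms; each entry
#' carries those provenance flags so they can be filtered wholesale.
#' Exclusion patterns are left unchanged.
#'
#' @param lib a `keyword_library`.
#' @param drop_medication,drop_clinician_authored,drop_symptom_specific
#'   drop entries carrying the corresponding flag.
#' @return the filtered `keyword_library`; an error if nothing survives.
#' @export
filter_library <- function(lib,
                           drop_medication = FALSE,
                           drop_clinician_authored = FALSE,
                           drop_symptom_specific = FALSE) {
  validate_is_library(lib)
  keep <- rep(TRUE, nrow(lib$entries))
  if (drop_medication) keep <- keep & !lib$entries$is_medication
  if (drop_clinician_authored) keep <- keep & !lib$entries$is_clinician_authored
  if (drop_symptom_specific) keep <- keep & !lib$entries$is_symptom_specific
  if (!any(keep)) {
    stop_validation("Filtering removed every entry; a library must keep >= 1.")
  }
  keyword_library(lib$entries[keep, ], lib$exclusions, lib$version_label,
                  lib$category_vocabulary)
}
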