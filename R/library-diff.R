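#' Diff two keyword-library versions
#'
#' Library development is iterative: a draft is validated against annotated
#' conversations, misclassifications are screened, and adjustments are
#' applied for the next version. `diff_libraries()` captures one such step
#' as an auditable object: terms added, terms removed, terms whose category
#' sets changed (with otherwise identical flags), and exclusion patterns
#' added or removed. [apply_library_diff()] replays it exactly:
#' `apply_library_diff(a, diff_libraries(a, b))` equals `b`.
#'
#' An entry whose flags or source changed between versions is recorded as a
#' removal plus an addition, so the term-count arithmetic
#' `term_count(b) == term_count(a) + nrow(added) - nrow(removed)` always
#' holds.
#'
#' @param a,b `keyword_library` objects (old and new version).
#' @return an object of class `library_diff` with elements `added`,
#'   `removed`, `recategorized` (term, old and new categories),
#'   `exclusions_added`, `exclusions_removed`, and the target
#'   `version_label`.
#' @export
diff_libraries <- function(a, b) {
  validate_is_library(a)
  validate_is_library(b)
  ea <- a$entries
  eb <- b$entries
  shared <- intersect(ea$term, eb$term)
  ia <- match(shared, ea$term)
  ib <- match(shared, eb$term)
  flags_equal <- ea$is_medication[ia] == eb$is_medication[ib] &
    ea$is_clinician_authored[ia] == eb$is_clinician_authored[ib] &
    ea$is_symptom_specific[ia] == eb$is_symptom_specific[ib] &
    ea$source[ia] == eb$source[ib]
  cats_equal <- mapply(identical, ea$categories[ia], eb$categories[ib])
  recat <- flags_equal & !cats_equal
  changed <- !flags_equal

  removed_terms <- c(setdiff(ea$term, eb$term), shared[changed])
  added_terms <- c(setdiff(eb$term, ea$term), shared[changed])
  structure(list(
    added = eb[match(sort(added_terms), eb$term), ],
    removed = ea[match(sort(removed_terms), ea$term), ],
    recategorized = tibble::tibble(
      term = shared[recat],
      old_categories = ea$categories[ia][recat],
      new_categories = eb$categories[ib][recat]),
    exclusions_added =
      b$exclusions[!b$exclusions$phrase %in% a$exclusions$phrase, ],
    exclusions_removed =
      a$exclusions[!a$exclusions$phrase %in% b$exclusions$phrase, ],
    version_label = b$version_label),
    class = "library_diff")
}

#' @export
print.library_diff <- function(x, ...) {
  cat(sprintf(
    "<library_diff -> '%s'>: +%d terms, -%d terms, %d recategorized, +%d/-%d exclusions\n",
    x$version_label, nrow(x$added), nrow(x$removed), nrow(x$recategorized),
    nrow(x$exclusions_added), nrow(x$exclusions_removed)))
  invisible(x)
}

#' Apply a library diff
#'
#' @param a the `keyword_library` the diff was computed from.
#' @param diff a `library_diff`.
#' @return the updated `keyword_library`.
#' @rdname diff_libraries
#' @export
apply_library_diff <- function(a, diff) {
  validate_is_library(a)
  if (!inherits(diff, "library_diff")) {
    stop_validation("`diff` must be a library_diff object.")
  }
  entries <- a$entries[!a$entries$term %in% diff$removed$term, ]
  entries <- dplyr::bind_rows(entries, diff$added)
  if (nrow(diff$recategorized)) {
    idx <- match(diff$recategorized$term, entries$term)
    if (anyNA(idx)) {
      stop_validation("Recategorized term(s) absent from library: %s.",
                      toString(diff$recategorized$term[is.na(idx)]))
    }
    entries$categories[idx] <- diff$recategorized$new_categories
  }
  exclusions <- a$exclusions[
    !a$exclusions$phrase %in% diff$exclusions_removed$phrase, ]
  exclusions <- dplyr::bind_rows(exclusions, diff$exclusions_added)
  keyword_library(entries, exclusions,
                  version_label = diff$version_label,
                  category_vocabulary = a$category_vocabulary)
}
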