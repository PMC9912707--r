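cat_join <- function(x) vapply(x, paste, "", collapse = ";")

#' Read a keyword library from disk
#'
#' Two dialects are supported. The tabular dialect (`"csv"`) is a UTF-8
#' comma-separated file with a header row and columns `type`
#' (`keyword`/`exclusion`), `term`, `categories` (semicolon-joined),
#' `is_medication`, `is_clinician_authored`, `is_symptom_specific`,
#' `source`, `rationale`; leading `#`-comment lines may carry
#' `version_label` and `category_vocabulary` metadata. The structured-text
#' dialect (`"yaml"`) is a YAML document with the same fields. Format is
#' inferred from the file extension when `format = "auto"`.
#'
#' Duplicate terms are collapsed to one entry with the union of their
#' categories (with a warning); a file that yields zero entries is an
#' error, as is an unknown category or a malformed row.
#'
#' @param path file to read.
#' @param format `"auto"`, `"csv"` or `"yaml"`.
#' @return a [keyword_library()].
#' @seealso [write_keyword_library()] for the round-trip guarantee.
#' @export
read_keyword_library <- function(path, format = c("auto", "csv", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("Library file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "csv"
  }
  if (format == "yaml") {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$entries) || length(doc$entries) == 0) {
      stop_validation("Library file %s contains no entries.", path)
    }
    entries <- dplyr::bind_rows(lapply(doc$entries, function(e) {
      tibble::tibble(
        term = e$term %||% NA_character_,
        categories = list(unlist(e$categories)),
        is_medication = isTRUE(e$is_medication),
        is_clinician_authored = isTRUE(e$is_clinician_authored),
        is_symptom_specific = isTRUE(e$is_symptom_specific),
        source = e$source %||% "user")
    }))
    exclusions <- if (length(doc$exclusions)) {
      dplyr::bind_rows(lapply(doc$exclusions, function(e) {
        tibble::tibble(phrase = e$phrase %||% NA_character_,
                       rationale = e$rationale %||% "")
      }))
    } else NULL
    if (anyNA(entries$term)) {
      stop_validation("Library file %s: entry %d lacks a term.",
                      path, which(is.na(entries$term))[1])
    }
    return(keyword_library(
      entries, exclusions,
      version_label = doc$version_label %||% "unversioned",
      category_vocabulary = unlist(doc$category_vocabulary) %||%
        default_categories()))
  }

  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_meta(meta_lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) <= 1) {
    stop_validation("Library file %s contains no entries.", path)
  }
  tab <- readr::read_csv(I(paste(body, collapse = "\n")),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("term", "categories") %in% names(tab))) {
    stop_validation("Library file %s lacks required columns term, categories.",
                    path)
  }
  if (anyNA(tab$term)) {
    # +1 for the header row; comment lines precede the body in our writer
    bad <- which(is.na(tab$term))[1]
    stop_validation("Library file %s: malformed row at data line %d (no term).",
                    path, bad)
  }
  col_or <- function(name, default) {
    (tab[[name]] %||% rep(default, nrow(tab))) %|na|% default
  }
  tab$type <- col_or("type", "keyword")
  ex_rows <- tab$type == "exclusion"
  flags <- function(x) !is.na(x) & tolower(x) %in% c("true", "t", "1", "yes")
  entries <- tibble::tibble(
    term = tab$term[!ex_rows],
    categories = strsplit(col_or("categories", "")[!ex_rows], ";",
                          fixed = TRUE),
    is_medication = flags(col_or("is_medication", "false")[!ex_rows]),
    is_clinician_authored =
      flags(col_or("is_clinician_authored", "false")[!ex_rows]),
    is_symptom_specific =
      flags(col_or("is_symptom_specific", "false")[!ex_rows]),
    source = col_or("source", "user")[!ex_rows])
  exclusions <- if (any(ex_rows)) {
    tibble::tibble(phrase = tab$term[ex_rows],
                   rationale = col_or("rationale", "")[ex_rows])
  } else NULL
  vocab <- meta$category_vocabulary %||% default_categories()
  lib <- keyword_library(entries, exclusions,
                         version_label = meta$version_label %||% "unversioned",
                         category_vocabulary = vocab)
  message(sprintf("Loaded keyword library '%s': %d terms, %d exclusions.",
                  lib$version_label, term_count(lib), nrow(lib$exclusions)))
  lib
}

parse_meta <- function(meta_lines) {
  out <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) {
      key <- m[2]
      val <- trimws(m[3])
      out[[key]] <- if (key == "category_vocabulary") {
        trimws(strsplit(val, ";", fixed = TRUE)[[1]])
      } else val
    }
  }
  out
}

#' Write a keyword library to disk
#'
#' Inverse of [read_keyword_library()]: `read(write(lib))` reproduces the
#' library field-for-field (terms, category sets, flags, exclusions,
#' version label, vocabulary).
#'
#' @param lib a `keyword_library`.
#' @param path destination file.
#' @param format `"auto"` (from extension), `"csv"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_keyword_library <- function(lib, path,
                                  format = c("auto", "csv", "yaml")) {
  validate_is_library(lib)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) "yaml" else "csv"
  }
  if (format == "yaml") {
    doc <- list(
      version_label = lib$version_label,
      category_vocabulary = as.list(lib$category_vocabulary),
      entries = lapply(seq_len(nrow(lib$entries)), function(i) {
        e <- lib$entries[i, ]
        list(term = e$term, categories = as.list(e$categories[[1]]),
             is_medication = e$is_medication,
             is_clinician_authored = e$is_clinician_authored,
             is_symptom_specific = e$is_symptom_specific,
             source = e$source)
      }),
      exclusions = lapply(seq_len(nrow(lib$exclusions)), function(i) {
        list(phrase = lib$exclusions$phrase[i],
             rationale = lib$exclusions$rationale[i])
      }))
    yaml::write_yaml(doc, path)
    return(invisible(path))
  }
  tab <- tibble::tibble(
    type = c(rep("keyword", nrow(lib$entries)),
             rep("exclusion", nrow(lib$exclusions))),
    term = c(lib$entries$term, lib$exclusions$phrase),
    categories = c(cat_join(lib$entries$categories),
                   rep("", nrow(lib$exclusions))),
    is_medication = c(lib$entries$is_medication,
                      rep(FALSE, nrow(lib$exclusions))),
    is_clinician_authored = c(lib$entries$is_clinician_authored,
                              rep(FALSE, nrow(lib$exclusions))),
    is_symptom_specific = c(lib$entries$is_symptom_specific,
                            rep(FALSE, nrow(lib$exclusions))),
    source = c(lib$entries$source, rep("", nrow(lib$exclusions))),
    rationale = c(rep("", nrow(lib$entries)), lib$exclusions$rationale))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# version_label: %s", lib$version_label),
    sprintf("# category_vocabulary: %s",
            paste(lib$category_vocabulary, collapse = ";"))), con)
  writeLines(readr::format_csv(tab), con, sep = "")
  invisible(path)
}
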