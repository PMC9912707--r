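speaker_roles <- function() c("patient", "clinician", "caregiver", "other")
dataset_labels <- function() c("development", "validation", "test", "user")

#' Construct a conversation
#'
#' A conversation is an ordered sequence of speaker turns — a turn being an
#' uninterrupted span of speech by one participant — plus identifying and
#' stratification metadata. Turn indices are 0-based, unique and
#' contiguous; turn text may be empty (e.g. inaudible segments).
#'
#' @param conversation_id unique conversation identifier.
#' @param patient_id patient identifier (required: conversations without
#'   one cannot be linked to annotations or strata and are rejected).
#' @param turns data frame with columns `speaker_role` (one of `patient`,
#'   `clinician`, `caregiver`, `other`) and `text`; an optional
#'   `turn_index` column must be `0:(n-1)`.
#' @param dataset_label which analytic sample the conversation belongs to:
#'   `"development"`, `"validation"`, `"test"` or `"user"`.
#' @param metadata named list of conversation/patient attributes used for
#'   stratified evaluation (e.g. `race = "black"`).
#' @return object of class `conversation`.
#' @export
conversation <- function(conversation_id, patient_id, turns,
                         dataset_label = "user", metadata = list()) {
  if (is.null(patient_id) || is.na(patient_id) || !nzchar(patient_id)) {
    stop_validation("Conversation '%s' lacks patient_id data.",
                    as.character(conversation_id))
  }
  if (!dataset_label %in% dataset_labels()) {
    stop_validation("dataset_label must be one of: %s.",
                    toString(dataset_labels()))
  }
  turns <- tibble::as_tibble(turns)
  if (nrow(turns) == 0) {
    stop_validation("Conversation '%s' has no turns (>= 1 required).",
                    conversation_id)
  }
  if (!all(c("speaker_role", "text") %in% names(turns))) {
    stop_validation("Conversation '%s': turns need speaker_role and text.",
                    conversation_id)
  }
  if (anyNA(turns$speaker_role) || anyNA(turns$text)) {
    bad <- which(is.na(turns$speaker_role) | is.na(turns$text))[1]
    stop_validation("Conversation '%s': turn %d lacks speaker_role or text.",
                    conversation_id, bad - 1L)
  }
  bad_role <- setdiff(unique(turns$speaker_role), speaker_roles())
  if (length(bad_role)) {
    stop_validation("Conversation '%s': unknown speaker role(s) %s.",
                    conversation_id, toString(bad_role))
  }
  if (is.null(turns[["turn_index"]])) {
    turns$turn_index <- seq_len(nrow(turns)) - 1L
  } else if (!identical(as.integer(turns$turn_index),
                        seq_len(nrow(turns)) - 1L)) {
    stop_validation(
      "Conversation '%s': turn_index must be contiguous 0..n-1.",
      conversation_id)
  }
  structure(
    list(conversation_id = as.character(conversation_id),
         patient_id = as.character(patient_id),
         dataset_label = dataset_label,
         turns = turns[, c("turn_index", "speaker_role", "text")],
         metadata = metadata),
    class = "conversation")
}

#' @export
print.conversation <- function(x, ...) {
  cat(sprintf("<conversation '%s'> patient %s, %s sample, %d turns\n",
              x$conversation_id, x$patient_id, x$dataset_label,
              nrow(x$turns)))
  invisible(x)
}

#' Assemble conversations into a corpus
#'
#' A corpus holds a set of conversations in two tidy tables: one row per
#' conversation (`conversations(x)`) and one row per turn (`turns(x)`).
#' Conversation ids must be unique; conversations are kept in sorted id
#' order so corpus operations are deterministic.
#'
#' @param convs list of [conversation()] objects.
#' @return object of class `symtalk_corpus`.
#' @export
as_corpus <- function(convs) {
  if (inherits(convs, "conversation")) convs <- list(convs)
  if (length(convs) == 0) {
    warn("Empty corpus: no conversations.")
    return(structure(
      list(conversations = tibble::tibble(
             conversation_id = character(), patient_id = character(),
             dataset_label = character(), metadata = list()),
           turns = tibble::tibble(
             conversation_id = character(), turn_index = integer(),
             speaker_role = character(), text = character())),
      class = "symtalk_corpus"))
  }
  ids <- vapply(convs, function(cv) cv$conversation_id, "")
  if (anyDuplicated(ids)) {
    stop_validation("Duplicate conversation_id(s): %s.",
                    toString(unique(ids[duplicated(ids)])))
  }
  convs <- convs[order(ids)]
  structure(
    list(
      conversations = tibble::tibble(
        conversation_id = sort(ids),
        patient_id = vapply(convs, function(cv) cv$patient_id, ""),
        dataset_label = vapply(convs, function(cv) cv$dataset_label, ""),
        metadata = lapply(convs, function(cv) cv$metadata)),
      turns = dplyr::bind_rows(lapply(convs, function(cv) {
        dplyr::mutate(cv$turns, conversation_id = cv$conversation_id,
                      .before = 1)
      }))),
    class = "symtalk_corpus")
}

#' @export
print.symtalk_corpus <- function(x, ...) {
  cat(sprintf(
    "<symtalk_corpus>: %d conversations, %d patients, %d turns\n",
    nrow(x$conversations), length(unique(x$conversations$patient_id)),
    nrow(x$turns)))
  invisible(x)
}

#' @rdname as_corpus
#' @param x a `symtalk_corpus`.
#' @export
conversations <- function(x) x$conversations

#' @rdname as_corpus
#' @export
turns <- function(x) x$turns

# conversation-level metadata value for each conversation; NA -> "Missing"
conversation_strata <- function(corpus, key) {
  vals <- vapply(corpus$conversations$metadata, function(m) {
    v <- m[[key]]
    if (is.null(v) || is.na(v) || !nzchar(as.character(v))) NA_character_
    else as.character(v)
  }, "")
  setNames(vals %|na|% "Missing", corpus$conversations$conversation_id)
}

#' Read a transcript corpus
#'
#' Two dialects. The structured-text dialect is one YAML document per
#' conversation (extension `.yml`/`.yaml`) with header fields
#' `conversation_id`, `patient_id`, `dataset_label`, `metadata`, and an
#' ordered `turns` list of `{speaker_role, text}`; `path` is the directory
#' holding them. The tabular dialect is a single delimiter-separated file
#' (one row per turn) with columns `conversation_id`, `patient_id`,
#' `dataset_label`, `turn_index`, `speaker_role`, `text`, plus optional
#' `meta_*` columns for stratification metadata.
#'
#' @param path directory of YAML transcripts, or a tabular file.
#' @return a `symtalk_corpus`; conversations sorted by id, turn order
#'   preserved. An empty directory yields an empty corpus with a warning.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.ya?ml$", full.names = TRUE))
    convs <- lapply(files, function(f) {
      doc <- yaml::read_yaml(f)
      if (is.null(doc$turns) || length(doc$turns) == 0) {
        stop_validation("Transcript %s: no turns.", f)
      }
      turns <- dplyr::bind_rows(lapply(seq_along(doc$turns), function(i) {
        tn <- doc$turns[[i]]
        if (is.null(tn$speaker_role) || is.null(tn$text)) {
          stop_validation("Transcript %s: turn %d lacks speaker_role or text.",
                          f, i - 1L)
        }
        tibble::tibble(speaker_role = tn$speaker_role,
                       text = as.character(tn$text))
      }))
      conversation(doc$conversation_id %||%
                     stop_validation("Transcript %s: no conversation_id.", f),
                   doc$patient_id %||% NA_character_,
                   turns,
                   dataset_label = doc$dataset_label %||% "user",
                   metadata = doc$metadata %||% list())
    })
    return(as_corpus(convs))
  }
  if (!file.exists(path)) stop_io("Transcript path not found: %s", path)
  tab <- readr::read_delim(path, delim = guess_delim(path),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  need <- c("conversation_id", "patient_id", "turn_index", "speaker_role",
            "text")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_validation("Transcript table %s lacks column(s): %s.",
                    path, toString(miss))
  }
  tab$text <- tab$text %|na|% ""
  meta_cols <- grep("^meta_", names(tab), value = TRUE)
  convs <- lapply(split(tab, tab$conversation_id), function(g) {
    g <- g[order(as.integer(g$turn_index)), ]
    md <- lapply(meta_cols, function(cl) g[[cl]][1])
    names(md) <- sub("^meta_", "", meta_cols)
    conversation(g$conversation_id[1], g$patient_id[1],
                 tibble::tibble(turn_index = as.integer(g$turn_index),
                                speaker_role = g$speaker_role,
                                text = g$text),
                 dataset_label = (g[["dataset_label"]] %||% "user")[1],
                 metadata = md)
  })
  as_corpus(unname(convs))
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Write a transcript corpus
#'
#' Inverse of [read_corpus()]: writing then reading reproduces every field.
#'
#' @param corpus a `symtalk_corpus`.
#' @param path directory (YAML dialect) or `.tsv`/`.csv` file path
#'   (tabular dialect).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  if (grepl("\\.(tsv|csv)$", path, ignore.case = TRUE)) {
    meta_keys <- sort(unique(unlist(
      lapply(corpus$conversations$metadata, names))))
    tab <- dplyr::left_join(
      corpus$turns,
      corpus$conversations[, c("conversation_id", "patient_id",
                               "dataset_label")],
      by = "conversation_id")
    for (k in meta_keys) {
      vals <- conversation_strata(corpus, k)
      tab[[paste0("meta_", k)]] <-
        unname(vals[tab$conversation_id])
    }
    tab <- tab[, c("conversation_id", "patient_id", "dataset_label",
                   "turn_index", "speaker_role", "text",
                   paste0("meta_", meta_keys))]
    readr::write_delim(tab, path, delim = guess_delim(path))
    return(invisible(path))
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus$conversations))) {
    cid <- corpus$conversations$conversation_id[i]
    ct <- corpus$turns[corpus$turns$conversation_id == cid, ]
    doc <- list(
      conversation_id = cid,
      patient_id = corpus$conversations$patient_id[i],
      dataset_label = corpus$conversations$dataset_label[i],
      metadata = corpus$conversations$metadata[[i]],
      turns = lapply(seq_len(nrow(ct)), function(j) {
        list(speaker_role = ct$speaker_role[j], text = ct$text[j])
      }))
    yaml::write_yaml(doc, file.path(path, paste0(make.names(cid), ".yml")))
  }
  invisible(path)
}
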