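#' Construct a sentence-level theme annotation set
#'
#' Stand-off annotation for one narrative: a mapping from sentence index
#' (1-based, referring to the sentence order produced by the package's
#' splitter on cleaned text) to the set of themes that sentence carries.
#' Sentences may carry multiple themes; unannotated sentences are simply
#' absent from the mapping.
#'
#' @param record_id Record identifier.
#' @param assignments Named list: names are sentence indices (as integers or
#'   strings), values character vectors of themes from [theme_labels()].
#' @return Object of class `theme_annotation`.
#' @export
theme_annotation <- function(record_id, assignments = list()) {
  if (length(assignments)) {
    idx <- suppressWarnings(as.integer(names(assignments)))
    if (anyNA(idx) || any(idx < 1L)) {
      stop("sentence indices must be positive integers (record '",
           record_id, "')", call. = FALSE)
    }
    themes <- unlist(assignments, use.names = FALSE)
    bad <- setdiff(themes, theme_labels())
    if (length(bad)) {
      stop("unknown theme '", bad[1], "' (record '", record_id,
           "'); allowed: ", paste(theme_labels(), collapse = ", "),
           call. = FALSE)
    }
    assignments <- lapply(assignments, as.character)
    names(assignments) <- as.character(idx)
  }
  structure(list(record_id = record_id, assignments = assignments),
            class = "theme_annotation")
}

#' Read theme annotations from JSON
#'
#' The file holds one object or an array of objects of the form
#' `{"record_id": ..., "assignments": {"0": ["attack_description"], ...}}`.
#' Sentence indices are 0-based on disk (the interchange convention) and
#' converted to 1-based internally.
#'
#' @param path JSON file path.
#' @return Named list of `theme_annotation`s keyed by `record_id`.
#' @export
read_theme_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(readLines(path, encoding = "UTF-8", warn = FALSE),
                            simplifyVector = FALSE)
  if (!is.null(raw$record_id)) raw <- list(raw)
  anns <- lapply(raw, function(obj) {
    asg <- obj$assignments %||% list()
    if (length(asg)) {
      names(asg) <- as.character(as.integer(names(asg)) + 1L)
      asg <- lapply(asg, function(x) as.character(unlist(x)))
    }
    theme_annotation(as.character(obj$record_id), asg)
  })
  names(anns) <- vapply(anns, `[[`, character(1), "record_id")
  anns
}

#' Write theme annotations to JSON
#'
#' @param annotations Named list of `theme_annotation`s.
#' @param path Output path. Indices are written 0-based.
#' @return `path`, invisibly.
#' @export
write_theme_annotations <- function(annotations, path) {
  objs <- lapply(annotations, function(ann) {
    asg <- ann$assignments
    if (length(asg)) names(asg) <- as.character(as.integer(names(asg)) - 1L)
    list(record_id = ann$record_id, assignments = asg)
  })
  writeLines(jsonlite::toJSON(unname(objs), auto_unbox = TRUE), path,
             useBytes = TRUE)
  invisible(path)
}

#' Per-text theme proportions
#'
#' The proportion of a theme in a narrative is the word-token count of the
#' sentences carrying that theme divided by the narrative's total word-token
#' count. Unannotated sentences contribute to the denominator only. With
#' multi-theme sentences each theme's proportion is computed independently,
#' so proportions can sum to more than 1.
#'
#' @param doc A `tokenized_document` with at least one token.
#' @param ann The record's `theme_annotation`.
#' @return Tibble with columns `record_id`, `theme` (all seven), `proportion`.
#' @export
theme_proportions <- function(doc, ann) {
  n_sent <- lengths(doc$sentences)
  total <- sum(n_sent)
  if (total == 0) {
    stop("document '", doc$record_id, "' has no tokens", call. = FALSE)
  }
  idx <- as.integer(names(ann$assignments))
  if (length(idx) && any(idx > length(n_sent))) {
    stop("sentence index ", max(idx), " out of range for document '",
         doc$record_id, "' (", length(n_sent), " sentences)", call. = FALSE)
  }
  prop <- vapply(theme_labels(), function(th) {
    has <- idx[vapply(ann$assignments, function(ts) th %in% ts, logical(1))]
    sum(n_sent[has]) / total
  }, numeric(1))
  tibble::tibble(record_id = doc$record_id, theme = theme_labels(),
                 proportion = unname(prop))
}

#' Theme proportions for a whole corpus
#'
#' @param docs Named list of `tokenized_document`s.
#' @param annotations Named list of `theme_annotation`s; records without an
#'   entry are treated as fully unannotated.
#' @return Long tibble (`record_id`, `theme`, `proportion`).
#' @export
theme_proportions_corpus <- function(docs, annotations) {
  dplyr::bind_rows(lapply(docs, function(doc) {
    ann <- annotations[[doc$record_id]] %||% theme_annotation(doc$record_id)
    theme_proportions(doc, ann)
  }))
}

#' Median (Q1-Q3) theme proportions per diagnostic group
#'
#' @param props Long tibble from [theme_proportions_corpus()].
#' @param labels Named character vector or corpus mapping `record_id` to
#'   diagnosis; every record in `props` must be labelled.
#' @return Tibble (`group`, `theme`, `median`, `q1`, `q3`), proportions in
#'   `[0, 1]`; groups are `full_cohort` plus each diagnosis label. Quartiles
#'   use the same type-7 convention as [summarize_corpus()].
#' @export
summarize_themes <- function(props, labels) {
  if (inherits(labels, "data.frame")) {
    labels <- stats::setNames(labels$diagnosis, labels$record_id)
  }
  lab <- labels[props$record_id]
  if (anyNA(lab)) {
    stop("unlabelled record '", props$record_id[which(is.na(lab))[1]], "'",
         call. = FALSE)
  }
  df <- dplyr::mutate(props, group = unname(lab))
  groups <- c("full_cohort", intersect(diagnosis_labels(), unique(df$group)))
  rows <- lapply(groups, function(g) {
    sub <- if (g == "full_cohort") df else df[df$group == g, ]
    dplyr::summarise(
      dplyr::group_by(sub, theme = factor(theme, levels = theme_labels())),
      median = stats::quantile(proportion, .5, type = 7, names = FALSE),
      q1 = stats::quantile(proportion, .25, type = 7, names = FALSE),
      q3 = stats::quantile(proportion, .75, type = 7, names = FALSE),
      .groups = "drop"
    ) |>
      dplyr::mutate(group = g, theme = as.character(theme)) |>
      dplyr::select(group, theme, median, q1, q3)
  })
  dplyr::bind_rows(rows)
}

#' Extract the sub-corpus of sentences carrying one theme
#'
#' For each record, concatenates (in order) the sentences annotated with the
#' given theme into a new narrative; records with no such sentence are
#' dropped. Used to build the attack-description corpus on which the
#' classification experiments run.
#'
#' @param corpus A `narrative_corpus`.
#' @param annotations Named list of `theme_annotation`s.
#' @param theme One of [theme_labels()].
#' @param abbreviations Sentence-splitter guard, which must match the one
#'   used when the annotations were made.
#' @return A `narrative_corpus` (metadata preserved). Warns if empty.
#' @export
extract_theme_subcorpus <- function(corpus, annotations, theme,
                                    abbreviations = dutch_abbreviations()) {
  theme <- match.arg(theme, theme_labels())
  keep_rows <- list()
  for (i in seq_len(nrow(corpus))) {
    rid <- corpus$record_id[i]
    ann <- annotations[[rid]]
    if (is.null(ann) || !length(ann$assignments)) next
    has <- vapply(ann$assignments, function(ts) theme %in% ts, logical(1))
    if (!any(has)) next
    sents <- split_sentences(clean_text(corpus$text[i]),
                             abbreviations = abbreviations)
    idx <- sort(as.integer(names(ann$assignments)[has]))
    if (any(idx > length(sents))) {
      stop("sentence index out of range for record '", rid, "'", call. = FALSE)
    }
    keep_rows[[length(keep_rows) + 1L]] <-
      tibble::tibble(record_id = rid,
                     text = paste(sents[idx], collapse = " "),
                     diagnosis = corpus$diagnosis[i],
                     age = corpus$age[i], sex = corpus$sex[i])
  }
  if (!length(keep_rows)) {
    warning("no record carries theme '", theme, "'; returning empty corpus",
            call. = FALSE)
    out <- tibble::tibble(record_id = character(0), text = character(0),
                          diagnosis = character(0), age = integer(0),
                          sex = character(0))
    class(out) <- c("narrative_corpus", class(out))
    return(out)
  }
  as_corpus(dplyr::bind_rows(keep_rows))
}
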