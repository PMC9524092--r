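#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Diagnosis labels recognised by the package
#'
#' The two primary headache disorders that form the binary classification
#' task: migraine and cluster headache.
#'
#' @return Character vector of the two allowed diagnosis labels.
#' @export
diagnosis_labels <- function() c("migraine", "cluster_headache")

#' The closed set of narrative themes
#'
#' Seven predefined themes used for sentence-level annotation of patient
#' narratives. "Previous medical history" is normalised to the identifier
#' `medical_history`.
#'
#' @return Character vector of the seven theme identifiers.
#' @export
theme_labels <- function() {
  c("attack_description", "burden_of_disease", "comorbidities",
    "technical_investigations", "triggers", "treatment", "medical_history")
}

validate_corpus_fields <- function(df, where) {
  n <- nrow(df)
  rid <- as.character(df$record_id)
  if (anyNA(rid) || any(!nzchar(trimws(rid)))) {
    bad <- which(is.na(rid) | !nzchar(trimws(rid)))[1]
    stop(where, ": missing record_id at row ", bad, call. = FALSE)
  }
  if (anyDuplicated(rid)) {
    dup <- rid[duplicated(rid)][1]
    stop(where, ": duplicate record_id '", dup, "'", call. = FALSE)
  }
  txt <- as.character(df$text)
  if (anyNA(txt) || any(!nzchar(trimws(txt)))) {
    bad <- which(is.na(txt) | !nzchar(trimws(txt)))[1]
    stop(where, ": empty text at row ", bad, " (record_id '", rid[bad], "')",
         call. = FALSE)
  }
  dx <- as.character(df$diagnosis)
  bad_dx <- !is.na(dx) & !dx %in% diagnosis_labels()
  if (any(bad_dx)) {
    stop(where, ": unknown diagnosis label '", dx[which(bad_dx)[1]],
         "'; allowed labels: ", paste(diagnosis_labels(), collapse = ", "),
         call. = FALSE)
  }
  age <- suppressWarnings(as.numeric(df$age))
  bad_age <- !is.na(age) & (age <= 0 | age != round(age))
  if (any(bad_age)) {
    stop(where, ": age must be a positive integer (record_id '",
         rid[which(bad_age)[1]], "')", call. = FALSE)
  }
  sx <- as.character(df$sex)
  bad_sx <- !is.na(sx) & !sx %in% c("female", "male")
  if (any(bad_sx)) {
    stop(where, ": sex must be 'female' or 'male' (record_id '",
         rid[which(bad_sx)[1]], "')", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a narrative corpus from a data frame
#'
#' A corpus is an ordered collection of narrative records. Each record has an
#' opaque unique `record_id`, free `text` (normalised to Unicode NFC), and
#' optional `diagnosis`, `age` (positive integer years) and `sex`
#' (`"female"`/`"male"`) metadata. Metadata may be missing at I/O time; stages
#' that need it reject records lacking it.
#'
#' @param df Data frame with at least columns `record_id` and `text`.
#' @return A tibble of class `narrative_corpus` with columns `record_id`,
#'   `text`, `diagnosis`, `age`, `sex`.
#' @export
as_corpus <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("diagnosis", "age", "sex")) {
    if (is.null(df[[col]])) df[[col]] <- NA
  }
  if (is.null(df$record_id) || is.null(df$text)) {
    stop("corpus needs 'record_id' and 'text' columns", call. = FALSE)
  }
  validate_corpus_fields(df, "corpus")
  out <- tibble::tibble(
    record_id = as.character(df$record_id),
    text = stringi::stri_trans_nfc(as.character(df$text)),
    diagnosis = as.character(df$diagnosis),
    age = as.integer(df$age),
    sex = as.character(df$sex)
  )
  class(out) <- c("narrative_corpus", class(out))
  out
}

#' Label counts of a corpus
#'
#' @param corpus A `narrative_corpus`.
#' @return Named integer vector: number of labelled records per diagnosis.
#' @export
label_counts <- function(corpus) {
  dx <- corpus$diagnosis[!is.na(corpus$diagnosis)]
  out <- vapply(diagnosis_labels(), function(l) sum(dx == l), integer(1))
  out
}

#' Read a narrative corpus
#'
#' JSONL (one JSON object per line, UTF-8) is the canonical serialization;
#' CSV is supported for interchange (text fields quoted, so embedded newlines
#' survive). Malformed rows are rejected with the offending line named —
#' readers never silently repair input.
#'
#' @param path File path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return A `narrative_corpus` tibble, input order preserved.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]
    if (!length(lines)) stop("no records in ", path, call. = FALSE)
    lineno <- which(keep)
    recs <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(
        jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
        error = function(e) {
          stop("malformed JSONL at line ", lineno[i], ": ",
               conditionMessage(e), call. = FALSE)
        }
      )
      if (is.null(obj$record_id) || is.null(obj$text)) {
        stop("malformed record at line ", lineno[i],
             ": record_id and text are required", call. = FALSE)
      }
      obj
    })
    df <- data.frame(
      record_id = vapply(recs, function(r) as.character(r$record_id), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      diagnosis = vapply(recs, function(r) as.character(r$diagnosis %||% NA_character_), character(1)),
      age = vapply(recs, function(r) if (is.null(r$age) || is.na(r$age)) NA_real_ else as.numeric(r$age), numeric(1)),
      sex = vapply(recs, function(r) as.character(r$sex %||% NA_character_), character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
    if (!nrow(df)) stop("no records in ", path, call. = FALSE)
    if (is.null(df$record_id) || is.null(df$text)) {
      stop("CSV corpus needs 'record_id' and 'text' columns", call. = FALSE)
    }
    if (!is.null(df$age)) df$age <- suppressWarnings(as.numeric(df$age))
  }
  as_corpus(df)
}

#' Write a narrative corpus
#'
#' @param corpus A `narrative_corpus`.
#' @param path Output file path.
#' @param format `"jsonl"` (canonical) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(record_id = corpus$record_id[i], text = corpus$text[i])
      if (!is.na(corpus$diagnosis[i])) rec$diagnosis <- corpus$diagnosis[i]
      if (!is.na(corpus$age[i])) rec$age <- corpus$age[i]
      if (!is.na(corpus$sex[i])) rec$sex <- corpus$sex[i]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(as.data.frame(corpus), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Construct a sentiment lexicon
#'
#' @param entries Named numeric vector mapping lowercased words to raw
#'   valences on the lexicon's native scale.
#' @param name Lexicon name.
#' @return Object of class `sentiment_lexicon`.
#' @export
sentiment_lexicon <- function(entries, name = "lexicon") {
  if (!length(entries)) stop("lexicon '", name, "' has no entries", call. = FALSE)
  words <- stringr::str_to_lower(names(entries))
  if (anyDuplicated(words)) {
    stop("lexicon '", name, "' has duplicate word '",
         words[duplicated(words)][1], "'", call. = FALSE)
  }
  if (anyNA(entries)) stop("lexicon '", name, "' has missing valences", call. = FALSE)
  entries <- as.numeric(entries)
  names(entries) <- words
  structure(list(name = name, entries = entries), class = "sentiment_lexicon")
}

#' Read a sentiment lexicon from TSV
#'
#' Expected format: two tab-separated columns `word<TAB>valence`, no header.
#' Words are lowercased at load. A word occurring twice in one file is an
#' error: precedence between conflicting valences is the cascade's job, not
#' the file's.
#'
#' @param path TSV file path.
#' @param name Lexicon name; defaults to the file name without extension.
#' @return A `sentiment_lexicon`.
#' @export
read_lexicon <- function(path, name = NULL) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) stop("lexicon '", name, "' is empty", call. = FALSE)
  lineno <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop("lexicon '", name, "': expected word<TAB>valence at line ",
         lineno[bad[1]], call. = FALSE)
  }
  words <- vapply(parts, `[[`, character(1), 1L)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(vals)) {
    stop("lexicon '", name, "': non-numeric valence at line ",
         lineno[which(is.na(vals))[1]], call. = FALSE)
  }
  names(vals) <- words
  sentiment_lexicon(vals, name = name)
}

#' Write a sentiment lexicon to TSV
#'
#' @param lexicon A `sentiment_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  lines <- paste(names(lexicon$entries),
                 format(lexicon$entries, trim = TRUE, scientific = FALSE),
                 sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a word list
#'
#' Word lists serve two purposes: `stopwords` (function words removed before
#' keyness and classification) and `label_blocklist` (class-label mentions
#' and medication names that would leak the diagnosis into the features).
#'
#' @param words Character vector; lowercased and deduplicated.
#' @param purpose `"stopwords"` or `"label_blocklist"`.
#' @return Object of class `word_list`.
#' @export
word_list <- function(words, purpose = c("stopwords", "label_blocklist")) {
  purpose <- match.arg(purpose)
  words <- unique(stringr::str_to_lower(trimws(words)))
  words <- words[nzchar(words)]
  if (!length(words)) stop("word list is empty after filtering", call. = FALSE)
  if (any(grepl("\\s", words))) {
    stop("word list entries must not contain whitespace: '",
         words[grepl("\\s", words)][1], "'", call. = FALSE)
  }
  structure(list(purpose = purpose, words = words), class = "word_list")
}

#' Read a word list from plain text
#'
#' One entry per line; `#` starts a comment (whole-line or trailing); blank
#' lines ignored; entries lowercased and deduplicated.
#'
#' @param path File path.
#' @inheritParams word_list
#' @return A `word_list`.
#' @export
read_wordlist <- function(path, purpose = c("stopwords", "label_blocklist")) {
  purpose <- match.arg(purpose)
  if (!file.exists(path)) stop("word list file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    stop("word list ", path, " is empty after filtering", call. = FALSE)
  }
  word_list(lines, purpose = purpose)
}
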