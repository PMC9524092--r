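#' Clean raw narrative text
#'
#' Normalises to Unicode NFC, removes control and format characters,
#' collapses runs of horizontal whitespace to a single space and runs of
#' vertical whitespace to a single newline (line breaks often mark sentence
#' boundaries in patient-typed text, so they are preserved for the splitter).
#' Idempotent: `clean_text(clean_text(x)) == clean_text(x)`.
#'
#' @param text Character vector.
#' @return Cleaned character vector (possibly empty strings; downstream
#'   stages reject those).
#' @export
clean_text <- function(text) {
  x <- stringi::stri_trans_nfc(as.character(text))
  x <- stringr::str_replace_all(x, "\r\n?", "\n")
  # control chars other than newline become spaces; format chars vanish
  x <- stringr::str_replace_all(x, "[^\\P{Cc}\n]", " ")
  x <- stringr::str_replace_all(x, "\\p{Cf}", "")
  x <- stringr::str_replace_all(x, "[ \\t\\u00a0]+", " ")
  x <- stringr::str_replace_all(x, " ?\n ?", "\n")
  x <- stringr::str_replace_all(x, "\n+", "\n")
  stringr::str_trim(x)
}

#' Default abbreviation guard for sentence splitting
#'
#' Dutch abbreviations after which a period does not end a sentence.
#'
#' @return Character vector of abbreviations (without the trailing period).
#' @export
dutch_abbreviations <- function() {
  c("dhr", "mevr", "dr", "prof", "bv", "bijv", "o.a", "d.w.z", "evt",
    "ca", "nr", "vgl", "afk", "m.a.w", "t.o.v", "i.v.m", "e.d")
}

#' Split cleaned text into sentences
#'
#' Terminators are `.`, `!` and `?` followed by whitespace or end of line; a
#' bare newline also ends a sentence. Periods inside decimal numbers (no
#' following whitespace) and after listed abbreviations do not split.
#'
#' @param text A single cleaned string.
#' @param abbreviations Abbreviation guard list.
#' @return Character vector of sentence strings (no empties).
#' @export
split_sentences <- function(text, abbreviations = dutch_abbreviations()) {
  stopifnot(length(text) == 1L)
  out <- character(0)
  for (line in strsplit(text, "\n", fixed = TRUE)[[1]]) {
    m <- gregexpr("[.!?]+(?=\\s|$)", line, perl = TRUE)[[1]]
    cuts <- integer(0)
    if (m[1] != -1L) {
      ends <- as.integer(m) + attr(m, "match.length") - 1L
      for (k in seq_along(m)) {
        start <- as.integer(m[k])
        term <- substr(line, start, ends[k])
        if (grepl("^\\.+$", term) && nchar(term) == 1L) {
          prefix <- substr(line, 1L, start - 1L)
          prev <- stringr::str_to_lower(
            stringr::str_extract(prefix, "[\\p{L}\\p{N}.]+$")
          )
          prev <- sub("\\.$", "", prev %||% "")
          if (!is.na(prev) && prev %in% abbreviations) next
        }
        cuts <- c(cuts, ends[k])
      }
    }
    prev_end <- 0L
    for (cut in cuts) {
      out <- c(out, substr(line, prev_end + 1L, cut))
      prev_end <- cut
    }
    if (prev_end < nchar(line)) out <- c(out, substr(line, prev_end + 1L, nchar(line)))
  }
  out <- stringr::str_trim(out)
  out[nzchar(out)]
}

#' Tokenize one sentence into lowercased word tokens
#'
#' Rule-based tokenizer: a token is a maximal run of Unicode letters/digits,
#' optionally joined by internal hyphens or apostrophes. Punctuation is split
#' off and discarded, so the result is a word-token stream. The interface is
#' deliberately small so another tokenizer can be swapped in.
#'
#' @param sentence A single string.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize <- function(sentence) {
  stringr::str_extract_all(
    stringr::str_to_lower(sentence),
    "[\\p{L}\\p{N}]+(?:[-'’][\\p{L}\\p{N}]+)*"
  )[[1]]
}

new_tokenized_document <- function(record_id, sentences, flags = character(0)) {
  sentences <- sentences[lengths(sentences) > 0L]
  structure(
    list(record_id = record_id, sentences = sentences, flags = unique(flags)),
    class = "tokenized_document"
  )
}

#' Tokenize a narrative into a sentence-structured document
#'
#' Applies `clean_text()`, `split_sentences()` and `tokenize()` in order.
#' Sentences that contain no word tokens are dropped.
#'
#' @param text Raw narrative text (single string).
#' @param record_id Record identifier carried through the pipeline.
#' @param abbreviations Abbreviation guard for the sentence splitter.
#' @return A `tokenized_document`: list with `record_id`, `sentences`
#'   (list of character vectors) and provenance `flags`.
#' @export
tokenize_document <- function(text, record_id = "doc",
                              abbreviations = dutch_abbreviations()) {
  cleaned <- clean_text(text)
  sents <- split_sentences(cleaned, abbreviations = abbreviations)
  new_tokenized_document(record_id, lapply(sents, tokenize), flags = "cleaned")
}

#' Tokenize every record of a corpus
#'
#' @param corpus A `narrative_corpus`.
#' @param abbreviations Abbreviation guard for the sentence splitter.
#' @return Named list of `tokenized_document`s keyed by `record_id`.
#' @export
tokenize_corpus <- function(corpus, abbreviations = dutch_abbreviations()) {
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    tokenize_document(corpus$text[i], record_id = corpus$record_id[i],
                      abbreviations = abbreviations)
  })
  names(docs) <- corpus$record_id
  docs
}

#' Flatten a tokenized document to one token stream
#'
#' @param doc A `tokenized_document`.
#' @return Character vector of tokens in original order.
#' @export
doc_tokens <- function(doc) {
  unlist(doc$sentences, use.names = FALSE) %||% character(0)
}

#' Count tokens, types and sentences of a document
#'
#' A token is one occurrence of a word-level character sequence; a type is
#' the class of all tokens with the same character sequence ("time after
#' time" has 3 tokens and 2 types).
#'
#' @param doc A `tokenized_document`.
#' @return Named integer vector with elements `tokens`, `types`, `sentences`.
#' @export
count_tokens_types <- function(doc) {
  toks <- doc_tokens(doc)
  c(tokens = length(toks),
    types = length(unique(toks)),
    sentences = length(doc$sentences))
}

#' Per-record token/type/sentence counts for a document set
#'
#' @param docs List of `tokenized_document`s.
#' @return Tibble with columns `record_id`, `tokens`, `types`, `sentences`.
#' @export
corpus_token_stats <- function(docs) {
  counts <- t(vapply(docs, count_tokens_types, integer(3)))
  tibble::tibble(
    record_id = vapply(docs, `[[`, character(1), "record_id"),
    tokens = counts[, "tokens"],
    types = counts[, "types"],
    sentences = counts[, "sentences"]
  )
}

filter_doc_tokens <- function(doc, words, flag) {
  sentences <- lapply(doc$sentences, function(s) s[!s %in% words])
  new_tokenized_document(doc$record_id, sentences, flags = c(doc$flags, flag))
}

#' Remove class-label (blocklist) tokens from a document
#'
#' Drops every token that matches the label blocklist (diagnosis names,
#' medication references and other words that hint at the class label).
#' Sentences left empty are dropped; surviving token order is untouched.
#'
#' @param doc A `tokenized_document`.
#' @param blocklist A `word_list` with purpose `label_blocklist`.
#' @return Filtered `tokenized_document` with flag `blocklist_filtered`.
#' @export
filter_blocklist <- function(doc, blocklist) {
  stopifnot(inherits(blocklist, "word_list"))
  if (blocklist$purpose != "label_blocklist") {
    stop("filter_blocklist() needs a word list with purpose 'label_blocklist'",
         call. = FALSE)
  }
  filter_doc_tokens(doc, blocklist$words, "blocklist_filtered")
}

#' Remove stop words from a document
#'
#' @param doc A `tokenized_document`.
#' @param stopwords A `word_list` with purpose `stopwords`.
#' @return Filtered `tokenized_document` with flag `stopwords_removed`.
#' @export
filter_stopwords <- function(doc, stopwords) {
  stopifnot(inherits(stopwords, "word_list"))
  if (stopwords$purpose != "stopwords") {
    stop("filter_stopwords() needs a word list with purpose 'stopwords'",
         call. = FALSE)
  }
  filter_doc_tokens(doc, stopwords$words, "stopwords_removed")
}

#' Apply the full pre-processing chain to a corpus
#'
#' clean -> sentence split -> tokenize -> blocklist filter -> stop-word
#' filter, the order used for the classification and keyness corpus. Set
#' `keep_stopwords = TRUE` for the sentiment variant, where stop words stay
#' because source lexicons may score intensifiers and negators.
#'
#' @param corpus A `narrative_corpus`.
#' @param blocklist Optional `word_list` (purpose `label_blocklist`).
#' @param stopwords Optional `word_list` (purpose `stopwords`).
#' @param keep_stopwords If `TRUE`, skip stop-word removal.
#' @param abbreviations Abbreviation guard for the sentence splitter.
#' @return Named list of `tokenized_document`s.
#' @export
preprocess_corpus <- function(corpus, blocklist = NULL, stopwords = NULL,
                              keep_stopwords = FALSE,
                              abbreviations = dutch_abbreviations()) {
  docs <- tokenize_corpus(corpus, abbreviations = abbreviations)
  if (!is.null(blocklist)) docs <- lapply(docs, filter_blocklist, blocklist)
  if (!is.null(stopwords) && !keep_stopwords) {
    docs <- lapply(docs, filter_stopwords, stopwords)
  }
  docs
}
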