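#' Feature-extraction specification
#'
#' Controls which feature families enter the classifier: word n-grams
#' (computed within sentences), character n-grams (computed within tokens
#' with explicit `#` boundary markers, so they never span removed stop-word
#' gaps) and patient metadata (age, sex). The n-gram order range applies to
#' both families. Weighting is raw term frequency by default, with binary
#' and tf-idf variants available.
#'
#' @param word_ngrams,char_ngrams Logical flags for the two n-gram families.
#' @param n_range Integer interval `c(n_min, n_max)`, default `c(1, 3)`.
#' @param metadata Include age (standardized on the training fold for SVM and
#'   logistic regression; raw years for naive Bayes) and a 0/1 female
#'   indicator.
#' @param weighting `"count"`, `"binary"` or `"tfidf"`.
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(word_ngrams = TRUE, char_ngrams = TRUE,
                         n_range = c(1L, 3L), metadata = FALSE,
                         weighting = c("count", "binary", "tfidf")) {
  weighting <- match.arg(weighting)
  n_range <- as.integer(n_range)
  if (length(n_range) != 2L || n_range[1] < 1L || n_range[1] > n_range[2]) {
    stop("n_range must be c(n_min, n_max) with 1 <= n_min <= n_max",
         call. = FALSE)
  }
  if (!word_ngrams && !char_ngrams && !metadata) {
    stop("at least one feature family must be enabled", call. = FALSE)
  }
  structure(list(word_ngrams = word_ngrams, char_ngrams = char_ngrams,
                 n_range = n_range, metadata = metadata,
                 weighting = weighting),
            class = "feature_spec")
}

#' Feature spec for one of the study's three feature groups
#'
#' `"ngrams"` = word + character 1–3-grams; `"metadata"` = age and sex only;
#' `"ngrams_metadata"` = both combined.
#'
#' @param group Feature-group name.
#' @return A `feature_spec`.
#' @export
feature_spec_group <- function(group = c("ngrams", "metadata", "ngrams_metadata")) {
  group <- match.arg(group)
  switch(group,
    ngrams = feature_spec(TRUE, TRUE, metadata = FALSE),
    metadata = feature_spec(FALSE, FALSE, metadata = TRUE),
    ngrams_metadata = feature_spec(TRUE, TRUE, metadata = TRUE)
  )
}

word_ngram_strings <- function(sentences, n_range) {
  out <- list()
  for (s in sentences) {
    len <- length(s)
    for (n in n_range[1]:n_range[2]) {
      if (len < n) next
      if (n == 1L) {
        out[[length(out) + 1L]] <- s
      } else {
        m <- len - n + 1L
        grams <- s[1:m]
        for (j in 2:n) grams <- paste(grams, s[j:(m + j - 1L)], sep = "_")
        out[[length(out) + 1L]] <- grams
      }
    }
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

char_ngram_strings <- function(tokens, n_range) {
  if (!length(tokens)) return(character(0))
  padded <- paste0("#", tokens, "#")
  out <- list()
  for (p in padded) {
    np <- nchar(p)
    for (n in n_range[1]:n_range[2]) {
      if (np < n) next
      starts <- 1:(np - n + 1L)
      out[[length(out) + 1L]] <- substring(p, starts, starts + n - 1L)
    }
  }
  unlist(out, use.names = FALSE)
}

#' N-gram occurrence counts of one document
#'
#' Word n-grams are prefixed `w:` and character n-grams `c:` in the feature
#' namespace. Computing these once per document and reusing them across
#' cross-validation folds is the main performance lever of the evaluation
#' code.
#'
#' @param doc A `tokenized_document`.
#' @param spec A `feature_spec`.
#' @return Named integer vector of n-gram counts.
#' @export
doc_ngram_counts <- function(doc, spec) {
  grams <- character(0)
  if (spec$word_ngrams) {
    grams <- c(grams, paste0("w:", word_ngram_strings(doc$sentences, spec$n_range)))
  }
  if (spec$char_ngrams) {
    grams <- c(grams, paste0("c:", char_ngram_strings(doc_tokens(doc), spec$n_range)))
  }
  if (!length(grams)) return(stats::setNames(integer(0), character(0)))
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

precompute_ngram_counts <- function(docs, spec) {
  if (!spec$word_ngrams && !spec$char_ngrams) {
    return(stats::setNames(vector("list", length(docs)), names(docs)))
  }
  lapply(docs, doc_ngram_counts, spec = spec)
}

#' Fit a feature vectorizer on a training subset
#'
#' The n-gram vocabulary and the age standardization statistics are functions
#' of the training subset only; unseen n-grams in held-out documents are
#' ignored at transform time. This is the no-leakage contract the nested
#' cross-validation relies on.
#'
#' @param counts Named list of per-document n-gram count vectors (from
#'   [precompute_ngram_counts()]).
#' @param records A `narrative_corpus` (for metadata).
#' @param spec A `feature_spec`.
#' @param train_ids Record ids of the training subset.
#' @param standardize_age Standardize age with training mean/sd (disable for
#'   multinomial naive Bayes, which needs non-negative features).
#' @return Object of class `featurizer`.
#' @export
fit_featurizer <- function(counts, records, spec, train_ids,
                           standardize_age = TRUE) {
  vocab <- character(0)
  if (spec$word_ngrams || spec$char_ngrams) {
    vocab <- sort(unique(unlist(lapply(counts[train_ids], names),
                                use.names = FALSE)))
  }
  idf <- NULL
  if (spec$weighting == "tfidf" && length(vocab)) {
    df <- numeric(length(vocab))
    names(df) <- vocab
    for (id in train_ids) {
      present <- names(counts[[id]])
      df[present[present %in% vocab]] <- df[present[present %in% vocab]] + 1
    }
    idf <- log((1 + length(train_ids)) / (1 + df)) + 1
  }
  age_mean <- age_sd <- NULL
  if (spec$metadata) {
    idx <- match(train_ids, records$record_id)
    if (anyNA(records$age[idx]) || anyNA(records$sex[idx])) {
      bad <- train_ids[which(is.na(records$age[idx]) | is.na(records$sex[idx]))[1]]
      stop("metadata features requested but age/sex missing for record_id '",
           bad, "'", call. = FALSE)
    }
    if (standardize_age) {
      age_mean <- mean(records$age[idx])
      age_sd <- stats::sd(records$age[idx])
      if (is.na(age_sd) || age_sd == 0) age_sd <- 1
    }
  }
  vocab_pos <- stats::setNames(seq_along(vocab), vocab)
  structure(list(spec = spec, vocab = vocab, vocab_pos = vocab_pos, idf = idf,
                 age_mean = age_mean, age_sd = age_sd,
                 standardize_age = standardize_age),
            class = "featurizer")
}

#' Transform documents into a feature matrix
#'
#' @param featurizer A fitted `featurizer`.
#' @param counts Named list of per-document n-gram count vectors.
#' @param records A `narrative_corpus`.
#' @param ids Record ids to transform (row order of the result).
#' @return Sparse `dgCMatrix` (rows = documents, columns = vocabulary plus
#'   any metadata columns `m:age`, `m:female`).
#' @export
transform_features <- function(featurizer, counts, records, ids) {
  spec <- featurizer$spec
  vocab <- featurizer$vocab
  n_meta <- if (spec$metadata) 2L else 0L
  p <- length(vocab) + n_meta
  ii <- list(); jj <- list(); xx <- list()
  if (length(vocab)) {
    vocab_pos <- featurizer$vocab_pos
    for (r in seq_along(ids)) {
      cnt <- counts[[ids[r]]]
      pos <- vocab_pos[names(cnt)]
      keep <- !is.na(pos)
      if (!any(keep)) next
      val <- as.numeric(cnt[keep])
      if (spec$weighting == "binary") val <- rep(1, length(val))
      if (spec$weighting == "tfidf") val <- val * featurizer$idf[names(cnt)[keep]]
      ii[[r]] <- rep.int(r, sum(keep))
      jj[[r]] <- unname(pos[keep])
      xx[[r]] <- val
    }
  }
  if (spec$metadata) {
    idx <- match(ids, records$record_id)
    if (anyNA(records$age[idx]) || anyNA(records$sex[idx])) {
      bad <- ids[which(is.na(records$age[idx]) | is.na(records$sex[idx]))[1]]
      stop("metadata features requested but age/sex missing for record_id '",
           bad, "'", call. = FALSE)
    }
    age <- as.numeric(records$age[idx])
    if (featurizer$standardize_age) {
      age <- (age - featurizer$age_mean) / featurizer$age_sd
    }
    female <- as.numeric(records$sex[idx] == "female")
    k <- length(ii)
    ii[[k + 1L]] <- seq_along(ids)
    jj[[k + 1L]] <- rep.int(length(vocab) + 1L, length(ids))
    xx[[k + 1L]] <- age
    ii[[k + 2L]] <- seq_along(ids)
    jj[[k + 2L]] <- rep.int(length(vocab) + 2L, length(ids))
    xx[[k + 2L]] <- female
  }
  Matrix::sparseMatrix(
    i = unlist(ii) %||% integer(0),
    j = unlist(jj) %||% integer(0),
    x = unlist(xx) %||% numeric(0),
    dims = c(length(ids), p),
    dimnames = list(ids, c(vocab, if (spec$metadata) c("m:age", "m:female")))
  )
}

#' One-call feature extraction with train-only fitting
#'
#' Convenience wrapper: fits the vectorizer on `fit_ids` and returns the
#' matrices for the training and (optionally) held-out documents.
#'
#' @param docs Named list of `tokenized_document`s.
#' @param records A `narrative_corpus`.
#' @param spec A `feature_spec`.
#' @param fit_ids Training record ids (vocabulary source).
#' @param transform_ids Held-out record ids (default none).
#' @param standardize_age See [fit_featurizer()].
#' @return List with `featurizer`, `train` and `test` matrices.
#' @export
extract_features <- function(docs, records, spec, fit_ids,
                             transform_ids = character(0),
                             standardize_age = TRUE) {
  counts <- precompute_ngram_counts(docs, spec)
  fz <- fit_featurizer(counts, records, spec, fit_ids,
                       standardize_age = standardize_age)
  list(
    featurizer = fz,
    train = transform_features(fz, counts, records, fit_ids),
    test = if (length(transform_ids)) {
      transform_features(fz, counts, records, transform_ids)
    }
  )
}
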