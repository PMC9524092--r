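#' Build an ordered lexicon cascade
#'
#' A cascade is an ordered sequence of sentiment lexicons consulted with
#' first-match-wins semantics: a token's valence comes from the first lexicon
#' that contains it. Because source lexicons use different native scales,
#' each lexicon is normalised at load by its maximum absolute valence — the
#' sign-preserving linear map onto `[-1, 1]`.
#'
#' @param lexicons List of `sentiment_lexicon`s, in consultation order.
#' @return Object of class `lexicon_cascade` with the normalised lexicons
#'   and a resolved first-match lookup table.
#' @export
lexicon_cascade <- function(lexicons) {
  if (!length(lexicons)) stop("cascade needs at least one lexicon", call. = FALSE)
  stopifnot(all(vapply(lexicons, inherits, logical(1), "sentiment_lexicon")))
  normalised <- lapply(lexicons, function(lex) {
    m <- max(abs(lex$entries))
    if (m == 0) stop("lexicon '", lex$name, "' has all-zero valences",
                     call. = FALSE)
    lex$entries <- lex$entries / m
    lex
  })
  map <- numeric(0)
  for (lex in normalised) {
    new <- setdiff(names(lex$entries), names(map))
    map <- c(map, lex$entries[new])
  }
  structure(list(lexicons = normalised, map = map), class = "lexicon_cascade")
}

#' Look up token valences in a cascade
#'
#' @param tokens Character vector of lowercased tokens.
#' @param cascade A `lexicon_cascade`.
#' @return Numeric vector of normalised valences; `NA` where no lexicon
#'   contains the token.
#' @export
cascade_lookup <- function(tokens, cascade) {
  stopifnot(inherits(cascade, "lexicon_cascade"))
  unname(cascade$map[tokens])
}

#' Sentiment score of one document
#'
#' The document score is the plain sum of the normalised valences of all
#' matched tokens, each occurrence counted (no negation or intensifier
#' arithmetic). Polarity is `positive` when the score is strictly greater
#' than zero and otherwise the value of `zero_polarity` (default
#' `"negative"`, matching a strict two-way split with no neutral class).
#' Documents should be tokenized *without* stop-word removal, since source
#' lexicons may score function words; blocklist filtering still applies.
#'
#' @param doc A `tokenized_document`.
#' @param cascade A `lexicon_cascade`.
#' @param zero_polarity Polarity assigned to a zero score.
#' @return Tibble row: `record_id`, `score`, `n_matched`, `polarity`.
#' @export
score_document <- function(doc, cascade, zero_polarity = c("negative", "positive")) {
  zero_polarity <- match.arg(zero_polarity)
  v <- cascade_lookup(doc_tokens(doc), cascade)
  matched <- !is.na(v)
  if (!any(matched)) {
    warning("no lexicon matches in document '", doc$record_id,
            "'; score 0", call. = FALSE)
  }
  score <- sum(v[matched])
  tibble::tibble(
    record_id = doc$record_id,
    score = score,
    n_matched = sum(matched),
    polarity = if (score > 0) "positive" else if (score < 0) "negative" else zero_polarity
  )
}

#' Sentiment scores for a document set
#'
#' @param docs Named list of `tokenized_document`s.
#' @inheritParams score_document
#' @return Tibble with one row per document (see [score_document()]).
#' @export
score_corpus <- function(docs, cascade, zero_polarity = c("negative", "positive")) {
  zero_polarity <- match.arg(zero_polarity)
  res <- withCallingHandlers(
    dplyr::bind_rows(lapply(docs, score_document, cascade = cascade,
                            zero_polarity = zero_polarity)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  n_zero <- sum(res$n_matched == 0)
  if (n_zero > 0) {
    message(n_zero, " document(s) had no lexicon matches (score 0)")
  }
  res
}

#' Polarity distribution per diagnostic group
#'
#' @param results Tibble from [score_corpus()].
#' @param labels Named character vector or corpus mapping `record_id` to
#'   diagnosis; every scored record must be labelled.
#' @return Tibble (`group`, `n`, `n_negative`, `n_positive`, `pct_negative`,
#'   `pct_positive`); groups are `all` plus each diagnosis label.
#'   Percentages sum to 100 within each group.
#' @export
polarity_distribution <- function(results, labels) {
  if (inherits(labels, "data.frame")) {
    labels <- stats::setNames(labels$diagnosis, labels$record_id)
  }
  lab <- labels[results$record_id]
  if (anyNA(lab)) {
    stop("unlabelled record '", results$record_id[which(is.na(lab))[1]], "'",
         call. = FALSE)
  }
  df <- dplyr::mutate(results, group = unname(lab))
  groups <- c("all", intersect(diagnosis_labels(), unique(df$group)))
  rows <- lapply(groups, function(g) {
    sub <- if (g == "all") df else df[df$group == g, ]
    n <- nrow(sub)
    nn <- sum(sub$polarity == "negative")
    tibble::tibble(group = g, n = n, n_negative = nn, n_positive = n - nn,
                   pct_negative = 100 * nn / n,
                   pct_positive = 100 * (n - nn) / n)
  })
  dplyr::bind_rows(rows)
}
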