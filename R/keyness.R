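#' Build a target/reference word-frequency table
#'
#' Aggregates token counts over all documents of a target group and a
#' reference group. Every word type occurring in either group gets a row.
#'
#' @param docs_target,docs_reference Lists of `tokenized_document`s.
#' @return Object of class `frequency_table`: list with `group_totals`
#'   (named numeric, `target`/`reference`) and `types` (tibble `word`, `a`,
#'   `b` = counts of the word in target/reference).
#' @export
build_frequency_table <- function(docs_target, docs_reference) {
  count_group <- function(docs, label) {
    if (!length(docs)) stop("empty ", label, " group", call. = FALSE)
    toks <- unlist(lapply(docs, doc_tokens), use.names = FALSE)
    if (!length(toks)) stop("no tokens in ", label, " group", call. = FALSE)
    table(toks)
  }
  ta <- count_group(docs_target, "target")
  tb <- count_group(docs_reference, "reference")
  words <- sort(unique(c(names(ta), names(tb))))
  a <- as.numeric(ta[words]); a[is.na(a)] <- 0
  b <- as.numeric(tb[words]); b[is.na(b)] <- 0
  structure(
    list(
      group_totals = c(target = sum(a), reference = sum(b)),
      types = tibble::tibble(word = words, a = a, b = b)
    ),
    class = "frequency_table"
  )
}

#' Significance tier of a keyness p-value
#'
#' Tiers follow the conventional keyword-plot legend: `"*"` for p < 1e-2,
#' `"**"` for p < 1e-5, `"***"` for p < 1e-8, `"ns"` otherwise. The tier is
#' a step function of p with breakpoints exactly at those thresholds
#' (strict inequalities).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Character vector of tiers.
#' @export
keyness_tier <- function(p) {
  out <- rep("ns", length(p))
  out[p < 1e-2] <- "*"
  out[p < 1e-5] <- "**"
  out[p < 1e-8] <- "***"
  out
}

#' 2x2 chi-square keyness statistic
#'
#' For one word type, `a`/`b` are its counts in the target/reference group
#' and `c`/`d` the counts of all other tokens in each group. The statistic is
#' the classical 2x2 chi-square
#' \deqn{\chi^2 = N(|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))}
#' with the Yates continuity term `N/2` applied by default (clamped at zero,
#' as in `chisq.test`); set `correct = FALSE` for the uncorrected statistic.
#' Direction is `target` when the word is relatively more frequent in the
#' target group. The p-value comes from the chi-square distribution with one
#' degree of freedom.
#'
#' @param a,b,c,d Non-negative counts (vectorised).
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return Tibble with columns `chi2`, `direction`, `p_value`, `tier`.
#' @export
keyness_chi2 <- function(a, b, c, d, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(a + c <= 0) || any(b + d <= 0)) {
    stop("both group totals must be positive", call. = FALSE)
  }
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (correct) dev <- pmax(0, dev - n / 2)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, n * dev^2 / denom, 0)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- ifelse(a / (a + c) > b / (b + d), "target", "reference")
  tibble::tibble(chi2 = chi2, direction = direction, p_value = p,
                 tier = keyness_tier(p))
}

#' Rank key words by chi-square keyness
#'
#' Computes the keyness statistic for every word type with total count
#' `a + b >= min_count`, ranked by chi-square descending with alphabetical
#' tie-break. Word types absent from both groups are excluded.
#'
#' @param table A `frequency_table`.
#' @param min_count Minimum combined count for a word to be tested
#'   (default 5; suppresses unstable single-occurrence keys).
#' @param correct Continuity correction, passed to [keyness_chi2()].
#' @return Tibble with columns `word`, `a`, `b`, `c`, `d`, `chi2`,
#'   `direction`, `p_value`, `tier`, sorted by decreasing `chi2`.
#' @export
rank_keywords <- function(table, min_count = 5, correct = TRUE) {
  stopifnot(inherits(table, "frequency_table"), min_count >= 1)
  tt <- table$types
  tt <- tt[tt$a + tt$b >= min_count & tt$a + tt$b > 0, , drop = FALSE]
  if (!nrow(tt)) {
    return(tibble::tibble(word = character(0), a = numeric(0), b = numeric(0),
                          c = numeric(0), d = numeric(0), chi2 = numeric(0),
                          direction = character(0), p_value = numeric(0),
                          tier = character(0)))
  }
  cc <- table$group_totals[["target"]] - tt$a
  dd <- table$group_totals[["reference"]] - tt$b
  res <- keyness_chi2(tt$a, tt$b, cc, dd, correct = correct)
  out <- tibble::tibble(word = tt$word, a = tt$a, b = tt$b, c = cc, d = dd,
                        chi2 = res$chi2, direction = res$direction,
                        p_value = res$p_value, tier = res$tier)
  out[order(-out$chi2, out$word), , drop = FALSE]
}

#' Keyness analysis between two diagnostic groups
#'
#' Convenience wrapper: splits a tokenized document set by label, builds the
#' frequency table and ranks keywords. Keyness is meant to be run on the
#' blocklist- and stop-word-filtered token stream so that the ranked keys
#' are content words.
#'
#' @param docs Named list of `tokenized_document`s.
#' @param labels Named character vector or tibble mapping `record_id` to
#'   diagnosis (a `narrative_corpus` works).
#' @param target Target group label (default `"cluster_headache"`).
#' @param reference Reference group label (default `"migraine"`).
#' @inheritParams rank_keywords
#' @return As [rank_keywords()].
#' @export
keyness_analysis <- function(docs, labels, target = "cluster_headache",
                             reference = "migraine", min_count = 5,
                             correct = TRUE) {
  if (inherits(labels, "data.frame")) {
    lab <- stats::setNames(labels$diagnosis, labels$record_id)
  } else {
    lab <- labels
  }
  ids <- names(docs)
  ft <- build_frequency_table(docs[ids[lab[ids] == target & !is.na(lab[ids])]],
                              docs[ids[lab[ids] == reference & !is.na(lab[ids])]])
  rank_keywords(ft, min_count = min_count, correct = correct)
}
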