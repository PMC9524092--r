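#' Demographic and textual summaries per diagnostic group
#'
#' For each diagnosis label and for the pooled cohort (`"all"`): record
#' count, mean (SD) age, number and percentage of female patients, and
#' median (Q1–Q3) of per-text token, type and sentence counts. Counts are
#' summarised with quartiles because their distribution across patients is
#' strongly right-skewed. Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7) so results are deterministic.
#'
#' @param corpus A `narrative_corpus` with `diagnosis`, `age` and `sex`
#'   present for every record.
#' @param docs Named list of `tokenized_document`s covering every record.
#' @return Tibble with one row per group (`all` first), columns `group`,
#'   `n`, `age_mean`, `age_sd`, `n_female`, `pct_female`,
#'   `{tokens,types,sentences}_{median,q1,q3}`.
#' @export
summarize_corpus <- function(corpus, docs) {
  missing_doc <- setdiff(corpus$record_id, names(docs))
  if (length(missing_doc)) {
    stop("no tokenized document for record_id '", missing_doc[1], "'",
         call. = FALSE)
  }
  need <- is.na(corpus$age) | is.na(corpus$sex) | is.na(corpus$diagnosis)
  if (any(need)) {
    stop("missing diagnosis/age/sex for record_id '",
         corpus$record_id[which(need)[1]], "'", call. = FALSE)
  }
  stats_tbl <- corpus_token_stats(docs[corpus$record_id])
  df <- dplyr::left_join(
    tibble::as_tibble(corpus)[, c("record_id", "diagnosis", "age", "sex")],
    stats_tbl, by = "record_id"
  )
  groups <- c("all", intersect(diagnosis_labels(), unique(df$diagnosis)))
  rows <- lapply(groups, function(g) {
    sub <- if (g == "all") df else df[df$diagnosis == g, ]
    q <- function(x) stats::quantile(x, c(.25, .5, .75), type = 7, names = FALSE)
    qt <- q(sub$tokens); qy <- q(sub$types); qs <- q(sub$sentences)
    tibble::tibble(
      group = g,
      n = nrow(sub),
      age_mean = mean(sub$age),
      age_sd = stats::sd(sub$age),
      n_female = sum(sub$sex == "female"),
      pct_female = 100 * mean(sub$sex == "female"),
      tokens_median = qt[2], tokens_q1 = qt[1], tokens_q3 = qt[3],
      types_median = qy[2], types_q1 = qy[1], types_q3 = qy[3],
      sentences_median = qs[2], sentences_q1 = qs[1], sentences_q3 = qs[3]
    )
  })
  dplyr::bind_rows(rows)
}
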