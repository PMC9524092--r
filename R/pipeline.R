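#' Run the full narrative-analysis workflow
#'
#' Orchestrates the stages in dependency order on a synthetic corpus (or a
#' caller-supplied one): preprocessing, group summaries, keyness, theme
#' proportions, attack-description extraction, cascade sentiment, and
#' nested cross-validated classification. Writes `table_characteristics.csv`,
#' `keyness.csv`, `table_themes.csv`, `table_sentiment.csv`,
#' `classification_report.json` and a `manifest.json` carrying the seed,
#' package version and MD5 hash of every output, so that a re-run with the
#' same inputs and seed reproduces identical artefacts.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed for generation and cross-validation.
#' @param config A `generator_config` used when `gen` is not supplied.
#' @param gen Optional pre-generated result of [generate_corpus()].
#' @param algorithms Classifiers to evaluate (nested stratified 5-fold,
#'   n-gram features).
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(outdir, seed = 17L, config = generator_config(),
                         gen = NULL,
                         algorithms = c("logistic_regression", "svm_linear",
                                        "naive_bayes")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- gen %||% generate_corpus(config, seed = seed)
  corpus <- gen$corpus
  blocklist <- default_blocklist()
  stopwords <- default_stopwords()

  docs_raw <- tokenize_corpus(corpus)
  tab1 <- summarize_corpus(corpus, docs_raw)

  docs_ml <- preprocess_corpus(corpus, blocklist = blocklist,
                               stopwords = stopwords)
  keys <- keyness_analysis(docs_ml, corpus)

  props <- theme_proportions_corpus(docs_raw, gen$annotations)
  tab2 <- summarize_themes(props, corpus)

  attacks <- extract_theme_subcorpus(corpus, gen$annotations,
                                     "attack_description")
  docs_sent <- preprocess_corpus(attacks, blocklist = blocklist,
                                 keep_stopwords = TRUE)
  sent <- suppressMessages(score_corpus(docs_sent, gen$cascade))
  tab3 <- polarity_distribution(sent, attacks)

  docs_attack_ml <- preprocess_corpus(attacks, blocklist = blocklist,
                                      stopwords = stopwords)
  reports <- lapply(algorithms, function(alg) {
    rep <- nested_cv(attacks, docs_attack_ml, feature_spec_group("ngrams"),
                     classifier_spec(alg), cv_plan(seed = seed))
    list(classifier = alg, features = "ngrams",
         aggregate = rep$aggregate,
         per_fold = rep$per_fold,
         chosen_params = rep$chosen_params)
  })

  paths <- c(
    table_characteristics = file.path(outdir, "table_characteristics.csv"),
    keyness = file.path(outdir, "keyness.csv"),
    table_themes = file.path(outdir, "table_themes.csv"),
    table_sentiment = file.path(outdir, "table_sentiment.csv"),
    classification_report = file.path(outdir, "classification_report.json")
  )
  utils::write.csv(tab1, paths["table_characteristics"], row.names = FALSE)
  utils::write.csv(keys, paths["keyness"], row.names = FALSE)
  utils::write.csv(tab2, paths["table_themes"], row.names = FALSE)
  utils::write.csv(tab3, paths["table_sentiment"], row.names = FALSE)
  writeLines(jsonlite::toJSON(reports, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             paths["classification_report"], useBytes = TRUE)

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("headachetext")),
    n_records = nrow(corpus),
    label_counts = as.list(label_counts(corpus)),
    n_attack_records = nrow(attacks),
    outputs = lapply(stats::setNames(nm = names(paths)), function(k) {
      list(path = basename(paths[[k]]),
           md5 = unname(tools::md5sum(paths[[k]])))
    })
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(outdir, "manifest.json"), useBytes = TRUE)
  invisible(manifest)
}
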