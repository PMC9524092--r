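#' Cross-validation plan
#'
#' @param scheme `"stratified_kfold"` (default) or `"loocv"`.
#' @param k_outer Outer folds (default 5).
#' @param k_inner Inner folds for the hyperparameter grid search (default 5).
#' @param seed Integer seed governing all fold draws.
#' @return Object of class `cv_plan`. The optimization metric of the inner
#'   grid search is always the macro-averaged F1.
#' @export
cv_plan <- function(scheme = c("stratified_kfold", "loocv"), k_outer = 5L,
                    k_inner = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "stratified_kfold" && k_outer < 2L) {
    stop("k_outer must be at least 2", call. = FALSE)
  }
  if (k_inner < 2L) stop("k_inner must be at least 2", call. = FALSE)
  structure(list(scheme = scheme, k_outer = as.integer(k_outer),
                 k_inner = as.integer(k_inner), seed = as.integer(seed),
                 optimization_metric = "macro_f1"),
            class = "cv_plan")
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * k) %% 2147483629)
}

#' Stratified fold assignment
#'
#' Partitions instances into `k` folds whose per-class counts differ by at
#' most one instance from the globally achievable proportion; fold totals are
#' balanced by assigning each class's remainder instances to the currently
#' smallest folds. Deterministic given `seed`. With `scheme = "loocv"` each
#' instance is its own test fold.
#'
#' @param labels Vector/factor of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param scheme `"stratified_kfold"` or `"loocv"`.
#' @return Integer vector of fold ids (1..k), one per instance.
#' @export
make_folds <- function(labels, k, seed = 1L,
                       scheme = c("stratified_kfold", "loocv")) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  if (scheme == "loocv") return(seq_len(n))
  labels <- as.character(labels)
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) < 2L) {
    stop("stratified folds need at least 2 classes", call. = FALSE)
  }
  if (k > min(tab)) {
    stop("k = ", k, " exceeds the size of the smallest class (", min(tab), ")",
         call. = FALSE)
  }
  fold_of <- integer(n)
  totals <- numeric(k)
  withr::with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      base <- length(idx) %/% k
      r <- length(idx) %% k
      counts <- rep.int(base, k)
      if (r > 0) {
        ord <- order(totals, seq_len(k))
        counts[ord[seq_len(r)]] <- base + 1L
      }
      fold_of[idx] <- rep.int(seq_len(k), counts)
      totals <- totals + counts
    }
  })
  fold_of
}

corpus_label_factor <- function(corpus) {
  lv <- intersect(diagnosis_labels(), unique(corpus$diagnosis))
  y <- factor(corpus$diagnosis, levels = lv)
  if (anyNA(y)) {
    stop("unlabelled record '", corpus$record_id[which(is.na(y))[1]],
         "' cannot enter classification", call. = FALSE)
  }
  stats::setNames(y, corpus$record_id)
}

# Inner stratified grid search over the classifier's hyperparameter grid,
# maximising macro-F1 averaged over inner folds. Matrices are built once per
# inner split and shared across grid values. First-listed value wins ties.
inner_grid_search <- function(counts, corpus, labels_by_id, train_ids,
                              feature_spec, classifier_spec, k_inner, seed,
                              standardize) {
  y_train <- droplevels(labels_by_id[train_ids])
  if (nlevels(y_train) < 2L) {
    stop("training portion contains a single class", call. = FALSE)
  }
  inner <- make_folds(y_train, k_inner, seed = seed)
  grid <- classifier_spec$hyper_grid
  scores <- matrix(NA_real_, nrow = length(grid), ncol = k_inner)
  inner_train_sets <- vector("list", k_inner)
  for (g in seq_len(k_inner)) {
    itr <- train_ids[inner != g]
    ite <- train_ids[inner == g]
    inner_train_sets[[g]] <- itr
    fz <- fit_featurizer(counts, corpus, feature_spec, itr,
                         standardize_age = standardize)
    xtr <- transform_features(fz, counts, corpus, itr)
    xte <- transform_features(fz, counts, corpus, ite)
    models <- fit_model_grid(xtr, labels_by_id[itr], classifier_spec$algorithm,
                             grid)
    for (p in seq_along(grid)) {
      pred <- predict_model(models[[p]], xte)
      scores[p, g] <- compute_metrics(as.character(labels_by_id[ite]),
                                      as.character(pred),
                                      classes = levels(labels_by_id),
                                      warn = FALSE)$macro_f1
    }
  }
  mean_scores <- rowMeans(scores)
  list(best_param = grid[which.max(mean_scores)],
       mean_scores = stats::setNames(mean_scores, grid),
       inner_folds = inner,
       inner_train_sets = inner_train_sets)
}

flatten_metrics <- function(met) {
  out <- c(accuracy = met$accuracy, macro_f1 = met$macro_f1)
  for (i in seq_len(nrow(met$per_class))) {
    cl <- met$per_class$class[i]
    out[paste0("precision_", cl)] <- met$per_class$precision[i]
    out[paste0("recall_", cl)] <- met$per_class$recall[i]
    out[paste0("f1_", cl)] <- met$per_class$f1[i]
  }
  out
}

#' Nested stratified cross-validation
#'
#' Outer stratified k-fold evaluation with an inner stratified k-fold grid
#' search inside every outer training portion, so hyperparameter selection
#' never sees the outer test fold. The winning hyperparameter value is refit
#' on the full outer training portion and evaluated on the held-out fold;
#' reported metrics are averages over the outer folds. The n-gram vocabulary
#' and age standardization are refit from scratch inside every training
#' portion (inner ones included).
#'
#' @param corpus A fully labelled `narrative_corpus`.
#' @param docs Named list of pre-processed `tokenized_document`s.
#' @param feature_spec A `feature_spec`.
#' @param classifier_spec A `classifier_spec`.
#' @param plan A `cv_plan` (scheme `stratified_kfold`).
#' @param audit Keep per-fold fold memberships, vocabulary and
#'   standardization statistics for leakage auditing.
#' @return An `evaluation_report`: per-fold metrics and chosen
#'   hyperparameters, their across-fold means (`aggregate`), pooled
#'   predictions, and (optionally) audit data.
#' @export
nested_cv <- function(corpus, docs, feature_spec, classifier_spec,
                      plan = cv_plan(), audit = FALSE) {
  labels_by_id <- corpus_label_factor(corpus)
  ids <- corpus$record_id
  counts <- precompute_ngram_counts(docs[ids], feature_spec)
  standardize <- classifier_spec$algorithm != "naive_bayes"
  outer <- make_folds(labels_by_id[ids], plan$k_outer, seed = plan$seed)
  fold_rows <- list()
  audit_info <- if (audit) vector("list", plan$k_outer)
  pooled <- tibble::tibble(record_id = character(0), truth = character(0),
                           prediction = character(0), fold = integer(0))
  for (f in seq_len(plan$k_outer)) {
    test_ids <- ids[outer == f]
    train_ids <- ids[outer != f]
    gs <- inner_grid_search(counts, corpus, labels_by_id, train_ids,
                            feature_spec, classifier_spec, plan$k_inner,
                            seed = derive_seed(plan$seed, f),
                            standardize = standardize)
    fz <- fit_featurizer(counts, corpus, feature_spec, train_ids,
                         standardize_age = standardize)
    xtr <- transform_features(fz, counts, corpus, train_ids)
    xte <- transform_features(fz, counts, corpus, test_ids)
    model <- fit_model(xtr, labels_by_id[train_ids],
                       classifier_spec$algorithm, gs$best_param)
    pred <- predict_model(model, xte)
    met <- compute_metrics(as.character(labels_by_id[test_ids]),
                           as.character(pred),
                           classes = levels(labels_by_id), warn = FALSE)
    fold_rows[[f]] <- tibble::as_tibble(c(
      list(fold = f, chosen_param = gs$best_param),
      as.list(flatten_metrics(met))
    ))
    pooled <- dplyr::bind_rows(pooled, tibble::tibble(
      record_id = test_ids,
      truth = as.character(labels_by_id[test_ids]),
      prediction = as.character(pred),
      fold = f
    ))
    if (audit) {
      audit_info[[f]] <- list(
        test_ids = test_ids,
        train_ids = train_ids,
        inner_train_sets = gs$inner_train_sets,
        vocab = fz$vocab,
        vocab_hash = rlang::hash(fz$vocab),
        age_mean = fz$age_mean,
        age_sd = fz$age_sd
      )
    }
  }
  per_fold <- dplyr::bind_rows(fold_rows)
  agg <- as.list(colMeans(per_fold[, setdiff(names(per_fold),
                                             c("fold", "chosen_param"))]))
  structure(list(
    scheme = "nested_stratified_kfold",
    algorithm = classifier_spec$algorithm,
    feature_spec = feature_spec,
    k_outer = plan$k_outer, k_inner = plan$k_inner, seed = plan$seed,
    classes = levels(labels_by_id),
    per_fold = per_fold,
    aggregate = agg,
    chosen_params = per_fold$chosen_param,
    pooled = pooled,
    pooled_metrics = compute_metrics(pooled$truth, pooled$prediction,
                                     classes = levels(labels_by_id),
                                     warn = FALSE),
    audit = if (audit) audit_info
  ), class = "evaluation_report")
}

#' Leave-one-out cross-validation
#'
#' N rounds, each holding out a single narrative; the hyperparameter grid
#' search remains a stratified `k_inner`-fold search inside each round's
#' training portion (singleton test folds cannot be stratified, so the outer
#' loop is plain leave-one-out). Metrics are computed over the pooled N
#' single-item predictions.
#'
#' @inheritParams nested_cv
#' @param k_inner Inner folds for the grid search.
#' @param seed Integer seed.
#' @return An `evaluation_report` (scheme `loocv`); `aggregate` holds the
#'   pooled metrics.
#' @export
loocv <- function(corpus, docs, feature_spec, classifier_spec, k_inner = 5L,
                  seed = 1L) {
  labels_by_id <- corpus_label_factor(corpus)
  ids <- corpus$record_id
  counts <- precompute_ngram_counts(docs[ids], feature_spec)
  standardize <- classifier_spec$algorithm != "naive_bayes"
  rounds <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    test_ids <- ids[i]
    train_ids <- ids[-i]
    gs <- inner_grid_search(counts, corpus, labels_by_id, train_ids,
                            feature_spec, classifier_spec, k_inner,
                            seed = derive_seed(seed, i),
                            standardize = standardize)
    fz <- fit_featurizer(counts, corpus, feature_spec, train_ids,
                         standardize_age = standardize)
    xtr <- transform_features(fz, counts, corpus, train_ids)
    xte <- transform_features(fz, counts, corpus, test_ids)
    model <- fit_model(xtr, labels_by_id[train_ids],
                       classifier_spec$algorithm, gs$best_param)
    pred <- predict_model(model, xte)
    rounds[[i]] <- tibble::tibble(
      record_id = test_ids,
      truth = as.character(labels_by_id[test_ids]),
      prediction = as.character(pred),
      fold = i,
      chosen_param = gs$best_param
    )
  }
  pooled <- dplyr::bind_rows(rounds)
  met <- compute_metrics(pooled$truth, pooled$prediction,
                         classes = levels(labels_by_id), warn = FALSE)
  structure(list(
    scheme = "loocv",
    algorithm = classifier_spec$algorithm,
    feature_spec = feature_spec,
    k_inner = k_inner, seed = seed,
    classes = levels(labels_by_id),
    per_fold = pooled,
    aggregate = as.list(flatten_metrics(met)),
    chosen_params = pooled$chosen_param,
    pooled = pooled[, c("record_id", "truth", "prediction", "fold")],
    pooled_metrics = met,
    audit = NULL
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$algorithm, ", scheme ", x$scheme, "\n", sep = "")
  cat("  accuracy: ", round(x$aggregate$accuracy, 3),
      "  macro-F1: ", round(x$aggregate$macro_f1, 3), "\n", sep = "")
  invisible(x)
}

#' Run the full classifier-by-feature-group evaluation grid
#'
#' Evaluates the three classifiers crossed with the three feature groups
#' (n-grams, metadata, n-grams + metadata) under one cross-validation plan
#' and returns one row per setup.
#'
#' @inheritParams nested_cv
#' @param algorithms Classifier names to include.
#' @param groups Feature-group names to include.
#' @return Tibble with one row per classifier-by-feature-group setup and the
#'   averaged metrics as columns.
#' @export
evaluate_grid <- function(corpus, docs, plan = cv_plan(),
                          algorithms = c("naive_bayes", "svm_linear",
                                         "logistic_regression"),
                          groups = c("ngrams", "metadata", "ngrams_metadata")) {
  rows <- list()
  for (alg in algorithms) {
    for (grp in groups) {
      rep <- nested_cv(corpus, docs, feature_spec_group(grp),
                       classifier_spec(alg), plan)
      rows[[length(rows) + 1L]] <- tibble::as_tibble(c(
        list(classifier = alg, features = grp), rep$aggregate
      ))
    }
  }
  dplyr::bind_rows(rows)
}
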