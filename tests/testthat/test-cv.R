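test_that("stratified folds partition with near-constant label distribution", {
  labels <- c(rep("migraine", 74), rep("cluster_headache", 38))
  for (seed in c(1, 7, 99)) {
    folds <- make_folds(labels, 5, seed = seed)
    expect_identical(sort(unique(folds)), 1:5)
    sizes <- as.integer(table(folds))
    expect_identical(sort(sizes), c(22L, 22L, 22L, 23L, 23L))
    minority <- as.integer(table(folds[labels == "cluster_headache"]))
    expect_true(all(minority %in% c(7L, 8L)))
    # a partition: every instance in exactly one fold
    expect_length(folds, 112L)
  }
  # determinism
  expect_identical(make_folds(labels, 5, seed = 3),
                   make_folds(labels, 5, seed = 3))
  expect_false(identical(make_folds(labels, 5, seed = 3),
                         make_folds(labels, 5, seed = 4)))

  expect_identical(make_folds(rep(c("a", "b"), 5), 3, scheme = "loocv"), 1:10)
  expect_error(make_folds(c(rep("a", 10), "b"), 5), "smallest class")
  expect_error(make_folds(rep("a", 10), 2), "at least 2 classes")
})

test_that("each classifier separates a disjoint-vocabulary corpus perfectly", {
  corp <- separable_corpus(10)
  docs <- tokenize_corpus(corp)
  spec <- feature_spec(word_ngrams = TRUE, char_ngrams = FALSE)
  for (alg in c("naive_bayes", "svm_linear", "logistic_regression")) {
    rep <- nested_cv(corp, docs, spec, classifier_spec(alg),
                     cv_plan(k_outer = 5, k_inner = 2, seed = 1))
    expect_equal(rep$aggregate$accuracy, 1)
    expect_equal(rep$aggregate$macro_f1, 1)
  }
})

test_that("naive Bayes posteriors match a hand-computed toy example", {
  # two training docs per class over vocabulary {p, q}; alpha = 1
  x <- Matrix::sparseMatrix(i = c(1, 1, 2, 3, 4, 4),
                            j = c(1, 2, 1, 2, 2, 1),
                            x = c(3, 1, 2, 4, 3, 1),
                            dims = c(4, 2),
                            dimnames = list(NULL, c("p", "q")))
  y <- factor(c("migraine", "migraine", "cluster_headache", "cluster_headache"),
              levels = c("migraine", "cluster_headache"))
  m <- fit_model(x, y, "naive_bayes", 1)
  # class migraine: counts p = 5, q = 1 -> theta = (6/8, 2/8)
  # class cluster:  counts p = 1, q = 7 -> theta = (2/10, 8/10)
  xt <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(2, 2),
                             dims = c(2, 2),
                             dimnames = list(NULL, c("p", "q")))
  pred <- predict_model(m, xt)
  ll_m <- 2 * log(6 / 8); ll_c <- 2 * log(2 / 10)
  expect_identical(as.character(pred[1]),
                   if (ll_m > ll_c) "migraine" else "cluster_headache")
  expect_identical(as.character(pred), c("migraine", "cluster_headache"))
})

test_that("nested CV reports per-fold metrics, their means, chosen params", {
  gen <- generate_corpus(small_signal_config(), seed = 13)
  docs <- preprocess_corpus(gen$corpus, blocklist = default_blocklist(),
                            stopwords = default_stopwords())
  spec <- feature_spec(TRUE, FALSE)
  rep <- nested_cv(gen$corpus, docs, spec,
                   classifier_spec("logistic_regression"),
                   cv_plan(k_outer = 3, k_inner = 3, seed = 2))
  expect_identical(nrow(rep$per_fold), 3L)
  expect_equal(rep$aggregate$accuracy, mean(rep$per_fold$accuracy))
  expect_equal(rep$aggregate$macro_f1, mean(rep$per_fold$macro_f1))
  expect_true(all(rep$chosen_params %in% c(0.1, 1, 10, 100)))
  expect_true(all(unlist(rep$aggregate) >= 0 & unlist(rep$aggregate) <= 1))
  # every record tested exactly once
  expect_setequal(rep$pooled$record_id, gen$corpus$record_id)

  # bitwise reproducibility
  rep2 <- nested_cv(gen$corpus, docs, spec,
                    classifier_spec("logistic_regression"),
                    cv_plan(k_outer = 3, k_inner = 3, seed = 2))
  expect_equal(rep[setdiff(names(rep), "audit")],
               rep2[setdiff(names(rep2), "audit")])
})

test_that("LOOCV pools single predictions that match per-round refits", {
  corp <- as_corpus(tibble::tibble(
    record_id = sprintf("r%d", 1:6),
    text = c("bonk dalf bonk gorm", "dalf bonk gorm bonk", "bonk gorm dalf",
             "pelt nusk pelt fiam", "nusk pelt fiam", "pelt fiam nusk nusk"),
    diagnosis = rep(c("migraine", "cluster_headache"), each = 3),
    age = c(31L, 42L, 53L, 44L, 55L, 66L),
    sex = rep(c("female", "male"), 3)))
  docs <- tokenize_corpus(corp)
  spec <- feature_spec(TRUE, FALSE, n_range = c(1, 1))
  cls <- classifier_spec("naive_bayes", hyper_grid = 1)
  rep <- loocv(corp, docs, spec, cls, k_inner = 2, seed = 5)
  expect_identical(nrow(rep$pooled), 6L)
  expect_identical(sort(rep$pooled$record_id), sort(corp$record_id))

  # oracle: six independent single-round fits at the same (only) grid value
  counts <- headachetext:::precompute_ngram_counts(docs, spec)
  oracle <- vapply(seq_len(6), function(i) {
    tr <- corp$record_id[-i]
    fx <- extract_features(docs, corp, spec, fit_ids = tr,
                           transform_ids = corp$record_id[i],
                           standardize_age = FALSE)
    y <- factor(corp$diagnosis[-i], levels = diagnosis_labels())
    m <- fit_model(fx$train, y, "naive_bayes", 1)
    as.character(predict_model(m, fx$test))
  }, character(1))
  expect_identical(rep$pooled$prediction, oracle)
  expect_equal(rep$aggregate$accuracy,
               mean(oracle == corp$diagnosis))

  # determinism
  rep2 <- loocv(corp, docs, spec, cls, k_inner = 2, seed = 5)
  expect_equal(rep$pooled, rep2$pooled)
})

test_that("single-class training data is rejected", {
  corp <- separable_corpus(3)
  docs <- tokenize_corpus(corp)
  only_m <- corp[corp$diagnosis == "migraine", ]
  class(only_m) <- class(corp)
  expect_error(
    nested_cv(only_m, docs, feature_spec(TRUE, FALSE),
              classifier_spec("naive_bayes"), cv_plan(k_outer = 2, seed = 1)),
    "2 classes")
})

test_that("the evaluation grid covers classifiers crossed with feature groups", {
  gen <- generate_corpus(small_signal_config(), seed = 23)
  docs <- preprocess_corpus(gen$corpus, blocklist = default_blocklist(),
                            stopwords = default_stopwords())
  out <- evaluate_grid(gen$corpus, docs,
                       plan = cv_plan(k_outer = 3, k_inner = 2, seed = 3),
                       algorithms = c("naive_bayes", "logistic_regression"),
                       groups = c("metadata", "ngrams"))
  expect_identical(nrow(out), 4L)
  expect_setequal(out$classifier, c("naive_bayes", "logistic_regression"))
  expect_true(all(out$accuracy >= 0 & out$accuracy <= 1))
})
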