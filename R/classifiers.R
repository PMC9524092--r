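#' Classifier specification
#'
#' The three study classifiers with their hyperparameter grid. One scalar
#' hyperparameter is gridded per algorithm: the regularization parameter C
#' for the linear SVM and logistic regression, and the additive-smoothing
#' strength for multinomial naive Bayes. The default grid `{0.1, 1, 10,
#' 100}` is the log grid over the 0.1–100 range. Class weighting is always
#' balanced: uniform class priors for naive Bayes, inverse-class-frequency
#' weights for SVM and logistic regression.
#'
#' @param algorithm `"naive_bayes"`, `"svm_linear"` or
#'   `"logistic_regression"`.
#' @param hyper_grid Numeric vector of candidate hyperparameter values.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("logistic_regression", "svm_linear",
                                          "naive_bayes"),
                            hyper_grid = c(0.1, 1, 10, 100)) {
  algorithm <- match.arg(algorithm)
  if (!length(hyper_grid)) stop("hyper_grid must be non-empty", call. = FALSE)
  structure(list(algorithm = algorithm, hyper_grid = as.numeric(hyper_grid)),
            class = "classifier_spec")
}

balanced_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  as.numeric(w[as.character(y)])
}

fit_nb <- function(x, y, alpha) {
  lvls <- levels(y)
  logtheta <- matrix(0, nrow = length(lvls), ncol = ncol(x),
                     dimnames = list(lvls, colnames(x)))
  for (cl in lvls) {
    cnt <- Matrix::colSums(x[y == cl, , drop = FALSE]) + alpha
    logtheta[cl, ] <- log(cnt) - log(sum(cnt))
  }
  # balanced class weighting realised as uniform log-priors
  list(logtheta = logtheta, logprior = log(rep(1 / length(lvls), length(lvls))),
       levels = lvls)
}

predict_nb <- function(model, x) {
  scores <- as.matrix(x %*% t(model$logtheta))
  scores <- sweep(scores, 2, model$logprior, `+`)
  # deterministic tie-break: first level wins
  factor(model$levels[max.col(scores, ties.method = "first")],
         levels = model$levels)
}

# Linear SVM via libsvm (e1071), fed the sparse feature matrix directly so
# the optimiser skips zero entries; balanced class weights; scale = FALSE
# because n-gram counts share one natural scale and binary/metadata columns
# must not be re-centred.
fit_svm <- function(x, y, cost) {
  tab <- table(y)
  cw <- stats::setNames(as.numeric(length(y) / (length(tab) * tab)), names(tab))
  e1071::svm(x, y, kernel = "linear", cost = cost,
             class.weights = cw, scale = FALSE)
}

predict_svm <- function(model, x) {
  stats::predict(model, x)
}

# map the C grid onto glmnet's ridge penalty: lambda = 1 / (C * n). Fitting
# the whole (decreasing) lambda path in one call exploits glmnet's warm
# starts; each grid value then reads its own s off the shared path.
fit_lr_path <- function(x, y, cost_grid) {
  lam <- 1 / (cost_grid * nrow(x))
  path <- sort(unique(c(max(lam) * c(100, 10), lam)), decreasing = TRUE)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = path,
                   weights = balanced_weights(y), standardize = FALSE,
                   thresh = 1e-6),
    # expected on small inner folds; the report carries per-fold sizes
    warning = function(w) {
      if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  list(fit = fit, s = stats::setNames(lam, cost_grid))
}

#' Fit classifiers for every value of a hyperparameter grid
#'
#' Equivalent to calling [fit_model()] per grid value, but logistic
#' regression shares one warm-started regularization path across the grid.
#'
#' @inheritParams fit_model
#' @param grid Numeric vector of hyperparameter values.
#' @return List of `headache_model`s, one per grid value, in grid order.
#' @export
fit_model_grid <- function(x, y, algorithm, grid) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  if (algorithm == "logistic_regression") {
    lp <- fit_lr_path(x, y, grid)
    return(lapply(seq_along(grid), function(i) {
      structure(list(algorithm = algorithm, param = grid[i],
                     fit = lp$fit, s = unname(lp$s[i]), levels = levels(y)),
                class = "headache_model")
    }))
  }
  lapply(grid, function(p) fit_model(x, y, algorithm, p))
}

#' Fit one classifier at a fixed hyperparameter value
#'
#' @param x Feature matrix (sparse `dgCMatrix`), rows = instances.
#' @param y Factor of class labels (2 levels).
#' @param algorithm See [classifier_spec()].
#' @param param Hyperparameter value (C, or NB smoothing strength).
#' @return Fitted model object of class `headache_model`.
#' @export
fit_model <- function(x, y, algorithm, param) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  if (algorithm == "logistic_regression") {
    lp <- fit_lr_path(x, y, param)
    return(structure(list(algorithm = algorithm, param = param, fit = lp$fit,
                          s = unname(lp$s[1]), levels = levels(y)),
                     class = "headache_model"))
  }
  fit <- switch(algorithm,
    naive_bayes = fit_nb(x, y, alpha = param),
    svm_linear = fit_svm(x, y, cost = param),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
  structure(list(algorithm = algorithm, param = param, fit = fit,
                 levels = levels(y)),
            class = "headache_model")
}

#' Predict class labels from a fitted model
#'
#' @param model A `headache_model`.
#' @param x Feature matrix with the same columns the model was fitted on.
#' @return Factor of predicted labels.
#' @export
predict_model <- function(model, x) {
  out <- switch(model$algorithm,
    naive_bayes = predict_nb(model$fit, x),
    svm_linear = predict_svm(model$fit, x),
    logistic_regression = {
      cls <- stats::predict(model$fit, newx = x, type = "class", s = model$s)
      factor(as.character(cls), levels = model$levels)
    }
  )
  factor(as.character(out), levels = model$levels)
}
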