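#' Classification metrics
#'
#' Per-class precision (positive predictive value), recall (sensitivity) and
#' their harmonic mean F1, plus overall accuracy and the macro-averaged F1
#' (unweighted mean of per-class F1, giving the minority class equal weight
#' under class imbalance). Undefined ratios (zero denominators) yield 0,
#' with a warning unless `warn = FALSE`.
#'
#' @param truth,predictions Equal-length label vectors.
#' @param classes Class order for the per-class table; defaults to the
#'   diagnosis labels present, otherwise sorted unique truth labels.
#' @param warn Warn on zero-division (default `TRUE`).
#' @return List with `accuracy`, `macro_f1`, and `per_class` tibble
#'   (`class`, `precision`, `recall`, `f1`, `support`).
#' @export
compute_metrics <- function(truth, predictions, classes = NULL, warn = TRUE) {
  truth <- as.character(truth)
  predictions <- as.character(predictions)
  if (length(truth) != length(predictions)) {
    stop("truth and predictions differ in length (", length(truth), " vs ",
         length(predictions), ")", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- intersect(diagnosis_labels(), unique(c(truth, predictions)))
    if (!length(classes)) classes <- sort(unique(truth))
  }
  safe_div <- function(num, den, what, cls) {
    if (den == 0) {
      if (warn) warning(what, " undefined for class '", cls,
                        "' (zero denominator); using 0", call. = FALSE)
      return(0)
    }
    num / den
  }
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & predictions == cl)
    fp <- sum(truth != cl & predictions == cl)
    fn <- sum(truth == cl & predictions != cl)
    p <- safe_div(tp, tp + fp, "precision", cl)
    r <- safe_div(tp, tp + fn, "recall", cl)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    tibble::tibble(class = cl, precision = p, recall = r, f1 = f1,
                   support = sum(truth == cl))
  })
  per <- dplyr::bind_rows(per)
  list(accuracy = mean(truth == predictions),
       macro_f1 = mean(per$f1),
       per_class = per)
}
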