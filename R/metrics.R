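#' Area under the ROC curve
#'
#' Computes the AUC as the probability that a randomly chosen positive-class
#' score exceeds a randomly chosen negative-class score, with ties counted as
#' one half (the Mann-Whitney formulation). Invariant under any strictly
#' increasing transform of the scores.
#'
#' @param scores Numeric vector of continuous classifier scores, higher
#'   meaning more class-1-like.
#' @param labels Vector of class labels coercible to 0/1; class 1 is the
#'   positive (post-treatment) class.
#' @return A single number in \[0, 1\].
#' @examples
#' roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  # rank-sum form of the Mann-Whitney U statistic; midranks handle ties
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix performance metrics
#'
#' Computes accuracy, sensitivity, specificity, balanced F-score (F1) and the
#' Matthews correlation coefficient from hard class predictions, with class 1
#' (post-treatment) as the positive class. MCC is defined as 0 whenever a
#' factor of its denominator is 0.
#'
#' @param predicted Vector of predicted classes (0/1).
#' @param labels Vector of true classes (0/1).
#' @return A one-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_f`, `mcc`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_metrics <- function(predicted, labels) {
  predicted <- as_binary_labels(predicted)
  labels <- as_binary_labels(labels)
  if (length(predicted) != length(labels)) {
    stop("`predicted` and `labels` must have the same length", call. = FALSE)
  }
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  tp <- sum(predicted == 1L & labels == 1L)
  tn <- sum(predicted == 0L & labels == 0L)
  fp <- sum(predicted == 1L & labels == 0L)
  fn <- sum(predicted == 0L & labels == 1L)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    balanced_f = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
    mcc = if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  )
}

#' Aggregate a bootstrap distribution as mean and standard-error CI
#'
#' Summarises per-iteration metric values as the mean with a 95% confidence
#' interval of mean +/- 1.96 standard errors, the standard error being the
#' standard deviation across iterations divided by sqrt(n).
#'
#' @param values Numeric vector of per-iteration values; `NA`s (iterations
#'   where the metric was undefined) are dropped.
#' @return A one-row tibble with `mean`, `ci_low`, `ci_high`, `n`.
#' @examples
#' aggregate_bootstrap(c(0.8, 0.9))
#' @export
aggregate_bootstrap <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    stop("need at least two non-missing values to aggregate", call. = FALSE)
  }
  m <- mean(values)
  se <- stats::sd(values) / sqrt(length(values))
  tibble::tibble(
    mean = m, ci_low = m - 1.96 * se, ci_high = m + 1.96 * se,
    n = length(values)
  )
}

#' Two-sample Kolmogorov-Smirnov comparison of metric distributions
#'
#' Two-sided, two-sample KS test, used to compare per-iteration performance
#' distributions of two models. Significance is judged at 0.05; an exact
#' p-value is used for small samples (no ties), the asymptotic one otherwise.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @return A one-row tibble with `statistic` (the KS D), `p_value`,
#'   `significant` (logical, p < 0.05).
#' @export
ks_compare <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("both samples must contain at least two values", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(values_a, values_b,
    alternative = "two.sided"
  ))
  tibble::tibble(
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    significant = kt$p.value < 0.05
  )
}

#' ROC curve coordinates
#'
#' Enumerates every distinct score threshold and returns the true- and
#' false-positive rates attained there, suitable for plotting or export.
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `tpr`, `fpr`, ordered from the
#'   most permissive threshold to the strictest.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  th <- c(-Inf, sort(unique(scores)), Inf)
  purrr::map_dfr(th, function(t) {
    pos <- scores >= t
    tibble::tibble(
      threshold = t,
      tpr = sum(pos & labels == 1L) / n1,
      fpr = sum(pos & labels == 0L) / n0
    )
  })
}

# coerce factor/logical/numeric labels to integer 0/1, erroring on anything else
as_binary_labels <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) x <- suppressWarnings(as.numeric(x))
  if (is.logical(x)) x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("labels must be coded 0/1", call. = FALSE)
  }
  as.integer(x)
}
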