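#' Consensus out-of-fold prediction per trajectory vector
#'
#' Averages each vector's out-of-fold scores (scores produced only at
#' iterations where the vector's patient was held out) and thresholds the
#' mean to a class, ties going to class 1.
#'
#' @param result A [bootstrap_cv()] result.
#' @param threshold Decision threshold on the mean score.
#' @return A tibble: `row`, `patient_id`, `label`, `mean_score`, `n_scores`,
#'   `predicted`.
#' @export
consensus_predictions <- function(result, threshold = 0.5) {
  stopifnot(inherits(result, "bootstrap_cv"))
  out <- dplyr::summarise(
    dplyr::group_by(result$oof, .data$row, .data$patient_id, .data$label),
    mean_score = mean(.data$score), n_scores = dplyr::n(), .groups = "drop"
  )
  if (nrow(out) < result$n_vectors) {
    stop(
      "some vectors were never held out; increase n_iter",
      call. = FALSE
    )
  }
  dplyr::mutate(out, predicted = as.integer(.data$mean_score >= threshold))
}

#' Fisher's exact test p-value for a 2x2 table
#'
#' Two-sided p-value by summation of hypergeometric probabilities no larger
#' than that of the observed table (conditional on margins).
#'
#' @param a,b,c,d Non-negative cell counts: rows = predicted class, columns =
#'   true class.
#' @return The two-sided p-value.
#' @export
fisher_exact_p <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("empty table", call. = FALSE)
  m <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(1) # a zero margin carries no evidence of association
  }
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Sample odds ratio with Haldane-Anscombe correction
#'
#' Computes (a d) / (b c); if any cell is zero, 0.5 is first added to every
#' cell, guaranteeing a finite ratio.
#'
#' @inheritParams fisher_exact_p
#' @return The odds ratio.
#' @examples
#' odds_ratio(20, 5, 4, 21) # 21
#' @export
odds_ratio <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("cell counts must be non-negative", call. = FALSE)
  if (any(counts == 0)) counts <- counts + 0.5
  (counts[1] * counts[4]) / (counts[2] * counts[3])
}

#' Simulate randomised controlled trials of varying enrolment
#'
#' For each enrolment size N, repeatedly samples N patients without
#' replacement, pools all their trajectory vectors (a patient with both
#' periods contributes both) into a predicted-class by true-class 2x2 table,
#' and evaluates the association with Fisher's exact test and the sample odds
#' ratio. Reports, per N, the mean odds ratio with a 95% standard-error CI
#' and the achieved power: the fraction of repetitions rejecting at `alpha`,
#' with a normal-approximation binomial CI.
#'
#' @param predictions A tibble with one row per trajectory vector holding
#'   `patient_id`, `label` (true class) and `predicted` (classifier output),
#'   e.g. from [consensus_predictions()].
#' @param n_grid Enrolment sizes N to simulate.
#' @param n_rep Repetitions per N.
#' @param alpha Significance threshold for the power computation.
#' @param seed Integer seed.
#' @return An object of class `rct_result`: a tibble with columns `n`,
#'   `or_mean`, `or_ci_low`, `or_ci_high`, `power`, `power_ci_low`,
#'   `power_ci_high`.
#' @export
simulate_rcts <- function(predictions, n_grid = NULL, n_rep = 500,
                          alpha = 0.01, seed = 1L) {
  stopifnot(
    all(c("patient_id", "label", "predicted") %in% names(predictions)),
    alpha > 0, alpha < 1
  )
  patients <- unique(predictions$patient_id)
  n_pat <- length(patients)
  if (is.null(n_grid)) {
    n_grid <- unique(pmin(round(seq(19, n_pat, length.out = 6)), n_pat))
  }
  if (any(n_grid < 2) || any(n_grid > n_pat)) {
    stop("every N must be between 2 and the number of patients", call. = FALSE)
  }
  set.seed(seed)
  by_patient <- split(
    predictions[c("label", "predicted")],
    predictions$patient_id
  )

  rows <- purrr::map_dfr(n_grid, function(N) {
    ors <- numeric(n_rep)
    rejected <- logical(n_rep)
    for (r in seq_len(n_rep)) {
      chosen <- sample(patients, N)
      d <- dplyr::bind_rows(by_patient[chosen])
      a <- sum(d$predicted == 1 & d$label == 1)
      b <- sum(d$predicted == 1 & d$label == 0)
      cc <- sum(d$predicted == 0 & d$label == 1)
      dd <- sum(d$predicted == 0 & d$label == 0)
      ors[r] <- odds_ratio(a, b, cc, dd)
      rejected[r] <- fisher_exact_p(a, b, cc, dd) < alpha
    }
    or_m <- mean(ors)
    or_se <- stats::sd(ors) / sqrt(n_rep)
    p <- mean(rejected)
    p_se <- sqrt(p * (1 - p) / n_rep)
    tibble::tibble(
      n = N,
      or_mean = or_m,
      or_ci_low = or_m - 1.96 * or_se, or_ci_high = or_m + 1.96 * or_se,
      power = p,
      power_ci_low = max(p - 1.96 * p_se, 0),
      power_ci_high = min(p + 1.96 * p_se, 1)
    )
  })
  structure(rows,
    class = c("rct_result", class(rows)),
    alpha = alpha, n_rep = n_rep
  )
}

#' @rdname tidy.bootstrap_cv
#' @method tidy rct_result
#' @export
tidy.rct_result <- function(x, ...) tibble::as_tibble(x)
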