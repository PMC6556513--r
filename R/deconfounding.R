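#' Normalise volumetric features by total intracranial volume
#'
#' Divides every regional volume, total brain volume and total lesion volume
#' by the scan's total intracranial volume (TIV), removing head-size
#' variation. Disconnection estimates and lesion count are left unchanged, as
#' is the `tiv` column itself.
#'
#' @param cohort A `cohort_tbl`.
#' @return The cohort with volumetric features on the TIV-normalised scale.
#' @export
normalize_by_tiv <- function(cohort) {
  if (!"tiv" %in% names(cohort)) stop("cohort has no `tiv` column", call. = FALSE)
  if (any(!is.finite(cohort$tiv)) || any(cohort$tiv <= 0)) {
    stop("tiv must be positive on every scan", call. = FALSE)
  }
  vol_cols <- c(
    grep("^vol_", names(cohort), value = TRUE),
    intersect(c("total_brain_vol", "total_lesion_vol"), names(cohort))
  )
  out <- dplyr::mutate(
    tibble::as_tibble(cohort),
    dplyr::across(dplyr::all_of(vol_cols), ~ .x / .data$tiv)
  )
  restore_cohort_attrs(out, cohort)
}

restore_cohort_attrs <- function(out, cohort) {
  new_cohort_tbl(
    out,
    region_pairing = attr(cohort, "region_pairing"),
    ground_truth = attr(cohort, "ground_truth"),
    config = attr(cohort, "config")
  )
}

#' Bayesian ridge regression via evidence maximisation
#'
#' Fits a linear model with a zero-mean Gaussian prior on the coefficients,
#' estimating the noise precision and the prior (ridge) precision by
#' fixed-point maximisation of the marginal likelihood. The intercept is
#' unpenalised (handled by centring). As the estimated ridge penalty tends to
#' zero the fit coincides with ordinary least squares.
#'
#' @param x Numeric design matrix (no intercept column).
#' @param y Numeric response.
#' @param max_iter,tol Convergence controls for the precision updates.
#' @param lambda_init Starting value for the weight precision.
#' @param lambda_fixed If supplied, the weight precision is held at this value
#'   instead of being estimated (`lambda_fixed = 0` recovers ordinary least
#'   squares).
#' @return A list with `coef`, `intercept`, `fitted`, `residuals`, `alpha`
#'   (noise precision), `lambda` (weight precision), `n_iter`.
#' @export
bayesian_ridge <- function(x, y, max_iter = 100, tol = 1e-8,
                           lambda_init = 1, lambda_fixed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("length(y) must match nrow(x)", call. = FALSE)
  if (n < ncol(x) + 2L) {
    stop("need at least ncol(x) + 2 observations", call. = FALSE)
  }
  xm <- colMeans(x)
  ym <- mean(y)
  xc <- sweep(x, 2, xm)
  yc <- y - ym
  sv <- svd(xc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)

  vy <- stats::var(yc)
  alpha <- if (vy > 0) 1 / vy else 1 # noise precision
  lambda <- if (is.null(lambda_fixed)) lambda_init else lambda_fixed
  coef_old <- rep(Inf, ncol(x))
  it <- 0L
  repeat {
    it <- it + 1L
    shrink <- sv$d / (d2 + lambda / alpha)
    w <- sv$v %*% (shrink * uty)
    gamma <- sum(alpha * d2 / (alpha * d2 + lambda))
    sse <- sum((yc - sv$u %*% (sv$d * shrink * uty))^2)
    wtw <- sum(w^2)
    if (is.null(lambda_fixed)) {
      lambda <- if (wtw > 0) max(gamma, 1e-10) / wtw else 1e10
    }
    alpha <- if (sse > 0) max(n - gamma, 1e-10) / sse else 1e10
    if (it >= max_iter || sqrt(sum((w - coef_old)^2)) < tol) break
    coef_old <- w
  }
  fitted <- drop(xc %*% w) + ym
  list(
    coef = drop(w), intercept = ym - sum(xm * w), fitted = fitted,
    residuals = y - fitted, alpha = alpha, lambda = lambda, n_iter = it
  )
}

#' Build the covariate design matrix used for confounder regression
#'
#' Continuous covariates are standardised; categorical ones are one-hot
#' encoded with the reference level dropped. The intercept is handled by the
#' fitting routine.
#'
#' @param cohort A `cohort_tbl`.
#' @param confounders Covariate names to include.
#' @return A numeric matrix, one row per scan (zero columns if `confounders`
#'   is empty).
#' @keywords internal
confounder_design <- function(cohort, confounders = cohort_covariate_names()) {
  cov <- tibble::as_tibble(cohort)[cohort_covariate_names()]
  if (anyNA(cov)) stop("missing covariate values", call. = FALSE)
  std <- function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  manu_levels <- sort(unique(cov$manufacturer))
  manu <- purrr::map(
    manu_levels[-1],
    ~ as.numeric(cov$manufacturer == .x)
  )
  names(manu) <- paste0("manufacturer_", manu_levels[-1])
  cols <- c(
    list(
      age = std(cov$age),
      gender = as.numeric(cov$gender == "M"),
      field_strength = std(cov$field_strength),
      disease_duration = std(cov$disease_duration),
      edss = std(cov$edss),
      t1_slice = std(cov$t1_slice),
      t1_voxel = std(cov$t1_voxel),
      flair_slice = std(cov$flair_slice),
      flair_voxel = std(cov$flair_voxel)
    ),
    list(manufacturer = do.call(cbind, manu))
  )
  cols <- cols[c(
    setdiff(confounders, "manufacturer"),
    intersect("manufacturer", confounders)
  )]
  out <- do.call(cbind, cols)
  if (is.null(out)) out <- matrix(0, nrow(cov), 0)
  out
}

#' Regress covariates out of all imaging-derived features
#'
#' For every feature column, fits a Bayesian ridge model of the feature on
#' the covariate design (all scans) and replaces the feature with its
#' residual plus the feature's grand mean, keeping features on their original
#' scale. All downstream analyses operate on features deconfounded this way.
#'
#' @param cohort A `cohort_tbl`, typically TIV-normalised first.
#' @param features Feature columns to residualise; defaults to every imaging
#'   feature (regional volumes/disconnections and global aggregates).
#' @param confounders Covariates to regress out (all ten by default); with an
#'   empty vector the table is returned unchanged.
#' @return The deconfounded cohort.
#' @seealso [verify_deconfounding()] for the adversarial check that removal
#'   succeeded.
#' @export
residualize_features <- function(cohort,
                                 features = cohort_feature_names(cohort),
                                 confounders = cohort_covariate_names()) {
  x <- confounder_design(cohort, confounders)
  if (ncol(x) == 0L) {
    return(cohort)
  }
  out <- tibble::as_tibble(cohort)
  for (f in features) {
    fit <- bayesian_ridge(x, out[[f]])
    out[[f]] <- fit$residuals + mean(out[[f]])
  }
  restore_cohort_attrs(out, cohort)
}

#' One-call deconfounding: TIV normalisation then covariate residualisation
#'
#' @inheritParams residualize_features
#' @return The deconfounded cohort.
#' @export
deconfound_cohort <- function(cohort) {
  residualize_features(normalize_by_tiv(cohort))
}

#' Specifications of the verification confounders
#'
#' One row per covariate with its type and the rule used to dichotomise it
#' for adversarial verification: continuous covariates are split at the
#' sample mean, scanner manufacturer as modal category vs the rest, field
#' strength as 1.5 T vs 3.0 T, slice thicknesses at < 6 mm, gender as is.
#'
#' @return A tibble with columns `name`, `kind`, `rule`.
#' @export
confounder_specs <- function() {
  tibble::tibble(
    name = cohort_covariate_names(),
    kind = c(
      "continuous", "categorical", "categorical", "categorical",
      "continuous", "continuous", "continuous", "continuous",
      "continuous", "continuous"
    ),
    rule = c(
      "below_mean", "gender", "modal_vs_rest", "low_field",
      "below_mean", "below_mean", "thin_slice", "below_mean",
      "thin_slice", "below_mean"
    )
  )
}

#' Dichotomise a confounder for adversarial verification
#'
#' @param values The covariate values across scans.
#' @param rule One of `"below_mean"` (1 if less than the sample mean),
#'   `"modal_vs_rest"` (1 for the most common category),
#'   `"low_field"` (1 for 1.5 T), `"thin_slice"` (1 if less than 6 mm),
#'   `"gender"` (1 for male).
#' @return Integer 0/1 labels.
#' @export
binarize_confounder <- function(values, rule) {
  if (length(values) == 0L) stop("no values to binarize", call. = FALSE)
  out <- switch(rule,
    below_mean = as.integer(values < mean(values)),
    modal_vs_rest = {
      tab <- sort(table(values), decreasing = TRUE)
      as.integer(values == names(tab)[1])
    },
    low_field = as.integer(values == 1.5),
    thin_slice = as.integer(values < 6),
    gender = as.integer(values == "M"),
    stop("unknown binarization rule: ", rule, call. = FALSE)
  )
  out
}

#' Adversarial verification of confounder removal
#'
#' For each confounder, dichotomises it and trains classifiers to predict it
#' from the per-scan imaging feature vector under subject-constrained
#' bootstrap cross-validation. Successful deconfounding leaves every
#' confounder unpredictable: mean AUC confidence intervals covering 0.5.
#'
#' @param cohort A `cohort_tbl` (typically after [deconfound_cohort()]; run
#'   on the raw cohort for the before/after contrast).
#' @param confounders A tibble as from [confounder_specs()] (subsettable).
#' @param spec A [classifier_spec()]; the default is the kernel-margin (SVM)
#'   classifier.
#' @param n_iter Bootstrap iterations per confounder.
#' @param seed Integer seed.
#' @return A tibble: `confounder`, `auc_mean`, `ci_low`, `ci_high`.
#' @export
verify_deconfounding <- function(cohort,
                                 confounders = confounder_specs(),
                                 spec = classifier_spec("svm"),
                                 n_iter = 100,
                                 seed = 1L) {
  feats <- cohort_feature_names(cohort)
  purrr::map2_dfr(confounders$name, confounders$rule, function(nm, rule) {
    labels <- binarize_confounder(cohort[[nm]], rule)
    if (length(unique(labels)) < 2L || min(table(labels)) < 2L) {
      stop("binarized confounder ", nm, " has a class with < 2 scans",
        call. = FALSE
      )
    }
    dat <- dplyr::bind_cols(
      tibble::tibble(
        patient_id = cohort$patient_id,
        period_class = labels
      ),
      tibble::as_tibble(cohort)[feats]
    )
    res <- bootstrap_cv(dat,
      features = feats, spec = spec, n_iter = n_iter,
      seed = seed
    )
    auc <- dplyr::filter(tidy(res), .data$metric == "auc")
    tibble::tibble(
      confounder = nm, auc_mean = auc$mean,
      ci_low = auc$ci_low, ci_high = auc$ci_high
    )
  })
}
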