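#' Classifier specification
#'
#' Fixed hyperparameter specifications for the two classifier families used
#' throughout: a kernel-margin classifier (support vector machine with a
#' Gaussian radial basis kernel, penalty C = 10, kernel coefficient gamma =
#' 1/number-of-features) and a randomised tree ensemble (extremely randomised
#' trees: Gini impurity splits, 100 trees, features per split =
#' floor(sqrt(number of features))). Both apply balanced class weighting:
#' weights inversely proportional to training-class frequencies.
#'
#' @param kind `"svm"` or `"ert"`.
#' @param cost SVM penalty term C.
#' @param gamma SVM kernel coefficient; `NULL` means 1/n_features.
#' @param num_trees Number of trees for the ensemble.
#' @param mtry Features considered per split; `NULL` means
#'   floor(sqrt(n_features)).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm", "ert"), cost = 10, gamma = NULL,
                            num_trees = 100, mtry = NULL) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, cost = cost, gamma = gamma, num_trees = num_trees, mtry = mtry),
    class = "classifier_spec"
  )
}

#' Instantiate a trainable classifier
#'
#' Returns a model contract with `fit(x, y)` and `score(x)` where `score`
#' yields a continuous class-1 response score in \[0, 1\]: the fraction of
#' trees voting class 1 for the tree ensemble, and the decision value mapped
#' through a logistic transform for the SVM. Features are standardised
#' internally for the SVM using training-set statistics.
#'
#' @param spec A [classifier_spec()].
#' @param n_features Number of predictor columns.
#' @param seed Integer seed for the tree ensemble's internal randomness.
#' @return A list with functions `fit(x, y)` (x a numeric matrix, y 0/1) and
#'   `score(x)`.
#' @export
make_classifier <- function(spec, n_features, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"), n_features >= 1)
  if (spec$kind == "svm") {
    make_svm(spec, n_features)
  } else {
    make_ert(spec, n_features, seed)
  }
}

balanced_weights <- function(y) {
  # weight_k = n / (n_classes * n_k), as in balanced class weighting
  tab <- table(factor(y, levels = c("0", "1")))
  w <- length(y) / (2 * pmax(as.numeric(tab), 1))
  stats::setNames(w, names(tab))
}

make_svm <- function(spec, n_features) {
  gamma <- if (is.null(spec$gamma)) 1 / n_features else spec$gamma
  env <- new.env(parent = emptyenv())
  fit <- function(x, y) {
    x <- as.matrix(x)
    env$center <- colMeans(x)
    sds <- apply(x, 2, stats::sd)
    env$scale <- ifelse(sds > 0, sds, 1)
    xs <- sweep(sweep(x, 2, env$center), 2, env$scale, "/")
    env$model <- e1071::svm(
      x = xs, y = factor(y, levels = c("0", "1")),
      kernel = "radial", cost = spec$cost, gamma = gamma,
      class.weights = balanced_weights(y), scale = FALSE
    )
    invisible(NULL)
  }
  score <- function(x) {
    x <- as.matrix(x)
    xs <- sweep(sweep(x, 2, env$center), 2, env$scale, "/")
    pr <- stats::predict(env$model, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # decision values are oriented toward the class named first in "a/b"
    s <- drop(dv)
    if (!startsWith(colnames(dv)[1], "1")) s <- -s
    stats::plogis(s)
  }
  list(
    fit = fit, score = score, kind = "svm",
    params = list(cost = spec$cost, gamma = gamma)
  )
}

make_ert <- function(spec, n_features, seed) {
  mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(n_features))) else spec$mtry
  env <- new.env(parent = emptyenv())
  fit <- function(x, y) {
    x <- as.data.frame(x)
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    yf <- factor(y, levels = c("0", "1"))
    w <- balanced_weights(y)
    env$model <- ranger::ranger(
      x = x, y = yf,
      num.trees = spec$num_trees, mtry = min(mtry, ncol(x)),
      splitrule = "extratrees", num.random.splits = 1,
      probability = TRUE, class.weights = as.numeric(w[levels(yf)]),
      seed = seed, num.threads = 1
    )
    invisible(NULL)
  }
  score <- function(x) {
    x <- as.data.frame(x)
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    unname(stats::predict(env$model, data = x, num.threads = 1)$predictions[, "1"])
  }
  list(
    fit = fit, score = score, kind = "ert",
    params = list(num_trees = spec$num_trees, mtry = mtry)
  )
}

#' Subject-level train/test split
#'
#' Randomly allocates 80% of patients to training and 20% to testing
#' (rounded, at least one patient on each side). Because whole patients are
#' allocated, both trajectory vectors of a patient with pre- and
#' post-treatment periods always land on the same side, so no patient's data
#' ever appears in both training and testing.
#'
#' @param patients Character vector of unique patient ids.
#' @param test_frac Fraction of patients held out.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A list with character vectors `train` and `test` (disjoint).
#' @export
subject_level_split <- function(patients, test_frac = 0.2, seed = NULL) {
  patients <- unique(patients)
  n <- length(patients)
  if (n < 5L) stop("need at least 5 patients to split", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_test <- min(max(round(test_frac * n), 1L), n - 1L)
  test <- sample(patients, n_test)
  list(train = setdiff(patients, test), test = test)
}

#' Subject-constrained bootstrap cross-validation
#'
#' Evaluates a classifier over `n_iter` random 80/20 subject-level splits,
#' fully holding out each test set: at every iteration the model is fitted on
#' the training patients' vectors and scored on the held-out patients'
#' vectors, and AUC, accuracy, sensitivity, specificity, balanced F-score and
#' MCC are computed on the held-out set. Randomisation is at the subject
#' level, so a patient contributing both a pre- and a post-treatment vector
#' is never split across training and testing. Splits whose training side
#' lacks a class are redrawn (bounded retries); iterations whose held-out set
#' is single-class record AUC/sensitivity/specificity as missing and are
#' excluded from those metrics' aggregation.
#'
#' @param data A tibble with columns `patient_id`, `period_class` (0/1) and
#'   feature columns (e.g. a `traj_tbl`).
#' @param features Character vector of predictor columns to use.
#' @param spec A [classifier_spec()].
#' @param n_iter Number of bootstrap iterations (500 in the full analysis).
#' @param seed Integer seed; the full run is reproducible given it.
#' @param balance `"off"` or `"subsample"`: optionally subsample the
#'   majority class among training vectors to match the minority class size
#'   at each iteration.
#' @param test_frac Fraction of patients held out per iteration.
#' @return An object of class `bootstrap_cv` with per-iteration metrics and
#'   the out-of-fold score ledger; see [tidy.bootstrap_cv()] and
#'   [glance.bootstrap_cv()].
#' @export
bootstrap_cv <- function(data, features, spec, n_iter = 500, seed = 1L,
                         balance = c("off", "subsample"), test_frac = 0.2) {
  balance <- match.arg(balance)
  stopifnot(all(c("patient_id", "period_class") %in% names(data)))
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    stop("unknown feature(s): ", paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  labels <- as_binary_labels(data$period_class)
  if (min(tabulate(labels + 1L, 2L)) < 2L) {
    stop("need at least two vectors per class", call. = FALSE)
  }
  x_all <- as.matrix(tibble::as_tibble(data)[features])
  storage.mode(x_all) <- "double"
  patients <- unique(data$patient_id)

  set.seed(seed)
  metric_names <- c(
    "auc", "accuracy", "sensitivity", "specificity",
    "balanced_f", "mcc"
  )
  metrics <- matrix(NA_real_, n_iter, length(metric_names),
    dimnames = list(NULL, metric_names)
  )
  oof <- vector("list", n_iter)

  for (i in seq_len(n_iter)) {
    split <- NULL
    for (try in 1:25) {
      cand <- subject_level_split(patients, test_frac)
      tr_idx <- which(data$patient_id %in% cand$train)
      if (length(unique(labels[tr_idx])) == 2L) {
        split <- cand
        break
      }
    }
    if (is.null(split)) {
      stop("could not draw a split with both classes in training", call. = FALSE)
    }
    te_idx <- which(data$patient_id %in% split$test)

    if (balance == "subsample") tr_idx <- subsample_majority(tr_idx, labels)

    model <- make_classifier(spec, length(features),
      seed = sample.int(.Machine$integer.max - 1L, 1L)
    )
    model$fit(x_all[tr_idx, , drop = FALSE], labels[tr_idx])
    scores <- model$score(x_all[te_idx, , drop = FALSE])
    y_te <- labels[te_idx]

    cm <- confusion_metrics(as.integer(scores >= 0.5), y_te)
    metrics[i, "accuracy"] <- cm$accuracy
    metrics[i, "balanced_f"] <- cm$balanced_f
    metrics[i, "mcc"] <- cm$mcc
    if (length(unique(y_te)) == 2L) {
      metrics[i, "auc"] <- roc_auc(scores, y_te)
      metrics[i, "sensitivity"] <- cm$sensitivity
      metrics[i, "specificity"] <- cm$specificity
    }
    oof[[i]] <- tibble::tibble(
      iteration = i, row = te_idx,
      patient_id = data$patient_id[te_idx], label = y_te, score = scores
    )
  }

  structure(
    list(
      iterations = dplyr::bind_cols(
        tibble::tibble(iteration = seq_len(n_iter)),
        tibble::as_tibble(metrics)
      ),
      oof = dplyr::bind_rows(oof),
      n_iter = n_iter, features = features, spec = spec, seed = seed,
      balance = balance, n_vectors = nrow(data)
    ),
    class = "bootstrap_cv"
  )
}

subsample_majority <- function(tr_idx, labels) {
  y <- labels[tr_idx]
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == n0) {
    return(tr_idx)
  }
  maj <- if (n1 > n0) 1L else 0L
  keep_maj <- sample(tr_idx[y == maj], min(n0, n1))
  sort(c(tr_idx[y != maj], keep_maj))
}

#' @export
print.bootstrap_cv <- function(x, ...) {
  cat(
    "Subject-constrained bootstrap CV (", x$spec$kind, ", ",
    x$n_iter, " iterations, ", length(x$features), " features)\n",
    sep = ""
  )
  print(tidy(x))
  invisible(x)
}

#' Tidy and glance methods for bootstrap CV results
#'
#' `tidy()` returns one row per performance metric with the bootstrap mean
#' and its 95% standard-error confidence interval; `glance()` a one-row
#' summary keyed on the mean AUC.
#'
#' @param x A `bootstrap_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bootstrap_cv
#' @export
tidy.bootstrap_cv <- function(x, ...) {
  purrr::map_dfr(
    c("auc", "accuracy", "sensitivity", "specificity", "balanced_f", "mcc"),
    function(m) {
      dplyr::bind_cols(
        tibble::tibble(metric = m),
        safe_aggregate(x$iterations[[m]])
      )
    }
  )
}

# aggregate_bootstrap, degrading to NA when a metric was defined in fewer
# than two iterations (e.g. held-out sets almost always single-class)
safe_aggregate <- function(values) {
  if (sum(!is.na(values)) < 2L) {
    return(tibble::tibble(
      mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      n = sum(!is.na(values))
    ))
  }
  aggregate_bootstrap(values)
}

#' @rdname tidy.bootstrap_cv
#' @method glance bootstrap_cv
#' @export
glance.bootstrap_cv <- function(x, ...) {
  auc <- safe_aggregate(x$iterations$auc)
  tibble::tibble(
    classifier = x$spec$kind, n_features = length(x$features),
    n_iter = x$n_iter, n_vectors = x$n_vectors,
    auc_mean = auc$mean, auc_ci_low = auc$ci_low, auc_ci_high = auc$ci_high
  )
}

#' AUC-weighted ensemble of two models' scores
#'
#' Combines per-vector scores of the regional-volume and
#' regional-disconnection models as a weighted average with weights
#' proportional to the two models' mean AUCs.
#'
#' @param scores_v,scores_d Equal-length numeric score vectors.
#' @param auc_v,auc_d The two models' mean AUCs (in (0, 1\]).
#' @return The combined scores.
#' @examples
#' ensemble_predict(0.6, 0.8, 0.857, 0.817)
#' @export
ensemble_predict <- function(scores_v, scores_d, auc_v, auc_d) {
  if (length(scores_v) != length(scores_d)) {
    stop("score vectors must have equal length", call. = FALSE)
  }
  if (auc_v <= 0 || auc_d <= 0) stop("AUC weights must be positive", call. = FALSE)
  (auc_v * scores_v + auc_d * scores_d) / (auc_v + auc_d)
}

#' Ensemble two bootstrap CV runs sharing the same splits
#'
#' Given two [bootstrap_cv()] results obtained with the same seed, iteration
#' count and data (hence identical subject-level splits), combines their
#' out-of-fold scores per iteration via [ensemble_predict()], weighting by
#' each model's overall mean AUC, and recomputes every metric on the combined
#' scores. This constructs the best high-dimensional model from the
#' regional-volume and regional-disconnection models.
#'
#' @param res_v,res_d `bootstrap_cv` objects on the same data and seed.
#' @return A `bootstrap_cv` object for the ensemble.
#' @export
ensemble_cv <- function(res_v, res_d) {
  if (res_v$n_iter != res_d$n_iter || res_v$seed != res_d$seed ||
    res_v$n_vectors != res_d$n_vectors) {
    stop("ensemble requires runs with identical data, seed and n_iter",
      call. = FALSE
    )
  }
  auc_v <- mean(res_v$iterations$auc, na.rm = TRUE)
  auc_d <- mean(res_d$iterations$auc, na.rm = TRUE)
  joined <- dplyr::inner_join(
    res_v$oof, res_d$oof,
    by = c("iteration", "row", "patient_id", "label"),
    suffix = c("_v", "_d")
  )
  if (nrow(joined) != nrow(res_v$oof)) {
    stop("out-of-fold ledgers do not align; were the splits identical?",
      call. = FALSE
    )
  }
  joined$score <- ensemble_predict(
    joined$score_v, joined$score_d, auc_v, auc_d
  )

  per_iter <- lapply(split(joined, joined$iteration), function(d) {
    cm <- confusion_metrics(as.integer(d$score >= 0.5), d$label)
    two <- length(unique(d$label)) == 2L
    tibble::tibble(
      iteration = d$iteration[1],
      auc = if (two) roc_auc(d$score, d$label) else NA_real_,
      accuracy = cm$accuracy,
      sensitivity = if (two) cm$sensitivity else NA_real_,
      specificity = if (two) cm$specificity else NA_real_,
      balanced_f = cm$balanced_f, mcc = cm$mcc
    )
  })
  structure(
    list(
      iterations = dplyr::bind_rows(per_iter),
      oof = joined[c("iteration", "row", "patient_id", "label", "score")],
      n_iter = res_v$n_iter,
      features = union(res_v$features, res_d$features),
      spec = structure(
        list(kind = paste0("ensemble(", res_v$spec$kind, ")")),
        class = "classifier_spec"
      ),
      seed = res_v$seed, balance = res_v$balance,
      n_vectors = res_v$n_vectors,
      weights = c(volume = auc_v, disconnection = auc_d) / (auc_v + auc_d)
    ),
    class = "bootstrap_cv"
  )
}

#' Greedy forward-stepwise feature selection by out-of-fold AUC
#'
#' Starts from the single feature with the highest mean bootstrapped
#' out-of-fold AUC, then repeatedly adds the candidate that maximises the
#' mean AUC of the augmented set, evaluating every candidate on the same
#' splits (same seed). The chosen model size is the argmax of the cumulative
#' mean AUC, ties resolved toward the smaller set. Selection is performed
#' once; the selected features are then reused throughout.
#'
#' @inheritParams bootstrap_cv
#' @param candidates Candidate feature names.
#' @param max_features Optional cap on the number of selection steps.
#' @return An object of class `selection_trace`: a list with `trace` (tibble
#'   of step, feature, auc_mean, ci_low, ci_high), `chosen_size` and
#'   `selected` (the chosen feature set).
#' @export
greedy_forward_selection <- function(data, candidates, spec, n_iter = 50,
                                     seed = 1L, max_features = NULL) {
  stopifnot(length(candidates) >= 1L)
  if (is.null(max_features)) max_features <- length(candidates)
  selected <- character(0)
  remaining <- candidates
  trace <- list()
  while (length(remaining) > 0 && length(selected) < max_features) {
    evals <- purrr::map_dbl(remaining, function(f) {
      res <- bootstrap_cv(data, c(selected, f), spec,
        n_iter = n_iter,
        seed = seed
      )
      mean(res$iterations$auc, na.rm = TRUE)
    })
    best <- remaining[which.max(evals)]
    selected <- c(selected, best)
    res_best <- bootstrap_cv(data, selected, spec, n_iter = n_iter, seed = seed)
    agg <- aggregate_bootstrap(res_best$iterations$auc)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      step = length(selected), feature = best,
      auc_mean = agg$mean, ci_low = agg$ci_low, ci_high = agg$ci_high
    )
    remaining <- setdiff(remaining, best)
  }
  trace <- dplyr::bind_rows(trace)
  chosen <- which.max(trace$auc_mean) # first max: ties go to the smaller set
  structure(
    list(
      trace = trace, chosen_size = chosen,
      selected = trace$feature[seq_len(chosen)],
      spec = spec, n_iter = n_iter, seed = seed
    ),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(
    "Greedy forward selection (", nrow(x$trace), " steps, chosen size ",
    x$chosen_size, ")\n",
    sep = ""
  )
  print(x$trace)
  invisible(x)
}

#' @rdname tidy.bootstrap_cv
#' @method tidy selection_trace
#' @export
tidy.selection_trace <- function(x, ...) x$trace

#' Permutation null model of a cohort
#'
#' For each patient and each imaging feature independently, randomly permutes
#' the order of the feature's values across that patient's scans while
#' keeping scan times and covariates unchanged. Slopes computed from such a
#' cohort carry no temporal signal, so classifiers trained on the resulting
#' trajectories should perform at chance; this verifies that observed
#' performance is not an artefact of scan timing.
#'
#' @param cohort A `cohort_tbl`.
#' @param seed Integer seed.
#' @return The permuted cohort (same dimensions and per-patient value
#'   multisets).
#' @export
permute_null <- function(cohort, seed = 1L) {
  set.seed(seed)
  feats <- cohort_feature_names(cohort)
  out <- tibble::as_tibble(cohort)
  for (idx in split(seq_len(nrow(out)), out$patient_id)) {
    n <- length(idx)
    if (n < 2L) next
    for (f in feats) {
      out[[f]][idx] <- out[[f]][idx[sample.int(n)]]
    }
  }
  restore_cohort_attrs(out, cohort)
}
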