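#' Configuration of an end-to-end imaging-response experiment
#'
#' @param cohort A [cohort_config()] describing the synthetic cohort (or a
#'   `cohort_tbl` to analyse directly).
#' @param classifiers Which classifier families to run.
#' @param n_iter Bootstrap iterations per model.
#' @param balance Class-balancing mode passed to [bootstrap_cv()].
#' @param select If `TRUE`, run [greedy_forward_selection()] on the regional
#'   volume and disconnection candidate sets and use the chosen subsets; if
#'   `FALSE` (default) use the full regional sets.
#' @param selection_n_iter Bootstrap iterations per candidate during
#'   selection.
#' @param verify_n_iter Iterations for the deconfounding verification.
#' @param rct_n_grid,rct_n_rep,rct_alpha Passed to [simulate_rcts()].
#' @param seed Integer master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              classifiers = c("svm", "ert"),
                              n_iter = 100,
                              balance = "off",
                              select = FALSE,
                              selection_n_iter = 25,
                              verify_n_iter = 50,
                              rct_n_grid = NULL,
                              rct_n_rep = 200,
                              rct_alpha = 0.01,
                              seed = 1L) {
  stopifnot(all(classifiers %in% c("svm", "ert")))
  structure(
    list(
      cohort = cohort, classifiers = classifiers, n_iter = n_iter,
      balance = balance, select = select,
      selection_n_iter = selection_n_iter, verify_n_iter = verify_n_iter,
      rct_n_grid = rct_n_grid, rct_n_rep = rct_n_rep, rct_alpha = rct_alpha,
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Run the full imaging-response detection experiment
#'
#' Drives the whole pipeline on a synthetic (or supplied) cohort: generation,
#' TIV normalisation and covariate residualisation, adversarial verification
#' of deconfounding (before and after), trajectory feature construction,
#' optional greedy feature selection, subject-constrained bootstrap
#' evaluation of every predictor set under each classifier, AUC-weighted
#' ensembling of the regional volume and disconnection models, a
#' permutation-null rerun of the model comparison, and RCT power simulation
#' driven by the best high-dimensional model's out-of-fold consensus
#' predictions.
#'
#' @param config An [experiment_config()].
#' @return A list of class `experiment_result` with elements `performance`
#'   (per predictor set x classifier: mean AUC/accuracy/sensitivity/
#'   specificity/balanced F/MCC with CIs), `null_performance` (same layout on
#'   the permutation null), `verification` (per-confounder AUCs before and
#'   after residualisation), `selection` (traces, if requested), `rct`
#'   (an `rct_result`), `fits` (the underlying `bootstrap_cv` objects),
#'   `manifest` (seeds and configuration).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- config$seed

  cohort <- if (inherits(config$cohort, "cohort_config")) {
    generate_cohort(config$cohort)
  } else {
    config$cohort
  }

  clean <- deconfound_cohort(cohort)
  verification <- dplyr::bind_rows(
    dplyr::mutate(
      verify_deconfounding(normalize_by_tiv(cohort),
        n_iter = config$verify_n_iter, seed = seed + 11L
      ),
      stage = "before"
    ),
    dplyr::mutate(
      verify_deconfounding(clean,
        n_iter = config$verify_n_iter, seed = seed + 12L
      ),
      stage = "after"
    )
  )

  traj <- build_trajectory_dataset(clean)
  sets <- predictor_sets(traj)

  selection <- NULL
  if (config$select) {
    selection <- purrr::map(
      sets[c("regional_volume", "regional_disconnection")],
      function(cand) {
        greedy_forward_selection(
          traj, cand, classifier_spec(config$classifiers[1]),
          n_iter = config$selection_n_iter, seed = seed + 21L
        )
      }
    )
    sets$regional_volume <- selection$regional_volume$selected
    sets$regional_disconnection <- selection$regional_disconnection$selected
  }

  eval_sets <- function(trajectories, seed_off) {
    fits <- list()
    rows <- list()
    for (cl in config$classifiers) {
      spec <- classifier_spec(cl)
      for (set_name in names(sets)) {
        feats <- sets[[set_name]]
        if (length(feats) == 0) next
        res <- bootstrap_cv(trajectories, feats, spec,
          n_iter = config$n_iter, seed = seed + seed_off,
          balance = config$balance
        )
        fits[[paste(set_name, cl, sep = ".")]] <- res
      }
      fits[[paste("ensemble", cl, sep = ".")]] <- ensemble_cv(
        fits[[paste("regional_volume", cl, sep = ".")]],
        fits[[paste("regional_disconnection", cl, sep = ".")]]
      )
    }
    perf <- purrr::imap_dfr(fits, function(res, nm) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      dplyr::bind_cols(
        tibble::tibble(
          predictor_set = parts[1], classifier = parts[2]
        ),
        tidy(res)
      )
    })
    list(fits = fits, performance = perf)
  }

  main <- eval_sets(traj, 31L)

  null_traj <- build_trajectory_dataset(
    deconfound_cohort(permute_null(cohort, seed = seed + 41L))
  )
  null_eval <- eval_sets(null_traj, 51L)

  best <- main$fits[[paste("ensemble", config$classifiers[length(config$classifiers)],
    sep = "."
  )]]
  rct <- simulate_rcts(
    consensus_predictions(best),
    n_grid = config$rct_n_grid, n_rep = config$rct_n_rep,
    alpha = config$rct_alpha, seed = seed + 61L
  )

  structure(
    list(
      performance = main$performance,
      null_performance = null_eval$performance,
      verification = verification,
      selection = selection,
      rct = rct,
      fits = main$fits,
      null_fits = null_eval$fits,
      trajectories = traj,
      manifest = list(
        seed = seed, n_iter = config$n_iter,
        classifiers = config$classifiers, balance = config$balance,
        select = config$select,
        cohort_config = if (inherits(config$cohort, "cohort_config")) {
          unclass(config$cohort)
        }
      )
    ),
    class = "experiment_result"
  )
}

#' Write an experiment result bundle to a directory
#'
#' Emits the model-comparison table, the permutation-null table, the
#' before/after verification table, the RCT curves and a JSON run manifest as
#' plain CSV/JSON files.
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$performance, file.path(dir, "performance.csv"))
  readr::write_csv(result$null_performance, file.path(dir, "null_performance.csv"))
  readr::write_csv(result$verification, file.path(dir, "verification.csv"))
  readr::write_csv(tibble::as_tibble(result$rct), file.path(dir, "rct.csv"))
  if (!is.null(result$selection)) {
    purrr::iwalk(result$selection, function(s, nm) {
      readr::write_csv(s$trace, file.path(dir, paste0("selection_", nm, ".csv")))
    })
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Imaging-response detection experiment\n\n")
  cat("Model comparison (mean out-of-fold AUC):\n")
  print(dplyr::filter(x$performance, .data$metric == "auc"))
  invisible(x)
}
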