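test_that("classifier specs resolve the documented hyperparameters", {
  svm <- make_classifier(classifier_spec("svm"), n_features = 3)
  expect_equal(svm$params$gamma, 1 / 3)
  expect_equal(svm$params$cost, 10)
  ert <- make_classifier(classifier_spec("ert"), n_features = 9)
  expect_equal(ert$params$mtry, 3)
  expect_equal(ert$params$num_trees, 100)
  expect_error(classifier_spec("boosting"))
})

test_that("both classifier kinds separate a separable toy set", {
  set.seed(40)
  x <- rbind(
    matrix(rnorm(40, mean = -2), 20),
    matrix(rnorm(40, mean = 2), 20)
  )
  y <- rep(0:1, each = 20)
  for (kind in c("svm", "ert")) {
    model <- make_classifier(classifier_spec(kind), ncol(x), seed = 2)
    model$fit(x, y)
    scores <- model$score(x)
    expect_true(all(scores >= 0 & scores <= 1))
    expect_equal(roc_auc(scores, y), 1.0)
  }
})

test_that("subject-level splits are disjoint 80/20 partitions", {
  pats <- sprintf("P%02d", 1:10)
  s <- subject_level_split(pats, seed = 3)
  expect_equal(length(s$test), 2)
  expect_equal(length(s$train), 8)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), pats)
  expect_identical(subject_level_split(pats, seed = 3), s)
  expect_error(subject_level_split(pats[1:3]), "at least 5")
})

test_that("bootstrap_cv never scores a vector whose patient was trained on", {
  traj <- default_trajectories()
  res <- bootstrap_cv(
    traj, c("vol_r01", "vol_r02", "total_brain_vol"),
    classifier_spec("ert"),
    n_iter = 30, seed = 8
  )
  both_ids <- names(which(table(traj$patient_id) == 2))
  per_iter <- split(res$oof, res$oof$iteration)
  for (d in per_iter) {
    # at most 20% of patients held out, and both-period patients intact
    expect_lte(length(unique(d$patient_id)), ceiling(0.2 * 103) + 1)
    held_both <- intersect(unique(d$patient_id), both_ids)
    for (pid in held_both) {
      expect_equal(sum(d$patient_id == pid), 2)
    }
  }
  # ledger rows carry the vectors' true labels
  expect_equal(
    res$oof$label,
    traj$period_class[res$oof$row]
  )
})

test_that("bootstrap_cv is reproducible and balance-aware", {
  dat <- toy_classification_data()
  a <- bootstrap_cv(dat, "informative", classifier_spec("svm"),
    n_iter = 2, seed = 5
  )
  b <- bootstrap_cv(dat, "informative", classifier_spec("svm"),
    n_iter = 2, seed = 5
  )
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$oof, b$oof)
  bal <- bootstrap_cv(dat, "informative", classifier_spec("svm"),
    n_iter = 5, seed = 5, balance = "subsample"
  )
  expect_s3_class(bal, "bootstrap_cv")
  expect_error(
    bootstrap_cv(dat, "absent_feature", classifier_spec("svm"), n_iter = 2),
    "unknown feature"
  )
})

test_that("shuffled labels yield chance-level out-of-fold AUC on average", {
  # a single shuffle retains finite-sample label-feature correlation, so
  # average the mean AUC over several independent shuffles
  set.seed(41)
  means <- vapply(1:4, function(i) {
    dat <- toy_classification_data(n_per_class = 25, seed = 200 + i)
    dat$period_class <- sample(dat$period_class)
    res <- bootstrap_cv(dat, c("informative", "noise_1", "noise_2"),
      classifier_spec("ert"),
      n_iter = 25, seed = i
    )
    mean(res$iterations$auc, na.rm = TRUE)
  }, 0)
  # held-out AUC on null data is slightly pessimistic at small n (train- and
  # test-fold class differences anti-correlate around the fixed sample value)
  expect_gt(mean(means), 0.38)
  expect_lt(mean(means), 0.60)
})

test_that("tidy and glance summarise a bootstrap run", {
  dat <- toy_classification_data()
  res <- bootstrap_cv(dat, "informative", classifier_spec("ert"),
    n_iter = 10, seed = 9
  )
  td <- tidy(res)
  expect_setequal(
    td$metric,
    c("auc", "accuracy", "sensitivity", "specificity", "balanced_f", "mcc")
  )
  expect_true(all(td$ci_low <= td$mean & td$mean <= td$ci_high))
  gl <- glance(res)
  expect_equal(gl$n_iter, 10)
  expect_equal(gl$auc_mean, mean(res$iterations$auc, na.rm = TRUE))
})

test_that("greedy selection finds the informative feature first", {
  hits <- 0
  for (seed in 1:8) {
    dat <- toy_classification_data(n_per_class = 20, seed = 100 + seed)
    trace <- greedy_forward_selection(
      dat, c("informative", paste0("noise_", 1:5)),
      classifier_spec("svm"),
      n_iter = 10, seed = seed, max_features = 1
    )
    hits <- hits + (trace$trace$feature[1] == "informative")
  }
  expect_gte(hits, 7)
})

test_that("greedy selection matches exhaustive search on a nested toy", {
  set.seed(43)
  n <- 60
  labels <- rep(0:1, each = n / 2)
  dat <- tibble::tibble(
    patient_id = sprintf("Q%03d", 1:n),
    period_class = labels,
    strong = ifelse(labels == 1, 1, -1) * sample(c(1, 1, 1, 1, -1), n, TRUE),
    medium = ifelse(labels == 1, 1, -1) * sample(c(1, 1, -1), n, TRUE),
    junk = sample(c(-1L, 0L, 1L), n, TRUE)
  )
  feats <- c("strong", "medium", "junk")
  trace <- greedy_forward_selection(dat, feats, classifier_spec("svm"),
    n_iter = 15, seed = 3
  )
  # brute force over all non-empty subsets with the same splits
  subsets <- unlist(
    lapply(1:3, function(k) combn(feats, k, simplify = FALSE)),
    recursive = FALSE
  )
  best <- subsets[[which.max(vapply(subsets, function(s) {
    mean(bootstrap_cv(dat, s, classifier_spec("svm"),
      n_iter = 15, seed = 3
    )$iterations$auc, na.rm = TRUE)
  }, 0))]]
  expect_setequal(trace$selected, best)
  single <- greedy_forward_selection(dat, "strong", classifier_spec("svm"),
    n_iter = 5, seed = 3
  )
  expect_equal(nrow(single$trace), 1)
  expect_equal(single$chosen_size, 1)
})

test_that("ensemble weighting follows the stated formula", {
  expect_equal(
    ensemble_predict(0.6, 0.8, 0.857, 0.817),
    (0.857 * 0.6 + 0.817 * 0.8) / (0.857 + 0.817) # = 0.69761
  )
  expect_equal(ensemble_predict(c(0.2, 0.9), c(0.4, 0.1), 0.7, 0.7), c(0.3, 0.5))
  s <- runif(5)
  expect_equal(ensemble_predict(s, s, 0.9, 0.6), s)
  expect_error(ensemble_predict(0.5, 0.5, 0, 0.5), "positive")
  expect_error(ensemble_predict(c(0.5, 0.2), 0.5, 0.9, 0.5), "equal length")
})

test_that("ensemble_cv recombines aligned runs and guards mismatches", {
  traj <- default_trajectories()
  a <- bootstrap_cv(traj, c("vol_r01", "vol_r02"), classifier_spec("ert"),
    n_iter = 15, seed = 12
  )
  b <- bootstrap_cv(traj, c("disc_r01", "disc_r02"), classifier_spec("ert"),
    n_iter = 15, seed = 12
  )
  en <- ensemble_cv(a, b)
  expect_s3_class(en, "bootstrap_cv")
  expect_equal(en$n_iter, 15)
  expect_equal(sum(en$weights), 1)
  expect_equal(nrow(en$oof), nrow(a$oof))
  mismatched <- bootstrap_cv(traj, c("disc_r01", "disc_r02"),
    classifier_spec("ert"),
    n_iter = 15, seed = 99
  )
  expect_error(ensemble_cv(a, mismatched), "identical")
})

test_that("permute_null shuffles feature series within patients only", {
  co <- tiny_cohort()
  perm <- permute_null(co, seed = 77)
  expect_identical(perm$scan_time_years, co$scan_time_years)
  expect_identical(perm$age, co$age)
  expect_identical(perm$manufacturer, co$manufacturer)
  expect_identical(perm$tiv, co$tiv)
  for (pid in unique(co$patient_id)) {
    i <- co$patient_id == pid
    expect_setequal(perm$vol_r01_L[i], co$vol_r01_L[i])
    expect_setequal(perm$lesion_count[i], co$lesion_count[i])
  }
  expect_false(identical(perm$vol_r01_L, co$vol_r01_L))
  expect_identical(
    tibble::as_tibble(permute_null(co, seed = 77)),
    tibble::as_tibble(perm)
  )
  one <- co[1, ]
  expect_identical(
    tibble::as_tibble(permute_null(one, seed = 1)),
    tibble::as_tibble(one)
  )
})
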