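test_that("default cohort reproduces the study composition", {
  co <- default_cohort()
  expect_equal(length(unique(co$patient_id)), 103)
  traj <- build_trajectory_dataset(normalize_by_tiv(co))
  expect_equal(nrow(traj), 130) # 16 + 60 + 2 x 27 patient-periods
  expect_equal(sum(traj$period_class == 0), 43)
  expect_equal(round(100 * mean(traj$period_class == 0), 1), 33.1)
})

test_that("per-scan fingerprint has 2 x n_region_pairs regional variables", {
  co <- default_cohort()
  expect_equal(sum(grepl("^vol_", names(co))), 144)
  expect_equal(sum(grepl("^disc_", names(co))), 144)
  tiny <- tiny_cohort()
  expect_equal(sum(grepl("^(vol|disc)_", names(tiny))), 16)
})

test_that("class-0 fraction follows exactly from the group counts", {
  for (cfg in list(
    tiny_config(),
    cohort_config(
      n_pre_only = 5, n_post_only = 2, n_both = 4,
      n_region_pairs = 2, seed = 3
    )
  )) {
    traj <- build_trajectory_dataset(normalize_by_tiv(generate_cohort(cfg)))
    expect_equal(
      mean(traj$period_class == 0),
      (cfg$n_pre_only + cfg$n_both) /
        (cfg$n_pre_only + cfg$n_post_only + 2 * cfg$n_both)
    )
  }
})

test_that("generation is bit-reproducible given the seed", {
  a <- generate_cohort(tiny_config(seed = 123))
  b <- generate_cohort(tiny_config(seed = 123))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- generate_cohort(tiny_config(seed = 124))
  expect_false(identical(a$vol_r01_L, c$vol_r01_L))
})

test_that("scan tables satisfy the structural invariants", {
  co <- tiny_cohort()
  by_pat <- split(co, co$patient_id)
  for (scans in by_pat) {
    expect_true(all(diff(scans$scan_time_years) > 0))
    periods <- split_periods(scans)
    for (p in periods) {
      if (nrow(p) > 0) expect_gte(nrow(p), 2)
    }
  }
  disc <- as.matrix(co[grepl("^disc_", names(co))])
  expect_true(all(disc >= 0 & disc <= 1))
  vols <- as.matrix(co[grepl("^vol_", names(co))])
  expect_true(all(vols >= 0))
  expect_true(all(co$lesion_count >= 0))
  expect_true(all(co$tiv > co$total_brain_vol))
  expect_equal(co$total_brain_vol, unname(rowSums(vols)))
})

test_that("lesion burden rises before treatment and plateaus after", {
  co <- default_cohort()
  truth <- cohort_ground_truth(co)
  expect_true(!is.null(truth))
  pre <- dplyr::filter(co, scan_time_years < 0)
  post <- dplyr::filter(co, scan_time_years > 0)
  pre_slopes <- vapply(
    split(pre, pre$patient_id)[table(pre$patient_id) >= 2],
    function(d) fit_slope(d$scan_time_years, d$lesion_count), 0
  )
  post_slopes <- vapply(
    split(post, post$patient_id)[table(post$patient_id) >= 2],
    function(d) fit_slope(d$scan_time_years, d$lesion_count), 0
  )
  expect_gt(mean(pre_slopes), mean(post_slopes))
  expect_gt(mean(pre_slopes), 0.5)
  expect_lt(abs(mean(post_slopes)), 1)
})

test_that("noiseless affected regions return the generating slope exactly", {
  cfg <- cohort_config(
    n_pre_only = 3, n_post_only = 2, n_both = 2, n_region_pairs = 3,
    noise_sd = 0, affected_fraction = 1,
    confounder_effects = zero_confounder_effects(), seed = 5
  )
  co <- generate_cohort(cfg)
  truth <- cohort_ground_truth(co)
  pre <- dplyr::filter(co, scan_time_years < 0)
  for (pid in unique(pre$patient_id)) {
    scans <- dplyr::filter(pre, patient_id == pid)
    if (nrow(scans) < 2) next
    for (pair in truth$affected_pairs) {
      est <- fit_slope(scans$scan_time_years, scans[[paste0("vol_", pair, "_L")]])
      gen <- dplyr::filter(
        truth$slopes,
        patient_id == pid, pair == !!pair, modality == "vol", period == "pre"
      )$slope_L
      expect_equal(est, gen, tolerance = 1e-8)
    }
  }
})

test_that("zero confounder effects leave features unrelated to covariates", {
  cfg <- cohort_config(
    n_pre_only = 10, n_post_only = 30, n_both = 10, n_region_pairs = 3,
    affected_fraction = 0, confounder_effects = zero_confounder_effects(),
    seed = 9
  )
  co <- generate_cohort(cfg)
  # per-feature regression slope on field strength should sit inside its CI of 0
  outside <- 0
  feats <- grep("^vol_", names(co), value = TRUE)
  for (f in feats) {
    fit <- stats::lm(co[[f]] ~ co$field_strength + factor(co$patient_id))
    cf <- summary(fit)$coefficients
    z <- cf[2, 1] / cf[2, 2]
    outside <- outside + (abs(z) > 1.96)
  }
  expect_lte(outside, ceiling(0.25 * length(feats)))
})

test_that("cohort CSV round trip is lossless", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(co),
    ignore_attr = TRUE
  )
  expect_identical(names(back), names(co))
  pairing <- cohort_pairing(back)
  expect_equal(sort(names(pairing$pairs)), sort(names(cohort_pairing(co)$pairs)))
})

test_that("cohort reader validates its input", {
  co <- tiny_cohort()
  path <- withr::local_tempfile(fileext = ".csv")
  broken <- dplyr::select(tibble::as_tibble(co), -scan_time_years)
  readr::write_csv(broken, path)
  expect_error(read_cohort(path), "scan_time_years")
  dup <- dplyr::bind_rows(tibble::as_tibble(co), tibble::as_tibble(co)[1, ])
  readr::write_csv(dup, path)
  expect_error(read_cohort(path), "duplicate")
  expect_error(write_cohort(co[0, ], path), "empty cohort")
  readr::write_csv(tibble::as_tibble(co)[0, ], path)
  expect_error(read_cohort(path), "empty cohort")
})

test_that("cohort config survives a YAML round trip", {
  cfg <- tiny_config(seed = 31, affected_fraction = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back, cfg)
  expect_identical(
    tibble::as_tibble(generate_cohort(back)),
    tibble::as_tibble(generate_cohort(cfg))
  )
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(scans_per_period = c(1, 3)))
  expect_error(cohort_config(affected_fraction = 1.5))
  expect_error(cohort_config(noise_sd = -1))
  expect_error(cohort_config(n_pre_only = 0, n_post_only = 0, n_both = 0))
})
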