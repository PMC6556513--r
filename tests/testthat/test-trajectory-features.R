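test_that("split_periods partitions scans by the sign of scan time", {
  scans <- tibble::tibble(scan_time_years = c(-2, -1, 0.5, 1.5))
  p <- split_periods(scans)
  expect_equal(p$pre$scan_time_years, c(-2, -1))
  expect_equal(p$post$scan_time_years, c(0.5, 1.5))

  one <- split_periods(tibble::tibble(scan_time_years = -1))
  expect_equal(nrow(one$pre), 1)
  expect_equal(nrow(one$post), 0)

  expect_warning(
    z <- split_periods(tibble::tibble(scan_time_years = 0)),
    "t = 0"
  )
  expect_equal(nrow(z$pre), 0)
  expect_equal(nrow(z$post), 0)
})

test_that("fit_slope is the least-squares slope", {
  expect_equal(fit_slope(c(0, 1, 2), c(5, 5, 5)), 0)
  expect_equal(fit_slope(c(0, 1), c(0, 2)), 2)
  expect_equal(fit_slope(c(0, 1, 2), c(1, 2, 4)), 1.5)
  # normal-equations oracle via lm on random series
  set.seed(10)
  for (i in 1:10) {
    t <- sort(runif(sample(2:6, 1), -3, 3))
    v <- rnorm(length(t))
    expect_equal(fit_slope(t, v), unname(coef(lm(v ~ t))[2]))
  }
  expect_error(fit_slope(1, 5), "insufficient scans")
  expect_error(fit_slope(c(1, 1), c(0, 2)), "degenerate times")
  expect_error(fit_slope(c(1, 2), c(0, 1, 2)), "same length")
})

test_that("trajectories are slope signs and collapse by summation", {
  expect_equal(slope_to_trajectory(0.07), 1L)
  expect_equal(slope_to_trajectory(-3.2), -1L)
  expect_equal(slope_to_trajectory(0), 0L)
  expect_error(slope_to_trajectory(Inf))

  expect_equal(collapse_hemispheres(-1, -1), -2L)
  expect_equal(collapse_hemispheres(+1, -1), 0L)
  expect_equal(collapse_hemispheres(+1, +1), +2L)
  expect_error(collapse_hemispheres(2, 0), "\\{-1, 0, \\+1\\}")
  # collapsing is symmetric in hemispheres
  for (l in -1:1) {
    for (r in -1:1) {
      expect_equal(collapse_hemispheres(l, r), collapse_hemispheres(r, l))
    }
  }
})

test_that("trajectories are invariant to increasing affine feature transforms", {
  set.seed(11)
  for (i in 1:20) {
    t <- sort(runif(4, -3, -0.5))
    v <- rnorm(4)
    base <- slope_to_trajectory(fit_slope(t, v))
    scaled <- slope_to_trajectory(fit_slope(t, 7.3 * v + 11))
    expect_equal(scaled, base)
  }
})

test_that("region_pairing pairs homologues and collects singletons", {
  p <- region_pairing(c(
    "vol_r01_L", "vol_r01_R", "disc_r01_L", "disc_r01_R",
    "total_brain_vol", "lesion_count", "tiv"
  ))
  expect_setequal(names(p$pairs), c("vol_r01", "disc_r01"))
  expect_equal(p$pairs$vol_r01, c("vol_r01_L", "vol_r01_R"))
  expect_setequal(p$singletons, c("total_brain_vol", "lesion_count"))
  expect_error(region_pairing(c("vol_r01_L", "total_brain_vol")), "unpaired")
})

test_that("build_trajectory_dataset emits one vector per eligible period", {
  co <- tiny_cohort()
  traj <- build_trajectory_dataset(normalize_by_tiv(co))
  cfg <- tiny_config()
  expect_equal(nrow(traj), cfg$n_pre_only + cfg$n_post_only + 2 * cfg$n_both)
  both_ids <- names(which(table(traj$patient_id) == 2))
  expect_equal(length(both_ids), cfg$n_both)
  for (pid in both_ids) {
    expect_setequal(traj$period_class[traj$patient_id == pid], c(0L, 1L))
  }
  # paired columns stay in {-2..2}, singletons in {-1..1}
  pairing <- cohort_pairing(co)
  for (nm in names(pairing$pairs)) {
    expect_true(all(traj[[nm]] %in% -2:2))
  }
  for (nm in pairing$singletons) {
    expect_true(all(traj[[nm]] %in% -1:1))
  }
})

test_that("single-scan periods are skipped, not imputed", {
  scans <- tibble::tibble(
    patient_id = "P1",
    scan_time_years = c(-1, 0.5, 1.0, 2.0),
    f_L = c(1, 2, 3, 4), f_R = c(2, 2, 1, 0)
  )
  pairing <- region_pairing(c("f_L", "f_R"))
  traj <- build_trajectory_dataset(scans, pairing)
  expect_equal(nrow(traj), 1)
  expect_equal(traj$period_class, 1L)
  expect_equal(traj$f, 0L) # rising left (+1) + falling right (-1)
})

test_that("noiseless trajectories equal the generating slope signs", {
  cfg <- cohort_config(
    n_pre_only = 2, n_post_only = 2, n_both = 2, n_region_pairs = 4,
    noise_sd = 0, affected_fraction = 1,
    confounder_effects = zero_confounder_effects(), seed = 21
  )
  co <- generate_cohort(cfg)
  truth <- cohort_ground_truth(co)
  traj <- build_trajectory_dataset(co, cohort_pairing(co))
  for (i in seq_len(nrow(traj))) {
    pid <- traj$patient_id[i]
    period <- if (traj$period_class[i] == 0) "pre" else "post"
    for (pair in truth$affected_pairs) {
      gen <- dplyr::filter(
        truth$slopes,
        patient_id == pid, pair == !!pair, modality == "vol",
        period == !!period
      )
      expect_equal(
        traj[[paste0("vol_", pair)]][i],
        as.integer(sign(gen$slope_L) + sign(gen$slope_R))
      )
    }
  }
})

test_that("unknown features in the pairing are reported", {
  co <- tiny_cohort()
  bad <- region_pairing(c("vol_zz_L", "vol_zz_R"))
  expect_error(build_trajectory_dataset(co, bad), "unknown feature")
})

test_that("trajectory CSV round trip preserves the dataset", {
  traj <- build_trajectory_dataset(normalize_by_tiv(tiny_cohort()))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(traj, path)
  back <- read_trajectories(path)
  expect_equal(
    as.data.frame(back),
    as.data.frame(traj),
    ignore_attr = TRUE
  )
  readr::write_csv(dplyr::select(tibble::as_tibble(traj), -period_class), path)
  expect_error(read_trajectories(path), "period_class")
})
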