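#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration describing a longitudinal imaging cohort:
#' how many patients carry pre-treatment-only, post-treatment-only, or both
#' scan periods, how scans are spread in time, how many homologous left/right
#' region pairs are simulated, and the effect-size, noise and confounding
#' structure of the features.
#'
#' Defaults emulate a natalizumab-treated multiple-sclerosis cohort followed
#' with routine clinical MRI: 16 patients with at least two pre-treatment
#' scans only, 60 with post-treatment scans only, and 27 with both periods;
#' 72 region pairs yielding 144 regional volumes and 144 regional
#' disconnection estimates per scan; regional atrophy (negative volume
#' slopes) and rising disconnection before treatment, with stabilisation or
#' mild recovery afterwards, in a configurable fraction of regions.
#'
#' @param n_pre_only,n_post_only,n_both Patient counts per scan-availability
#'   group.
#' @param scans_per_period Integer range (min, max); the number of scans in
#'   each period a patient holds is drawn uniformly from this range.
#' @param time_window_years Positive durations (pre_span, post_span): pre
#'   scans fall in (-pre_span, -0.1\], post scans in \[0.1, post_span) years
#'   relative to treatment start.
#' @param n_region_pairs Number of homologous left/right region pairs.
#' @param affected_fraction Fraction of region pairs carrying a
#'   treatment-modulated slope.
#' @param pre_slope_mean,pre_slope_sd Normal distribution of the
#'   pre-treatment annual volume change (mm^3/year, negative for atrophy) in
#'   affected regions.
#' @param post_slope_mean,post_slope_sd Post-treatment volume change
#'   (mm^3/year, near zero or positive) in affected regions.
#' @param disc_pre_slope_mean,disc_pre_slope_sd,disc_post_slope_mean,disc_post_slope_sd
#'   The analogous disconnection slopes (per year, on the \[0, 1\]
#'   disconnection scale) with mirrored signs: rising pre, flat or falling
#'   post.
#' @param noise_sd Shared per-scan measurement noise on regional volumes
#'   (mm^3): scanner/positioning/segmentation variability that shifts every
#'   region of a scan coherently. Disconnection noise is scaled by
#'   `disc_scale`.
#' @param idio_noise_sd Independent per-region measurement noise (mm^3);
#'   `NULL` defaults to `noise_sd / 5`.
#' @param disc_scale Ratio converting volume-scale quantities (noise,
#'   confounder effects) to the disconnection scale.
#' @param confounder_effects Named numeric vector of linear coefficients
#'   mapping covariate design columns to additive offsets on every regional
#'   volume (mm^3 per unit covariate); the same offsets scaled by
#'   `disc_scale` act on disconnection. Recognised names: `age`, `gender_M`,
#'   `manufacturer_B`, `manufacturer_C`, `field_strength`,
#'   `disease_duration`, `edss`, `t1_slice`, `t1_voxel`, `flair_slice`,
#'   `flair_voxel`. Set to `zero_confounder_effects()` for covariate-free
#'   features.
#' @param seed Integer seed making generation fully reproducible.
#' @return An object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_pre_only = 16,
                          n_post_only = 60,
                          n_both = 27,
                          scans_per_period = c(2L, 5L),
                          time_window_years = c(3, 4),
                          n_region_pairs = 72,
                          affected_fraction = 0.3,
                          pre_slope_mean = -30,
                          pre_slope_sd = 10,
                          post_slope_mean = 4,
                          post_slope_sd = 5,
                          disc_pre_slope_mean = 0.005,
                          disc_pre_slope_sd = 0.002,
                          disc_post_slope_mean = -0.0007,
                          disc_post_slope_sd = 0.001,
                          noise_sd = 50,
                          idio_noise_sd = NULL,
                          disc_scale = 2e-4,
                          confounder_effects = default_confounder_effects(),
                          seed = 1L) {
  cfg <- list(
    n_pre_only = as.integer(n_pre_only),
    n_post_only = as.integer(n_post_only),
    n_both = as.integer(n_both),
    scans_per_period = as.integer(scans_per_period),
    time_window_years = as.numeric(time_window_years),
    n_region_pairs = as.integer(n_region_pairs),
    affected_fraction = affected_fraction,
    pre_slope_mean = pre_slope_mean, pre_slope_sd = pre_slope_sd,
    post_slope_mean = post_slope_mean, post_slope_sd = post_slope_sd,
    disc_pre_slope_mean = disc_pre_slope_mean,
    disc_pre_slope_sd = disc_pre_slope_sd,
    disc_post_slope_mean = disc_post_slope_mean,
    disc_post_slope_sd = disc_post_slope_sd,
    noise_sd = noise_sd,
    idio_noise_sd = if (is.null(idio_noise_sd)) noise_sd / 5 else idio_noise_sd,
    disc_scale = disc_scale,
    confounder_effects = confounder_effects,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_confounder_effects <- function() {
  c(
    age = -5, gender_M = 60, manufacturer_B = 100, manufacturer_C = -80,
    field_strength = 120, disease_duration = -3, edss = -8,
    t1_slice = 10, t1_voxel = 40, flair_slice = 5, flair_voxel = 20
  )
}

#' @rdname cohort_config
#' @export
zero_confounder_effects <- function() {
  e <- default_confounder_effects()
  e[] <- 0
  e
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_pre_only >= 0, cfg$n_post_only >= 0, cfg$n_both >= 0,
    cfg$n_pre_only + cfg$n_post_only + cfg$n_both > 0,
    length(cfg$scans_per_period) == 2L,
    cfg$scans_per_period[1] >= 2L,
    cfg$scans_per_period[2] >= cfg$scans_per_period[1],
    length(cfg$time_window_years) == 2L, all(cfg$time_window_years > 0.2),
    cfg$n_region_pairs >= 1L,
    cfg$affected_fraction >= 0, cfg$affected_fraction <= 1,
    cfg$pre_slope_sd >= 0, cfg$post_slope_sd >= 0,
    cfg$disc_pre_slope_sd >= 0, cfg$disc_post_slope_sd >= 0,
    cfg$noise_sd >= 0, cfg$idio_noise_sd >= 0, cfg$disc_scale > 0
  )
  if (cfg$scans_per_period[1] < 2L) {
    stop("each period needs at least 2 scans for a slope", call. = FALSE)
  }
  invisible(cfg)
}

#' Covariate column names of a cohort table
#' @keywords internal
#' @export
cohort_covariate_names <- function() {
  c(
    "age", "gender", "manufacturer", "field_strength", "disease_duration",
    "edss", "t1_slice", "t1_voxel", "flair_slice", "flair_voxel"
  )
}

#' Generate a synthetic longitudinal imaging cohort
#'
#' Simulates one row per scan: patient id, scan time in years relative to
#' treatment start (negative = pre-treatment), ten acquisition/clinical
#' covariates, per-region volumes and disconnection estimates for each of
#' `2 * n_region_pairs` regions, and the global aggregates (total brain
#' volume as the sum of regional volumes, total lesion volume, lesion count,
#' total intracranial volume).
#'
#' Each regional feature follows a piecewise-linear trajectory through its
#' patient baseline at treatment start: in affected region pairs the volume
#' declines pre-treatment and stabilises or recovers post-treatment, while
#' disconnection rises pre-treatment and flattens after; unaffected regions
#' have zero structural slope in both periods. Covariates contribute linear
#' additive offsets per `confounder_effects`, and i.i.d. Gaussian measurement
#' noise is added per scan. Lesion count is a monotone step process (new
#' lesions arrive at a Poisson rate that is high pre-treatment and near zero
#' after), with lesion volume proportional to count.
#'
#' @param config A [cohort_config()].
#' @return A `cohort_tbl`: a tibble of scans carrying attributes
#'   `region_pairing` (see [region_pairing()]), `ground_truth` (the affected
#'   pair set and every generating slope, for parameter-recovery checks) and
#'   `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_pre_only = 2, n_post_only = 2,
#'   n_both = 2, n_region_pairs = 3
#' ))
#' dplyr::count(cohort, patient_id)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)

  n_pat <- config$n_pre_only + config$n_post_only + config$n_both
  groups <- rep(
    c("pre_only", "post_only", "both"),
    c(config$n_pre_only, config$n_post_only, config$n_both)
  )
  ids <- sprintf("P%03d", seq_len(n_pat))

  npairs <- config$n_region_pairs
  pair_names <- sprintf("r%02d", seq_len(npairs))
  n_aff <- round(config$affected_fraction * npairs)
  affected <- sort(sample(pair_names, n_aff))

  # cohort-level anatomy: typical size of each region pair
  pair_vol_mean <- stats::runif(npairs, 4000, 12000)
  pair_disc_mean <- stats::runif(npairs, 0.10, 0.40)

  patients <- purrr::map2(ids, groups, function(id, grp) {
    simulate_patient(id, grp, config,
      pair_names = pair_names, affected = affected,
      pair_vol_mean = pair_vol_mean, pair_disc_mean = pair_disc_mean
    )
  })

  rows <- dplyr::bind_rows(purrr::map(patients, "scans"))
  truth <- dplyr::bind_rows(purrr::map(patients, "slopes"))

  feature_cols <- setdiff(
    names(rows),
    c("patient_id", "scan_time_years", cohort_covariate_names())
  )
  new_cohort_tbl(
    rows,
    region_pairing = region_pairing(feature_cols),
    ground_truth = list(affected_pairs = affected, slopes = truth),
    config = config
  )
}

simulate_patient <- function(id, grp, cfg, pair_names, affected,
                             pair_vol_mean, pair_disc_mean) {
  npairs <- length(pair_names)
  spans <- cfg$time_window_years

  n_scans <- function() {
    sample(seq(cfg$scans_per_period[1], cfg$scans_per_period[2]), 1L)
  }
  pre_times <- if (grp %in% c("pre_only", "both")) {
    sort(stats::runif(n_scans(), -spans[1], -0.1))
  } else {
    numeric(0)
  }
  post_times <- if (grp %in% c("post_only", "both")) {
    sort(stats::runif(n_scans(), 0.1, spans[2]))
  } else {
    numeric(0)
  }
  times <- c(pre_times, post_times)
  ns <- length(times)

  # per-patient clinical state (EDSS and durations indexed to treatment start)
  age0 <- pmin(pmax(stats::rnorm(1, 38, 10), 20), 70)
  gender <- sample(c("M", "F"), 1L, prob = c(44, 80))
  dd0 <- max(stats::rnorm(1, 6.3, 2.2), 0.5)
  edss <- pmin(pmax(stats::rnorm(1, 4.8, 1.7), 0), 10)

  cov <- tibble::tibble(
    age = age0 + times,
    gender = gender,
    manufacturer = sample(c("A", "B", "C"), ns,
      replace = TRUE,
      prob = c(0.5, 0.3, 0.2)
    ),
    field_strength = sample(c(1.5, 3.0), ns, replace = TRUE, prob = c(0.6, 0.4)),
    disease_duration = dd0 + times,
    edss = edss,
    t1_slice = sample(c(1, 3, 6), ns, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    t1_voxel = stats::runif(ns, 0.9, 1.3),
    flair_slice = sample(c(1, 3, 6), ns, replace = TRUE, prob = c(0.4, 0.3, 0.3)),
    flair_voxel = stats::runif(ns, 0.9, 1.3)
  )
  conf_offset <- confounder_offset(cov, cfg$confounder_effects)

  # per-hemisphere baselines and generating slopes; regional anatomy is
  # dominated by a shared per-patient scale (head size, proportional to TIV)
  # so regional features are correlated within patient, as in real data
  tiv <- max(stats::rnorm(1, 1.45e6, 9e4), 1.1e6)
  anatomy <- tiv / 1.45e6
  is_aff <- pair_names %in% affected
  draw_slopes <- function(mean_aff, sd_aff) {
    s <- matrix(0, npairs, 2)
    n <- sum(is_aff)
    if (n > 0) {
      s[is_aff, ] <- stats::rnorm(2 * n, mean_aff, sd_aff)
    }
    s
  }
  vol_base <- matrix(pair_vol_mean * anatomy, npairs, 2)
  disc_shift <- stats::rnorm(1, 0, 0.01)
  disc_base <- matrix(
    pmin(pmax(pair_disc_mean + disc_shift, 0.01), 0.9),
    npairs, 2
  )
  vol_pre <- draw_slopes(cfg$pre_slope_mean, cfg$pre_slope_sd)
  vol_post <- draw_slopes(cfg$post_slope_mean, cfg$post_slope_sd)
  disc_pre <- draw_slopes(cfg$disc_pre_slope_mean, cfg$disc_pre_slope_sd)
  disc_post <- draw_slopes(cfg$disc_post_slope_mean, cfg$disc_post_slope_sd)

  vols <- matrix(NA_real_, ns, 2 * npairs)
  discs <- matrix(NA_real_, ns, 2 * npairs)
  # measurement noise: scanner/positioning/segmentation variability shifts all
  # regions of a scan coherently (dominant shared term) on top of a smaller
  # independent per-region term
  vol_shared <- stats::rnorm(ns, 0, cfg$noise_sd)
  disc_shared <- stats::rnorm(ns, 0, cfg$noise_sd * cfg$disc_scale)
  idio_sd <- cfg$idio_noise_sd
  for (i in seq_len(ns)) {
    t <- times[i]
    sv <- if (t < 0) vol_pre else vol_post
    sd_ <- if (t < 0) disc_pre else disc_post
    v <- vol_base + sv * t + conf_offset[i] + vol_shared[i] +
      matrix(stats::rnorm(2 * npairs, 0, idio_sd), npairs, 2)
    d <- disc_base + sd_ * t + conf_offset[i] * cfg$disc_scale +
      disc_shared[i] +
      matrix(stats::rnorm(2 * npairs, 0, idio_sd * cfg$disc_scale),
        npairs, 2
      )
    vols[i, ] <- pmax(as.vector(v), 0)
    discs[i, ] <- pmin(pmax(as.vector(d), 0), 1)
  }
  # column order: all pairs left hemisphere, then all pairs right
  vol_cols <- c(paste0("vol_", pair_names, "_L"), paste0("vol_", pair_names, "_R"))
  disc_cols <- c(paste0("disc_", pair_names, "_L"), paste0("disc_", pair_names, "_R"))
  colnames(vols) <- vol_cols
  colnames(discs) <- disc_cols

  # lesion load: monotone count, high accrual rate pre-treatment only
  count0 <- stats::rpois(1, 8) + 2
  gaps <- diff(c(times[1], times))
  rate <- ifelse(times < 0, 2.0, 0.05)
  increments <- stats::rpois(ns, rate * gaps)
  increments[1] <- 0
  true_count <- count0 + cumsum(increments)
  # automated lesion segmentation miscounts scan to scan
  lesion_count <- pmax(true_count + round(stats::rnorm(ns, 0, 3)), 0)
  lesion_vol <- pmax(
    true_count * 120 * exp(stats::rnorm(ns, 0, 0.25)),
    0
  )

  tbv <- rowSums(vols)
  tiv <- max(tiv, max(tbv) * 1.15)

  scans <- dplyr::bind_cols(
    tibble::tibble(patient_id = id, scan_time_years = times),
    cov,
    tibble::as_tibble(vols),
    tibble::as_tibble(discs),
    tibble::tibble(
      total_brain_vol = tbv,
      total_lesion_vol = lesion_vol,
      lesion_count = as.numeric(lesion_count),
      tiv = tiv
    )
  )

  slopes <- tibble::tibble(
    patient_id = id,
    pair = rep(pair_names, 4),
    modality = rep(c("vol", "vol", "disc", "disc"), each = npairs),
    period = rep(c("pre", "post", "pre", "post"), each = npairs),
    slope_L = c(vol_pre[, 1], vol_post[, 1], disc_pre[, 1], disc_post[, 1]),
    slope_R = c(vol_pre[, 2], vol_post[, 2], disc_pre[, 2], disc_post[, 2])
  )
  list(scans = scans, slopes = slopes)
}

confounder_offset <- function(cov, effects) {
  e <- function(nm) if (nm %in% names(effects)) effects[[nm]] else 0
  e("age") * cov$age +
    e("gender_M") * (cov$gender == "M") +
    e("manufacturer_B") * (cov$manufacturer == "B") +
    e("manufacturer_C") * (cov$manufacturer == "C") +
    e("field_strength") * (cov$field_strength - 1.5) +
    e("disease_duration") * cov$disease_duration +
    e("edss") * cov$edss +
    e("t1_slice") * cov$t1_slice +
    e("t1_voxel") * cov$t1_voxel +
    e("flair_slice") * cov$flair_slice +
    e("flair_voxel") * cov$flair_voxel
}

new_cohort_tbl <- function(rows, region_pairing, ground_truth = NULL,
                           config = NULL) {
  out <- tibble::as_tibble(rows)
  attr(out, "region_pairing") <- region_pairing
  attr(out, "ground_truth") <- ground_truth
  attr(out, "config") <- config
  class(out) <- c("cohort_tbl", class(out))
  out
}

#' Accessors for cohort metadata
#'
#' @param cohort A `cohort_tbl`.
#' @return `cohort_ground_truth()` returns the generator's affected-pair set
#'   and generating slopes (or `NULL` for cohorts read from disk);
#'   `cohort_pairing()` the [region_pairing()]; `cohort_feature_names()` all
#'   feature columns (regional features plus global aggregates, excluding
#'   `tiv`).
#' @export
cohort_ground_truth <- function(cohort) attr(cohort, "ground_truth")

#' @rdname cohort_ground_truth
#' @export
cohort_pairing <- function(cohort) {
  p <- attr(cohort, "region_pairing")
  if (is.null(p)) {
    feature_cols <- setdiff(
      names(cohort),
      c("patient_id", "scan_time_years", cohort_covariate_names())
    )
    p <- region_pairing(feature_cols)
  }
  p
}

#' @rdname cohort_ground_truth
#' @export
cohort_feature_names <- function(cohort) {
  setdiff(
    names(cohort),
    c("patient_id", "scan_time_years", cohort_covariate_names(), "tiv")
  )
}

#' Write / read a cohort scan table as CSV
#'
#' Long-format CSV, one row per scan, with columns `patient_id,
#' scan_time_years, <covariates>, <features>`. The round trip is lossless on
#' values and row order; generator ground truth is an in-memory attribute and
#' is not serialised.
#'
#' @param cohort A `cohort_tbl` (or plain data frame with the same columns).
#' @param path File path.
#' @return `read_cohort()` returns a `cohort_tbl`.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  readr::write_csv(tibble::as_tibble(cohort), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("patient_id", "scan_time_years", cohort_covariate_names(), "tiv")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop(
      "cohort file is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(tbl) == 0L) stop("empty cohort", call. = FALSE)
  if (anyDuplicated(tbl[c("patient_id", "scan_time_years")]) > 0) {
    stop("duplicate (patient_id, scan_time_years) keys", call. = FALSE)
  }
  feature_cols <- setdiff(
    names(tbl),
    c("patient_id", "scan_time_years", cohort_covariate_names())
  )
  new_cohort_tbl(tbl, region_pairing = region_pairing(feature_cols))
}

#' Write / read a cohort configuration as a flat YAML file
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$confounder_effects <- as.list(x$confounder_effects)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$confounder_effects <- unlist(x$confounder_effects)
  do.call(cohort_config, x)
}
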