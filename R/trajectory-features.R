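#' Pair homologous left/right features and identify singletons
#'
#' Scans a set of feature column names and maps every `<modality>_<region>_L`
#' / `<modality>_<region>_R` pair to one collapsed feature name
#' (`<modality>_<region>`); names without a hemispheric suffix (the global
#' aggregates) become singletons. `tiv` is the normalising denominator, not a
#' predictor, and is excluded.
#'
#' @param feature_names Character vector of feature column names.
#' @return A list of class `region_pairing` with elements `pairs` (named list
#'   collapsed-name -> c(left, right)) and `singletons`.
#' @export
region_pairing <- function(feature_names) {
  feature_names <- setdiff(feature_names, "tiv")
  is_l <- grepl("_L$", feature_names)
  is_r <- grepl("_R$", feature_names)
  stems_l <- sub("_L$", "", feature_names[is_l])
  stems_r <- sub("_R$", "", feature_names[is_r])
  if (!setequal(stems_l, stems_r)) {
    stop("unpaired hemispheric feature(s): ",
      paste(
        c(setdiff(stems_l, stems_r), setdiff(stems_r, stems_l)),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  stems <- sort(unique(stems_l))
  pairs <- stats::setNames(
    purrr::map(stems, ~ c(paste0(.x, "_L"), paste0(.x, "_R"))),
    stems
  )
  structure(
    list(pairs = pairs, singletons = feature_names[!is_l & !is_r]),
    class = "region_pairing"
  )
}

#' Split one patient's scans into pre- and post-treatment periods
#'
#' Treatment starts at time 0. Scans with negative times are pre-treatment,
#' positive times post-treatment; a scan at exactly 0 belongs to neither
#' change regime and is dropped with a warning.
#'
#' @param scans A data frame of one patient's scans with a `scan_time_years`
#'   column.
#' @return A list with elements `pre` and `post`, each a tibble (possibly
#'   empty).
#' @export
split_periods <- function(scans) {
  stopifnot(all(is.finite(scans$scan_time_years)))
  at_zero <- scans$scan_time_years == 0
  if (any(at_zero)) {
    warning("dropping ", sum(at_zero),
      " scan(s) at exactly t = 0 (treatment start)",
      call. = FALSE
    )
  }
  list(
    pre = dplyr::filter(scans, .data$scan_time_years < 0),
    post = dplyr::filter(scans, .data$scan_time_years > 0)
  )
}

#' Least-squares slope of a feature over time
#'
#' Ordinary least-squares slope of `values` on `times`, the rate of change of
#' one imaging feature over one period's scans.
#'
#' @param times Scan times in years.
#' @param values Feature values at those times.
#' @return The slope (units of `values` per year).
#' @examples
#' fit_slope(c(0, 1, 2), c(1, 2, 4)) # 1.5
#' @export
fit_slope <- function(times, values) {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) stop("insufficient scans (need >= 2)", call. = FALSE)
  tc <- times - mean(times)
  sxx <- sum(tc^2)
  if (sxx == 0) stop("degenerate times (zero variance)", call. = FALSE)
  sum(tc * values) / sxx
}

#' Trajectory of a slope: its sign
#'
#' Dichotomises a slope into +1 (increasing), -1 (decreasing) or 0 (exactly
#' no change), discarding magnitude so that trajectories are insensitive to
#' scan timing and feature scale. Zero is mapped only under exact floating
#' equality; continuous features hit it with probability zero, while ordinal
#' or bounded features can genuinely produce it.
#'
#' @param slope Finite numeric slope(s).
#' @return Integer(s) in \{-1, 0, +1\}.
#' @export
slope_to_trajectory <- function(slope) {
  stopifnot(all(is.finite(slope)))
  as.integer(sign(slope))
}

#' Collapse hemispheric trajectories
#'
#' Sums the left and right trajectory of a homologous region pair, yielding a
#' net trajectory in \{-2, -1, 0, +1, +2\}: -2 when both hemispheres
#' decline, +2 when both rise, 0 when they disagree or both are flat.
#'
#' @param left_traj,right_traj Integers in \{-1, 0, +1\}.
#' @return Integer net trajectories.
#' @examples
#' collapse_hemispheres(-1, -1) # -2
#' collapse_hemispheres(+1, -1) # 0
#' @export
collapse_hemispheres <- function(left_traj, right_traj) {
  ok <- function(x) all(x %in% c(-1L, 0L, 1L))
  if (!ok(left_traj) || !ok(right_traj)) {
    stop("hemispheric trajectories must be in {-1, 0, +1}", call. = FALSE)
  }
  as.integer(left_traj) + as.integer(right_traj)
}

#' Build the per-patient-period trajectory dataset
#'
#' For every patient and every period (pre/post) holding at least two scans,
#' fits a least-squares slope per feature, takes its sign, and collapses
#' homologous pairs by summation. Periods with fewer than two scans are
#' skipped. The result is the classifiers' input: one row per
#' patient-period, labelled `period_class` 0 (pre-treatment) or 1
#' (post-treatment).
#'
#' @param cohort A `cohort_tbl`, normally TIV-normalised and deconfounded
#'   first (see [deconfound_cohort()]).
#' @param pairing A [region_pairing()]; defaults to the cohort's own.
#' @return A `traj_tbl` tibble: `patient_id`, `period_class`, then one
#'   integer column per collapsed feature (paired regional features in
#'   \{-2..+2\}, global singletons in \{-1, 0, +1\}).
#' @export
build_trajectory_dataset <- function(cohort, pairing = cohort_pairing(cohort)) {
  stopifnot(inherits(pairing, "region_pairing"))
  all_feats <- unique(c(unlist(pairing$pairs, use.names = FALSE), pairing$singletons))
  missing <- setdiff(all_feats, names(cohort))
  if (length(missing) > 0) {
    stop("pairing references unknown feature(s): ",
      paste(utils::head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }

  per_patient <- split(
    tibble::as_tibble(cohort),
    factor(cohort$patient_id, levels = unique(cohort$patient_id))
  )
  rows <- purrr::imap(per_patient, function(scans, pid) {
    periods <- split_periods(scans)
    purrr::compact(purrr::imap(periods, function(p, period_name) {
      if (nrow(p) < 2L) {
        return(NULL)
      }
      traj <- purrr::map_int(all_feats, function(f) {
        slope_to_trajectory(fit_slope(p$scan_time_years, p[[f]]))
      })
      names(traj) <- all_feats
      collapsed <- purrr::imap_int(
        pairing$pairs,
        ~ collapse_hemispheres(traj[[.x[1]]], traj[[.x[2]]])
      )
      single <- traj[pairing$singletons]
      dplyr::bind_cols(
        tibble::tibble(
          patient_id = pid,
          period_class = if (period_name == "pre") 0L else 1L
        ),
        tibble::as_tibble_row(c(collapsed, single))
      )
    }))
  })
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  class(out) <- c("traj_tbl", class(out))
  out
}

#' Names of the collapsed predictor sets
#'
#' The conventional low-dimensional predictors are the trajectories of the
#' three global aggregates (total brain volume, total lesion volume, lesion
#' count); the high-dimensional sets are the collapsed regional volume and
#' regional disconnection trajectories.
#'
#' @param trajectories A `traj_tbl` from [build_trajectory_dataset()].
#' @return A named list of character vectors: `brain_volume`,
#'   `lesion_count`, `lesion_volume`, `low_dimensional`, `regional_volume`,
#'   `regional_disconnection`.
#' @export
predictor_sets <- function(trajectories) {
  feats <- setdiff(names(trajectories), c("patient_id", "period_class"))
  list(
    brain_volume = intersect("total_brain_vol", feats),
    lesion_count = intersect("lesion_count", feats),
    lesion_volume = intersect("total_lesion_vol", feats),
    low_dimensional = intersect(
      c("total_brain_vol", "total_lesion_vol", "lesion_count"), feats
    ),
    regional_volume = grep("^vol_", feats, value = TRUE),
    regional_disconnection = grep("^disc_", feats, value = TRUE)
  )
}

#' Write / read a trajectory dataset as wide CSV
#'
#' @param trajectories A `traj_tbl`.
#' @param path File path.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(tibble::as_tibble(trajectories), path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("patient_id", "period_class"), names(tbl))
  if (length(missing) > 0) {
    stop("trajectory file is missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  class(tbl) <- c("traj_tbl", class(tbl))
  tbl
}
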