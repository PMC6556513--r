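# shared fixtures, built in code and cached so expensive objects are
# generated once per test run

tiny_config <- function(seed = 7, ...) {
  cohort_config(
    n_pre_only = 3, n_post_only = 4, n_both = 3,
    n_region_pairs = 4, seed = seed, ...
  )
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_cohort <- function() cached("tiny_cohort", generate_cohort(tiny_config()))

default_cohort <- function() {
  cached("default_cohort", generate_cohort(cohort_config(seed = 11)))
}

default_clean <- function() {
  cached("default_clean", deconfound_cohort(default_cohort()))
}

default_trajectories <- function() {
  cached("default_traj", build_trajectory_dataset(default_clean()))
}

# a small labelled dataset with one strongly informative binary feature and
# pure-noise companions, for classifier/selection checks
toy_classification_data <- function(n_per_class = 30, n_noise = 5, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c(0L, 1L), each = n_per_class)
  informative <- ifelse(labels == 1, 1, -1) * sample(c(1, 1, 1, -1), n, TRUE)
  noise <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), n * n_noise, TRUE), n)
  colnames(noise) <- paste0("noise_", seq_len(n_noise))
  dplyr::bind_cols(
    tibble::tibble(
      patient_id = sprintf("T%03d", seq_len(n)),
      period_class = labels,
      informative = informative
    ),
    tibble::as_tibble(noise)
  )
}
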