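# Synthetic qPCR / densitometry measurement layer.

#' Measurement noise model
#'
#' Multiplicative lognormal noise emulating scale-proportional qPCR and
#' western-blot densitometry error, with triplicate sampling and
#' reference-signal (housekeeping gene / loading control) normalization
#' noise.  Draws are mean-corrected (`meanlog = -sigma^2/2`) so the
#' expected raw value equals the true value.
#'
#' @param cv Coefficient of variation of the multiplicative measurement
#'   noise (default 0.15).
#' @param replicates Replicates per (scenario, species, time) (default 3,
#'   matching triplicate biological repeats).
#' @param normalizer_cv Extra lognormal noise on the reference signal used
#'   for normalization (default 0.05).
#' @param seed Integer seed making the generated table reproducible.
#' @return List with class `uprt_noise`.
#' @export
noise_model <- function(cv = 0.15, replicates = 3, normalizer_cv = 0.05,
                        seed = 1) {
  stopifnot(cv >= 0, normalizer_cv >= 0, replicates >= 1)
  structure(list(cv = cv, replicates = as.integer(replicates),
                 normalizer_cv = normalizer_cv, seed = as.integer(seed)),
            class = "uprt_noise")
}

lognormal_sigma <- function(cv) sqrt(log(1 + cv^2))

#' Generate synthetic replicate measurements from a simulated panel
#'
#' Emulates the measurement layer of the wet experiments: the true
#' trajectory value at each 30-min sampling time is multiplied by
#' mean-corrected lognormal noise (`raw_value`), then divided by a noisy
#' unit reference signal (`normalized_value`), for each replicate.
#'
#' @param panel A `uprt_panel` or `uprt_timecourse` tibble.
#' @param noise A [noise_model()].
#' @param grid Sampling times in minutes (must lie within the trajectories).
#' @return Tibble with class `uprt_synthetic` and columns `scenario`,
#'   `species`, `level`, `time_min`, `replicate`, `true_value`,
#'   `raw_value`, `normalized_value`; attributes `noise` and `seed`.
#' @export
generate_measurements <- function(panel, noise = noise_model(),
                                  grid = seq(0, 120, by = 30)) {
  scen <- unique(panel$scenario)
  rng <- range(panel$time_min)
  if (any(grid < rng[1] - 1e-9 | grid > rng[2] + 1e-9)) {
    stop("grid outside the trajectory window", call. = FALSE)
  }
  base <- tidyr::expand_grid(scenario = scen, species = SPECIES,
                             time_min = grid,
                             replicate = seq_len(noise$replicates))
  truth <- base |>
    dplyr::distinct(.data$scenario, .data$species, .data$time_min) |>
    dplyr::mutate(true_value = purrr::pmap_dbl(
      list(.data$scenario, .data$species, .data$time_min),
      function(sc, sp, t) value_at(panel, sp, t, scenario = sc)))
  tbl <- dplyr::left_join(base, truth,
                          by = c("scenario", "species", "time_min"))
  sig <- lognormal_sigma(noise$cv)
  sig_ref <- lognormal_sigma(noise$normalizer_cv)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(noise$seed)
  n <- nrow(tbl)
  meas_noise <- if (sig > 0) rlnorm(n, -sig^2 / 2, sig) else rep(1, n)
  ref_noise <- if (sig_ref > 0) rlnorm(n, -sig_ref^2 / 2, sig_ref) else
    rep(1, n)
  out <- tbl |>
    dplyr::mutate(level = unname(SPECIES_LEVEL[.data$species]),
                  raw_value = .data$true_value * meas_noise,
                  normalized_value = .data$raw_value / ref_noise,
                  .after = "species")
  structure(out, class = c("uprt_synthetic", class(out)),
            noise = noise, grid = grid)
}

# collapse replicates to means and reshape to the (scenario, species,
# time_min, value) layout the call-table builder expects
measurement_means <- function(meas) {
  meas |>
    dplyr::summarise(value = mean(.data$normalized_value),
                     .by = c("scenario", "species", "time_min")) |>
    dplyr::mutate(variant = "synthetic")
}

#' Phenotype-call recovery under measurement noise
#'
#' Robustness check for the phenotype pipeline: for each of `n_runs`
#' seeded noise realizations, replicate-mean synthetic measurements on the
#' 30-min grid are pushed through the call-table builder, and each call row
#' is scored against the call obtained from the same grid without noise.
#'
#' @param params Rate constants (default: shipped calibrated set).
#' @param noise A [noise_model()]; its `seed` field is ignored in favour of
#'   per-run seeds derived from `seed`.
#' @param n_runs Number of noise realizations (>= 1).
#' @param seed Master seed for the per-run seeds.
#' @param spec Call rows to score, default the shipped matrix rows.
#' @param grid Sampling grid (min).
#' @param panel Optional pre-computed panel (to avoid re-integration).
#' @return Tibble: one row per call row with the noiseless `call` and
#'   `recovery`, the fraction of runs reproducing it.
#' @export
call_recovery_experiment <- function(params = default_parameters(),
                                     noise = noise_model(),
                                     n_runs = 100, seed = 1,
                                     spec = NULL,
                                     grid = seq(0, 120, by = 30),
                                     panel = NULL) {
  stopifnot(n_runs >= 1)
  if (is.null(panel)) panel <- run_panel(params, "full")
  if (is.null(spec)) {
    spec <- expected_calls()[, c("scenario", "reference", "species",
                                 "feature")]
  }
  clean <- generate_measurements(
    panel, noise_model(cv = 0, replicates = 1, normalizer_cv = 0,
                       seed = 1), grid)
  base_calls <- build_call_table(measurement_means(clean), spec)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  hits <- matrix(FALSE, n_runs, nrow(spec))
  for (r in seq_len(n_runs)) {
    nm <- noise_model(cv = noise$cv, replicates = noise$replicates,
                      normalizer_cv = noise$normalizer_cv,
                      seed = run_seeds[r])
    meas <- generate_measurements(panel, nm, grid)
    calls <- build_call_table(measurement_means(meas), spec)
    hits[r, ] <- calls$call == base_calls$call
  }
  dplyr::mutate(base_calls, recovery = colMeans(hits))
}
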