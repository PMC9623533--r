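# Qualitative trajectory features and phenotype call tables.

#' Fold-change of a trajectory value against a reference
#'
#' Mirrors the densitometry/qPCR normalization used experimentally: a
#' read-out at time `t` is divided by a reference value (the untreated
#' control at the same time, or the comparator scenario's value at the same
#' time for cross-scenario comparisons).
#'
#' @inheritParams value_at
#' @param ref_value Positive reference value.
#' @return Positive numeric fold-change.
#' @export
fold_change <- function(tc, species, t, ref_value, scenario = NULL) {
  if (!is.numeric(ref_value) || ref_value <= 0) {
    stop("ref_value must be > 0", call. = FALSE)
  }
  value_at(tc, species, t, scenario) / ref_value
}

#' Classify a fold-change into a qualitative call
#'
#' Quantizes fold-changes into `up` / `down` / `unchanged` bands.  The
#' default band (1.3-fold either way) stands in for the significance
#' annotations of the wet-lab read-outs, which report stars rather than
#' effect sizes.
#'
#' @param fc Numeric fold-change(s).
#' @param up_band Threshold at or above which the call is `up` (> 1).
#' @param down_band Threshold at or below which the call is `down` (in
#'   `(0, 1)`).
#' @return Character vector of calls.
#' @export
classify_change <- function(fc, up_band = 1.3, down_band = 1 / 1.3) {
  if (!(down_band > 0 && down_band < 1 && up_band > 1)) {
    stop("need 0 < down_band < 1 < up_band", call. = FALSE)
  }
  dplyr::case_when(
    fc >= up_band ~ "up",
    fc <= down_band ~ "down",
    TRUE ~ "unchanged"
  )
}

#' Detect a transient peak in a trajectory
#'
#' A trajectory shows a transient peak on a window when its dense-grid
#' maximum exceeds both the window-start value and the final value by at
#' least `prominence`, and the final value has decayed to at most
#' `decay` times the peak.  This is the shape contrast between the
#' transient eIF2alpha-P response under tolerable stress and the sustained
#' response under excessive stress.
#'
#' @inheritParams value_at
#' @param window Length-2 numeric window `[t0, t1]` in minutes.
#' @param prominence Minimum peak-to-boundary ratio (> 1).
#' @param decay Maximum final-to-peak ratio for a transient call (in
#'   `(0, 1)`).
#' @return List with `transient` (logical), `peak_time`, `peak_value`.
#' @export
detect_transient_peak <- function(tc, species, window = c(0, 120),
                                  prominence = 1.5, decay = 0.7,
                                  scenario = NULL) {
  stopifnot(prominence > 1, decay > 0, decay < 1)
  d <- tc
  if (!is.null(scenario)) d <- d[d$scenario == scenario, ]
  d <- d[d$species == species &
           d$time_min >= window[1] - 1e-9 &
           d$time_min <= window[2] + 1e-9, ]
  if (!nrow(d)) stop("empty window", call. = FALSE)
  d <- d[order(d$time_min), ]
  i <- which.max(d$value)
  peak <- d$value[i]
  v0 <- d$value[1]
  vf <- d$value[nrow(d)]
  transient <- peak >= prominence * v0 && peak >= prominence * vf &&
    vf <= decay * peak
  list(transient = transient, peak_time = d$time_min[i], peak_value = peak)
}

#' Time to reach a detection threshold
#'
#' First time at which a species reaches an absolute `target` level (or,
#' by default, `frac` of its own value at `t_ref`).  "Rises earlier"
#' comparisons between stress levels use a shared absolute threshold --
#' half the comparator scenario's endpoint value -- mirroring how an
#' earlier appearance on a blot is a detection-threshold crossing, not a
#' statement about each curve's own normalized shape.
#'
#' @inheritParams value_at
#' @param frac Fraction of the `t_ref` value (default 0.5), used when no
#'   `target` is given.
#' @param t_ref Reference endpoint time (default 120 min).
#' @param from Start of the search window (default 0).
#' @param target Optional absolute threshold overriding `frac * value(t_ref)`.
#' @return Crossing time in minutes (`NA` if never reached).
#' @export
crossing_time <- function(tc, species, frac = 0.5, t_ref = 120, from = 0,
                          scenario = NULL, target = NULL) {
  d <- tc
  if (!is.null(scenario)) d <- d[d$scenario == scenario, ]
  d <- d[d$species == species & d$time_min >= from - 1e-9, ]
  d <- d[order(d$time_min), ]
  if (is.null(target)) {
    target <- frac * approx(d$time_min, d$value, xout = t_ref, rule = 2)$y
  }
  idx <- which(d$value >= target)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(d$time_min[1])
  # linear interpolation between the bracketing dense samples
  t0 <- d$time_min[i - 1]; t1 <- d$time_min[i]
  v0 <- d$value[i - 1]; v1 <- d$value[i]
  if (v1 == v0) return(t1)
  t0 + (target - v0) / (v1 - v0) * (t1 - t0)
}

#' The shipped expected phenotype call matrix
#'
#' Qualitative experimental outcomes (and, where the in-silico account
#' differs, both provenance-tagged variants) encoded as one row per
#' (scenario, reference, read-out): `up`, `down`, `unchanged` for level
#' calls at 120 min, `transient_peak`/`sustained` for the eIF2alpha-P shape
#' and `down` on the `t50` feature for "rises earlier" comparisons.  ATF4
#' mRNA under stress carries two provenance tags (`expected_experiment`:
#' unchanged by qPCR; `expected_simulation`: two-fold induction in the
#' in-silico account); scoring against a model panel uses the
#' simulation-tagged rows.
#'
#' @param provenance Which provenance tag to select for the rows that carry
#'   both: `"expected_simulation"` (default, the matrix the model panel is
#'   scored against) or `"expected_experiment"`.
#' @return Tibble with columns `scenario`, `reference`, `species`,
#'   `feature`, `call`, `provenance`, `anchor`.
#' @export
expected_calls <- function(provenance = c("expected_simulation",
                                          "expected_experiment")) {
  provenance <- match.arg(provenance)
  path <- system.file("extdata", "expected_calls.csv",
                      package = "perktriad")
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE) |> as_tibble()
  dual <- tbl |>
    dplyr::count(.data$scenario, .data$reference, .data$species,
                 .data$feature) |>
    dplyr::filter(.data$n > 1)
  keep <- tbl |>
    dplyr::anti_join(dual, by = c("scenario", "reference", "species",
                                  "feature")) |>
    dplyr::bind_rows(
      tbl |>
        dplyr::semi_join(dual, by = c("scenario", "reference", "species",
                                      "feature")) |>
        dplyr::filter(.data$provenance == !!provenance)
    )
  dplyr::arrange(keep, .data$scenario, .data$species, .data$feature)
}

#' Build the observed phenotype call table from a simulated panel
#'
#' Applies [fold_change()] + [classify_change()] at `t_call` for level
#' rows, [detect_transient_peak()] for shape rows and [crossing_time()]
#' ratios for `t50` rows, producing a call per row of `spec`.  References:
#' `CONTROL` rows are compared to the control value at the same time (with
#' a small floor `ref_floor`, since some proteins are exactly absent at
#' rest); cross-scenario rows are compared to the comparator scenario's
#' value at the same time.
#'
#' @param panel A `uprt_panel` containing every referenced scenario.
#' @param spec Tibble with columns `scenario`, `reference`, `species`,
#'   `feature` (`"level"`, `"shape"` or `"t50"`); defaults to the rows of
#'   the shipped expected matrix.
#' @param t_call Read-out time for level calls (min).
#' @param up_band,down_band Bands for [classify_change()] on level rows.
#' @param t50_up_band,t50_down_band Bands for the `t50` crossing-time
#'   ratio.  Timing shifts are resolved on a finer scale than densitometry
#'   levels, so a 10% earlier half-rise already counts as "earlier"
#'   (`down`).
#' @param prominence,decay Parameters for [detect_transient_peak()].
#' @param ref_floor Lower floor applied to reference values.
#' @return Tibble with class `uprt_calls`: `spec` plus columns `call` and
#'   `magnitude` (fold-change or peak ratio where applicable), provenance
#'   `"observed_model"`.
#' @export
build_call_table <- function(panel, spec = NULL, t_call = 120,
                             up_band = 1.3, down_band = 1 / 1.3,
                             t50_up_band = 1.1, t50_down_band = 0.9,
                             prominence = 1.5, decay = 0.7,
                             ref_floor = 0.01) {
  if (is.null(spec)) {
    spec <- expected_calls()[, c("scenario", "reference", "species",
                                 "feature")]
  }
  spec <- as_tibble(spec)
  if (anyDuplicated(spec[, c("scenario", "reference", "species",
                             "feature")])) {
    stop("duplicate (scenario, reference, species, feature) rows in spec",
         call. = FALSE)
  }
  have <- unique(panel$scenario)
  need <- unique(c(spec$scenario, spec$reference))
  miss <- setdiff(need, have)
  if (length(miss)) {
    stop("panel is missing scenario(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  res <- purrr::pmap(spec, function(scenario, reference, species, feature,
                                    ...) {
    if (feature == "level") {
      ref <- max(value_at(panel, species, t_call, scenario = reference),
                 ref_floor)
      fc <- fold_change(panel, species, t_call, ref, scenario = scenario)
      list(call = classify_change(fc, up_band, down_band), magnitude = fc)
    } else if (feature == "shape") {
      pk <- detect_transient_peak(panel, species, window = c(0, t_call),
                                  prominence = prominence, decay = decay,
                                  scenario = scenario)
      list(call = if (pk$transient) "transient_peak" else "sustained",
           magnitude = pk$peak_value)
    } else if (feature == "t50") {
      thr <- 0.5 * value_at(panel, species, t_call, scenario = reference)
      t_sc <- crossing_time(panel, species, scenario = scenario,
                            t_ref = t_call, target = thr)
      t_ref_sc <- crossing_time(panel, species, scenario = reference,
                                t_ref = t_call, target = thr)
      ratio <- t_sc / t_ref_sc
      list(call = classify_change(ratio, t50_up_band, t50_down_band),
           magnitude = ratio)
    } else {
      stop("unknown feature: ", feature, call. = FALSE)
    }
  })
  out <- dplyr::mutate(spec,
                       call = purrr::map_chr(res, "call"),
                       magnitude = purrr::map_dbl(res, "magnitude"),
                       provenance = "observed_model")
  structure(out, class = c("uprt_calls", class(out)))
}

#' Agreement between two call tables
#'
#' Fraction of rows with identical calls, plus the per-row differences.
#'
#' @param observed,expected Call tables sharing the same
#'   (scenario, reference, species, feature) key set.
#' @return Object of class `uprt_agreement`: list with `score`,
#'   `n_rows`, `diff` (tibble of mismatching rows with both calls).
#' @export
agreement_score <- function(observed, expected) {
  keys <- c("scenario", "reference", "species", "feature")
  ko <- do.call(paste, c(observed[keys], sep = "\r"))
  ke <- do.call(paste, c(expected[keys], sep = "\r"))
  if (!setequal(ko, ke) || length(ko) != length(ke)) {
    stop("call-table key sets differ: ",
         paste(union(setdiff(ko, ke), setdiff(ke, ko)), collapse = " | "),
         call. = FALSE)
  }
  j <- dplyr::inner_join(
    dplyr::select(as_tibble(observed), dplyr::all_of(keys),
                  observed_call = "call",
                  magnitude = dplyr::any_of("magnitude")),
    dplyr::select(as_tibble(expected), dplyr::all_of(keys),
                  expected_call = "call"),
    by = keys
  )
  diff <- dplyr::filter(j, .data$observed_call != .data$expected_call)
  structure(list(score = mean(j$observed_call == j$expected_call),
                 n_rows = nrow(j), rows = j, diff = diff),
            class = "uprt_agreement")
}

#' @export
print.uprt_agreement <- function(x, ...) {
  cat(sprintf("Phenotype agreement: %d/%d rows (%.3f)\n",
              x$n_rows - nrow(x$diff), x$n_rows, x$score))
  if (nrow(x$diff)) {
    cat("Mismatches:\n")
    print(as.data.frame(x$diff), row.names = FALSE)
  }
  invisible(x)
}

#' Discriminate the full and null model variants
#'
#' Runs the standard panel under both the full wiring and the null wiring
#' (GADD34-to-ATF4 and CHOP-to-ATF4 loops removed), scores each against the
#' expected call matrix and reports the rows on which only the full variant
#' matches.
#'
#' @param params Rate constants (default: the shipped calibrated set).
#' @param expected Expected call table (default: the shipped matrix,
#'   simulation-tagged rows).
#' @param ... Passed to [run_panel()].
#' @return Object of class `uprt_discrimination`: list with `full_score`,
#'   `null_score`, `discriminating_rows`, and both agreement objects.
#' @export
discriminate_models <- function(params = default_parameters(),
                                expected = expected_calls(), ...) {
  spec <- expected[, c("scenario", "reference", "species", "feature")]
  full <- build_call_table(run_panel(params, "full", ...), spec)
  null <- build_call_table(run_panel(params, "null", ...), spec)
  ag_full <- agreement_score(full, expected)
  ag_null <- agreement_score(null, expected)
  keys <- c("scenario", "reference", "species", "feature")
  disc <- dplyr::anti_join(ag_null$diff, ag_full$diff, by = keys)
  structure(list(full_score = ag_full$score, null_score = ag_null$score,
                 discriminating_rows = disc,
                 full = ag_full, null = ag_null),
            class = "uprt_discrimination")
}

#' @export
print.uprt_discrimination <- function(x, ...) {
  cat(sprintf("full variant:  %.3f\nnull variant:  %.3f\n",
              x$full_score, x$null_score))
  if (nrow(x$discriminating_rows)) {
    cat("Rows matched only by the full variant:\n")
    print(as.data.frame(x$discriminating_rows), row.names = FALSE)
  }
  invisible(x)
}
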