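# broom-style tidiers for the package's result objects.

#' Tidy a calibration result
#'
#' @param x A `uprt_calibration` object.
#' @param ... Unused.
#' @return One row per rate constant (`term`, `estimate`), or, with
#'   `constraints = TRUE`, the evaluated constraint tibble.
#' @param constraints Return the per-constraint evaluation instead of the
#'   parameter estimates.
#' @export
tidy.uprt_calibration <- function(x, constraints = FALSE, ...) {
  if (constraints) return(as_tibble(x$constraints))
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.uprt_calibration
#' @export
glance.uprt_calibration <- function(x, ...) {
  tibble(n_satisfied = x$n_satisfied, n_constraints = x$n_constraints,
         n_violated = x$objective$n_violated,
         anchor_sse = x$objective$anchor_sse,
         seed = x$seed, budget = x$budget, evaluations = x$evaluations)
}

#' Tidy a phenotype agreement result
#'
#' @param x A `uprt_agreement` object.
#' @param ... Unused.
#' @return One row per call row with observed and expected calls.
#' @export
tidy.uprt_agreement <- function(x, ...) {
  as_tibble(x$rows)
}

#' @rdname tidy.uprt_agreement
#' @export
glance.uprt_agreement <- function(x, ...) {
  tibble(score = x$score, n_rows = x$n_rows, n_mismatch = nrow(x$diff))
}

#' Tidy a model-discrimination report
#'
#' @param x A `uprt_discrimination` object.
#' @param ... Unused.
#' @return The discriminating rows (matched only by the full variant).
#' @export
tidy.uprt_discrimination <- function(x, ...) {
  as_tibble(x$discriminating_rows)
}

#' @rdname tidy.uprt_discrimination
#' @export
glance.uprt_discrimination <- function(x, ...) {
  tibble(full_score = x$full_score, null_score = x$null_score,
         n_discriminating = nrow(x$discriminating_rows))
}
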