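# Scenario definitions and ODE integration.

#' Stress program
#'
#' A piecewise-constant ER-stress input: an ordered set of segments
#' `(start, end, S)` that tile the simulation window without gaps.
#'
#' @param segments Data frame with columns `start`, `end` (minutes) and `S`
#'   (dimensionless stress in `[0, 1]`).
#' @return A tibble with class `uprt_stress_program`.
#' @export
stress_program <- function(segments) {
  seg <- as_tibble(segments)
  stopifnot(all(c("start", "end", "S") %in% names(seg)))
  seg <- dplyr::arrange(seg, .data$start)
  if (any(seg$end <= seg$start)) {
    stop("segment times must be strictly increasing", call. = FALSE)
  }
  if (nrow(seg) > 1 && any(abs(seg$start[-1] - seg$end[-nrow(seg)]) > 1e-9)) {
    stop("segments must tile the window without gaps", call. = FALSE)
  }
  if (any(seg$S < 0 | seg$S > 1)) {
    stop("stress level S must lie in [0, 1]", call. = FALSE)
  }
  structure(seg, class = c("uprt_stress_program", class(seg)))
}

#' Define a simulation scenario
#'
#' A scenario couples a stress program with an intervention state (and its
#' activation window) on a time axis.  Negative times represent
#' pretreatment (e.g. guanabenz added 60 min before the stressor).
#'
#' @param name Scenario identifier.
#' @param stress A [stress_program()].  Its segments must tile
#'   `[t_start, t_end]`.
#' @param iv An [interventions()] state.
#' @param iv_window Length-2 numeric: the window on which the interventions
#'   are active; defaults to the whole scenario window.
#' @param t_start,t_end Scenario window in minutes.
#' @return A list with class `uprt_scenario`.
#' @export
scenario <- function(name, stress, iv = interventions(),
                     iv_window = c(t_start, t_end),
                     t_start = 0, t_end = 120) {
  if (t_start >= t_end) stop("t_start must be < t_end", call. = FALSE)
  if (abs(min(stress$start) - t_start) > 1e-9 ||
      abs(max(stress$end) - t_end) > 1e-9) {
    stop("stress program must tile [t_start, t_end]", call. = FALSE)
  }
  if (iv_window[1] < t_start - 1e-9 || iv_window[2] > t_end + 1e-9) {
    stop("intervention window must lie within the scenario window",
         call. = FALSE)
  }
  structure(list(name = name, stress = stress, iv = iv,
                 iv_window = iv_window, t_start = t_start, t_end = t_end),
            class = "uprt_scenario")
}

#' The standard eight-scenario experiment panel
#'
#' Reproduces the in-silico experiment set: untreated control, tolerable
#' (low) and excessive (high) stress for 120 min, guanabenz pretreatment
#' (60 min) followed by high stress, CHOP or GADD34 silencing combined with
#' high stress, and CHOP or GADD34 overexpression combined with high
#' stress.  Interventions that are in place before the stressor is added
#' (guanabenz, siRNA transfection, overexpression constructs) are active
#' from a 60-min pretreatment window at zero stress, mirroring the wet
#' protocol ordering.
#'
#' @param S_high,S_low Stress magnitudes for the excessive and tolerable
#'   treatments.
#' @param eps_gb Residual GADD34 activity under guanabenz.
#' @param si_chop,si_gadd34,oe_chop,oe_gadd34 Intervention strengths, see
#'   [interventions()].
#' @return Named list of eight [scenario()] objects.
#' @export
standard_panel <- function(S_high = uprt_defaults()$S_high,
                           S_low = uprt_defaults()$S_low,
                           eps_gb = uprt_defaults()$eps_gb,
                           si_chop = uprt_defaults()$si_chop,
                           si_gadd34 = uprt_defaults()$si_gadd34,
                           oe_chop = uprt_defaults()$oe_chop,
                           oe_gadd34 = uprt_defaults()$oe_gadd34) {
  flat <- function(S, t0 = 0) {
    stress_program(tibble(start = t0, end = 120, S = S))
  }
  pre <- function(S) {
    stress_program(tibble(start = c(-60, 0), end = c(0, 120), S = c(0, S)))
  }
  list(
    CONTROL = scenario("CONTROL", flat(0)),
    LOW = scenario("LOW", flat(S_low)),
    HIGH = scenario("HIGH", flat(S_high)),
    GB_HIGH = scenario("GB_HIGH", pre(S_high),
                       iv = interventions(gb_active = TRUE, eps_gb = eps_gb),
                       t_start = -60),
    SI_CHOP_HIGH = scenario("SI_CHOP_HIGH", pre(S_high),
                            iv = interventions(si_chop = si_chop),
                            t_start = -60),
    SI_GADD34_HIGH = scenario("SI_GADD34_HIGH", pre(S_high),
                              iv = interventions(si_gadd34 = si_gadd34),
                              t_start = -60),
    OE_CHOP_HIGH = scenario("OE_CHOP_HIGH", pre(S_high),
                            iv = interventions(oe_chop = oe_chop),
                            t_start = -60),
    OE_GADD34_HIGH = scenario("OE_GADD34_HIGH", pre(S_high),
                              iv = interventions(oe_gadd34 = oe_gadd34),
                              t_start = -60)
  )
}

# piecewise-constant inputs for one scenario: breakpoints from the stress
# segments and the intervention window
scenario_pieces <- function(sc) {
  brk <- sort(unique(round(c(sc$stress$start, sc$stress$end,
                             sc$iv_window), 9)))
  brk <- brk[brk >= sc$t_start - 1e-9 & brk <= sc$t_end + 1e-9]
  purrr::map2(head(brk, -1), brk[-1], function(a, b) {
    mid <- (a + b) / 2
    i <- which(sc$stress$start - 1e-9 <= mid & mid <= sc$stress$end + 1e-9)[1]
    on <- mid >= sc$iv_window[1] && mid <= sc$iv_window[2]
    list(start = a, end = b, S = sc$stress$S[i], iv_on = on)
  })
}

#' Integrate a scenario
#'
#' Integrates the ODE system over a scenario window, starting from the
#' zero-stress resting state of the chosen variant.  Integration is
#' performed piecewise over the scenario's constant-input segments with the
#' state handed over exactly at each boundary, using `deSolve::lsoda` and
#' the package's compiled right-hand side.  The trajectory is recorded on a
#' fine fixed grid (`dense_step`) that contains the reporting `grid`, so
#' shape features (transient peaks, crossing times) do not depend on the
#' coarse 30-min sampling cadence.
#'
#' @param sc A [scenario()].
#' @param params Rate-constant vector, see [validate_parameters()].
#' @param loops Loop configuration of the variant, see [loop_config()].
#' @param grid Reporting times (minutes) within the scenario window.
#' @param dense_step Step of the fine recording grid (minutes).
#' @param rtol,atol Integrator tolerances.
#' @param compiled Use the compiled right-hand side (fast path); set to
#'   `FALSE` to integrate with the R-level [uprt_rhs()].
#' @return A tibble with class `uprt_timecourse` and columns `scenario`,
#'   `variant`, `species`, `time_min`, `value`, at dense resolution;
#'   attribute `grid` holds the reporting times.
#' @export
simulate_scenario <- function(sc, params, loops = loop_config("full"),
                              grid = seq(0, 120, by = 30),
                              dense_step = 0.5, rtol = 1e-8, atol = 1e-10,
                              compiled = TRUE) {
  params <- validate_parameters(params)
  if (any(grid < sc$t_start - 1e-9 | grid > sc$t_end + 1e-9)) {
    stop("grid must lie within the scenario window", call. = FALSE)
  }
  state <- resting_state(params, loops)
  pieces <- scenario_pieces(sc)
  rows <- vector("list", length(pieces))
  for (k in seq_along(pieces)) {
    pc <- pieces[[k]]
    times <- sort(unique(c(seq(pc$start, pc$end, by = dense_step), pc$end,
                           grid[grid >= pc$start & grid <= pc$end])))
    iv <- sc$iv
    gb_scale <- if (pc$iv_on && iv$gb_active) iv$eps_gb else 1
    on <- as.numeric(pc$iv_on)
    if (compiled) {
      parms <- pack_parms(params, loops, S = pc$S, gb_scale = gb_scale,
                          si_chop = on * iv$si_chop,
                          si_gadd34 = on * iv$si_gadd34,
                          oe_chop = on * iv$oe_chop,
                          oe_gadd34 = on * iv$oe_gadd34)
      out <- deSolve::lsoda(state, times, func = "perktriad_derivs",
                            parms = parms, dllname = "perktriad",
                            initfunc = "perktriad_initmod",
                            rtol = rtol, atol = atol, maxsteps = 20000)
    } else {
      iv_eff <- interventions(
        gb_active = pc$iv_on && iv$gb_active, eps_gb = iv$eps_gb,
        si_chop = on * iv$si_chop, si_gadd34 = on * iv$si_gadd34,
        oe_chop = on * iv$oe_chop, oe_gadd34 = on * iv$oe_gadd34)
      fr <- function(t, y, p) {
        list(unname(uprt_rhs(y, t, params, loops, stress = pc$S,
                             iv = iv_eff)))
      }
      out <- deSolve::lsoda(state, times, func = fr, parms = NULL,
                            rtol = rtol, atol = atol)
    }
    m <- unclass(out)
    if (attr(out, "istate")[1] < 0 ||
        abs(m[nrow(m), "time"] - pc$end) > 1e-6) {
      stop(sprintf("integration failed on [%g, %g] of scenario %s",
                   pc$start, pc$end, sc$name), call. = FALSE)
    }
    vals <- m[, SPECIES, drop = FALSE]
    if (any(vals < -1e-6) || any(vals[, "eP"] > 1 + 1e-6)) {
      stop(sprintf("invariant violation in scenario %s", sc$name),
           call. = FALSE)
    }
    vals[vals < 0] <- 0
    vals[, "eP"] <- pmin(vals[, "eP"], 1)
    rows[[k]] <- tibble(
      time_min = rep(m[, "time"], times = length(SPECIES)),
      species = rep(SPECIES, each = nrow(m)),
      value = as.vector(vals)
    )
    state <- setNames(vals[nrow(vals), ], SPECIES)
  }
  tc <- dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$time_min, .data$species, .keep_all = TRUE) |>
    dplyr::arrange(.data$species, .data$time_min) |>
    dplyr::mutate(scenario = sc$name,
                  variant = attr(loops, "variant") %||% "custom",
                  .before = 1)
  structure(tc, class = c("uprt_timecourse", class(tc)), grid = grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario panel under one model variant
#'
#' @inheritParams simulate_scenario
#' @param panel Named list of scenarios, default [standard_panel()].
#' @param variant `"full"` or `"null"` (shortcut for [loop_config()]), or a
#'   `uprt_loops` object via `loops`.
#' @param ... Passed to [simulate_scenario()].
#' @return A tibble with class `uprt_panel`: all trajectories stacked, with
#'   columns `scenario`, `variant`, `species`, `time_min`, `value`.
#' @export
run_panel <- function(params, variant = "full",
                      panel = standard_panel(), loops = NULL, ...) {
  if (is.null(loops)) loops <- loop_config(variant)
  out <- purrr::map(panel, function(sc) {
    tryCatch(simulate_scenario(sc, params, loops, ...),
             error = function(e) {
               stop(sprintf("scenario %s: %s", sc$name, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  grid <- attr(out[[1]], "grid")
  res <- dplyr::bind_rows(out)
  structure(res, class = c("uprt_panel", "uprt_timecourse", class(res)),
            grid = grid)
}

#' Interpolate a trajectory value
#'
#' Linear interpolation of a species trajectory at time `t` from the dense
#' recording grid of a time course or panel.
#'
#' @param tc A `uprt_timecourse`/`uprt_panel` tibble.
#' @param species One of `eP, mA, A, mC, C, mG, G`.
#' @param t Time in minutes.
#' @param scenario Scenario name (required when `tc` holds several).
#' @return Numeric value.
#' @export
value_at <- function(tc, species, t, scenario = NULL) {
  d <- tc
  if (!is.null(scenario)) d <- d[d$scenario == scenario, ]
  if (!nrow(d)) stop("no such scenario in panel: ", scenario, call. = FALSE)
  d <- d[d$species == species, ]
  if (t < min(d$time_min) - 1e-9 || t > max(d$time_min) + 1e-9) {
    stop("t outside the trajectory window", call. = FALSE)
  }
  approx(d$time_min, d$value, xout = t, rule = 2)$y
}
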