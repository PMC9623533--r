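# Constraint set, constraint evaluation and randomized calibration search.

#' The shipped qualitative constraint set
#'
#' Machine-evaluable encoding of the qualitative time-course outcomes the
#' calibrated model must reproduce, one row per constraint.  "Significant" /
#' "slight" changes are quantized once here into fold-change bands (down at
#' least 25% or 50%, within 20-30%, and a +/-25% band around the stated
#' two-fold inductions) and the same bands are reused by the phenotype
#' call table, so a parameter set satisfying the constraints also matches
#' the expected call matrix.
#'
#' Features: `fold` (fold-change of `species` in `scenario` vs `reference`
#' at `t = 120` min must lie in `[lo, hi]`), `transient` (transient peak
#' with peak time in `[lo, hi]` min), `sustained` (value at 120 min at
#' least `lo` times the window maximum), `t50` (ratio of times to cross
#' half the comparator's 120-min level, scenario vs reference, in
#' `[lo, hi]`).
#'
#' @return Tibble with columns `id`, `feature`, `scenario`, `reference`,
#'   `species`, `lo`, `hi`, `note`.
#' @export
constraint_set <- function() {
  tribble_ <- function(...) tibble::tribble(...)
  tribble_(
    ~id, ~feature, ~scenario, ~reference, ~species, ~lo, ~hi, ~note,
    "low_ep_transient", "transient", "LOW", "CONTROL", "eP", 30, 90,
    "transient eIF2a-P peak between 30 and 90 min under tolerable stress",
    "low_A_up", "fold", "LOW", "CONTROL", "A", 1.3, Inf,
    "ATF4 protein induced by tolerable stress",
    "low_C_up", "fold", "LOW", "CONTROL", "C", 1.3, Inf,
    "CHOP protein induced by tolerable stress",
    "low_G_up", "fold", "LOW", "CONTROL", "G", 1.3, Inf,
    "GADD34 protein induced by tolerable stress",
    "low_mC_up", "fold", "LOW", "CONTROL", "mC", 1.3, Inf,
    "CHOP mRNA markedly increased under tolerable stress",
    "low_mA_up", "fold", "LOW", "CONTROL", "mA", 1.3, 2.5,
    "ATF4 mRNA induced (about two-fold in the simulated account)",
    "low_mG_up", "fold", "LOW", "CONTROL", "mG", 1.3, 2.5,
    "GADD34 mRNA induced about two-fold",
    "high_ep_sustained", "sustained", "HIGH", "CONTROL", "eP", 0.8, Inf,
    "eIF2a-P remains at >= 80% of its maximum at 120 min",
    "high_A_earlier", "t50", "HIGH", "LOW", "A", 0, 0.9,
    "ATF4 protein rises earlier under excessive stress",
    "high_C_earlier", "t50", "HIGH", "LOW", "C", 0, 0.9,
    "CHOP protein rises earlier under excessive stress",
    "high_mC_up", "fold", "HIGH", "CONTROL", "mC", 3, Inf,
    "CHOP mRNA strongly induced",
    "high_mA_twofold", "fold", "HIGH", "CONTROL", "mA", 1.5, 2.5,
    "ATF4 mRNA induced two-fold (quantitative anchor)",
    "high_mG_twofold", "fold", "HIGH", "CONTROL", "mG", 1.5, 2.5,
    "GADD34 mRNA induced two-fold (quantitative anchor)",
    "high_A_up", "fold", "HIGH", "CONTROL", "A", 1.3, Inf,
    "ATF4 protein induced by excessive stress",
    "high_C_up", "fold", "HIGH", "CONTROL", "C", 1.3, Inf,
    "CHOP protein induced by excessive stress",
    "high_G_up", "fold", "HIGH", "CONTROL", "G", 1.3, Inf,
    "GADD34 protein induced by excessive stress",
    "gb_A_down", "fold", "GB_HIGH", "HIGH", "A", 0, 0.75,
    "ATF4 protein down at least 25% under guanabenz",
    "gb_mC_down", "fold", "GB_HIGH", "HIGH", "mC", 0, 0.75,
    "CHOP mRNA down at least 25% under guanabenz",
    "gb_C_down", "fold", "GB_HIGH", "HIGH", "C", 0, 0.75,
    "CHOP protein down at least 25% under guanabenz",
    "gb_G_modest_down", "fold", "GB_HIGH", "HIGH", "G", 0.3, 1 / 1.3,
    "GADD34 protein modestly reduced under guanabenz",
    "gb_ep_not_lower", "fold", "GB_HIGH", "HIGH", "eP", 1.0, 1.3,
    "eIF2a-P at 120 min not below the untreated high-stress level",
    "gb_mA_band", "fold", "GB_HIGH", "HIGH", "mA", 0.78, 1.28,
    "ATF4 mRNA essentially unchanged by guanabenz",
    "gb_mG_band", "fold", "GB_HIGH", "HIGH", "mG", 0.78, 1.28,
    "GADD34 mRNA within a tolerance band under guanabenz",
    "si_mC_down", "fold", "SI_CHOP_HIGH", "HIGH", "mC", 0, 0.5,
    "CHOP mRNA down at least 50% under silencing",
    "si_C_down", "fold", "SI_CHOP_HIGH", "HIGH", "C", 0, 0.5,
    "CHOP protein down at least 50% under silencing",
    "si_G_down", "fold", "SI_CHOP_HIGH", "HIGH", "G", 0, 0.75,
    "GADD34 protein down at least 25% under CHOP silencing",
    "si_mG_band", "fold", "SI_CHOP_HIGH", "HIGH", "mG", 0.78, 1.28,
    "GADD34 mRNA unchanged under CHOP silencing",
    "si_mA_band", "fold", "SI_CHOP_HIGH", "HIGH", "mA", 0.8, 1.2,
    "ATF4 mRNA unchanged under CHOP silencing",
    "si_A_band", "fold", "SI_CHOP_HIGH", "HIGH", "A", 0.8, 1.2,
    "ATF4 protein unchanged under CHOP silencing",
    "si_ep_band", "fold", "SI_CHOP_HIGH", "HIGH", "eP", 1 / 1.3, 1.3,
    "eIF2a-P similar with and without CHOP silencing",
    "oe_chop_C_up", "fold", "OE_CHOP_HIGH", "HIGH", "C", 1.5, Inf,
    "CHOP overexpression raises CHOP at least 1.5-fold over high stress",
    "oe_gadd34_C_up", "fold", "OE_GADD34_HIGH", "HIGH", "C", 1.5, Inf,
    "GADD34 overexpression raises CHOP at least 1.5-fold over high stress"
  )
}

# ids of the two quantitative fold-change anchors used in the secondary
# objective
ANCHOR_IDS <- c("high_mA_twofold", "high_mG_twofold")

# --- panel-matrix representation (shared by the public evaluator and the
# fast search path) ---------------------------------------------------------

# convert a uprt_panel tibble into the list-of-matrices form
as_panel_matrices <- function(panel) {
  split(as_tibble(panel), panel$scenario) |>
    purrr::map(function(d) {
      w <- tidyr::pivot_wider(d[, c("time_min", "species", "value")],
                              names_from = "species",
                              values_from = "value") |>
        dplyr::arrange(.data$time_min)
      have <- intersect(SPECIES, names(w))
      list(time = w$time_min, Y = as.matrix(w[, have, drop = FALSE]))
    })
}

# direct scenario integration to matrices, compiled RHS only; used by the
# calibration search where tibble construction would dominate the runtime
simulate_panel_matrices <- function(params, loops,
                                    scenarios = standard_panel(),
                                    dt = 1, rtol = 1e-6, atol = 1e-8,
                                    maxsteps = 20000) {
  y0 <- resting_state(params, loops)
  purrr::map(scenarios, function(sc) {
    if (all(sc$stress$S == 0) && !sc$iv$gb_active && sc$iv$si_chop == 0 &&
        sc$iv$si_gadd34 == 0 && sc$iv$oe_chop == 0 && sc$iv$oe_gadd34 == 0) {
      tm <- seq(sc$t_start, sc$t_end, by = dt)
      return(list(time = tm,
                  Y = matrix(rep(y0, each = length(tm)), ncol = 7,
                             dimnames = list(NULL, SPECIES))))
    }
    state <- y0
    pieces <- scenario_pieces(sc)
    tml <- list(); Yl <- list()
    for (pc in pieces) {
      times <- unique(c(seq(pc$start, pc$end, by = dt), pc$end))
      on <- as.numeric(pc$iv_on)
      gb_scale <- if (pc$iv_on && sc$iv$gb_active) sc$iv$eps_gb else 1
      parms <- pack_parms(params, loops, S = pc$S, gb_scale = gb_scale,
                          si_chop = on * sc$iv$si_chop,
                          si_gadd34 = on * sc$iv$si_gadd34,
                          oe_chop = on * sc$iv$oe_chop,
                          oe_gadd34 = on * sc$iv$oe_gadd34)
      # stiff corner cases of random parameter draws can make lsoda chatty;
      # genuine failures are detected below via istate / early return
      out <- suppressWarnings(
        deSolve::lsoda(state, times, func = "perktriad_derivs",
                       parms = parms, dllname = "perktriad",
                       initfunc = "perktriad_initmod",
                       rtol = rtol, atol = atol, maxsteps = maxsteps))
      m <- unclass(out)
      if (attr(out, "istate")[1] < 0 ||
          abs(m[nrow(m), 1] - pc$end) > 1e-6) {
        stop(sprintf("integration failed in scenario %s", sc$name),
             call. = FALSE)
      }
      tml[[length(tml) + 1]] <- m[, 1]
      Yl[[length(Yl) + 1]] <- m[, SPECIES, drop = FALSE]
      state <- setNames(m[nrow(m), SPECIES], SPECIES)
    }
    tm <- do.call(c, tml)
    Y <- do.call(rbind, Yl)
    keep <- !duplicated(tm)
    list(time = tm[keep], Y = Y[keep, , drop = FALSE])
  })
}

pm_value_at <- function(pm, scenario, species, t) {
  s <- pm[[scenario]]
  if (is.null(s)) stop("panel lacks scenario ", scenario, call. = FALSE)
  if (!species %in% colnames(s$Y)) {
    stop("panel lacks species ", species, " in scenario ", scenario,
         call. = FALSE)
  }
  approx(s$time, s$Y[, species], xout = t, rule = 2)$y
}

#' Evaluate the constraint set on a simulated panel
#'
#' @param panel A `uprt_panel` (as from [run_panel()]) containing the
#'   scenarios the constraints reference.
#' @param constraints Constraint tibble, default [constraint_set()].
#' @param ref_floor Floor applied to reference values in fold-changes.
#' @return The constraint tibble with columns `value` (the measured
#'   fold-change / ratio / peak time), `satisfied` (logical) and
#'   `violation` (0 when satisfied; a continuous measure of how far outside
#'   the band the value lies otherwise).
#' @export
evaluate_constraints <- function(panel, constraints = constraint_set(),
                                 ref_floor = 0.01) {
  pm <- if (inherits(panel, "uprt_panel") || is.data.frame(panel)) {
    as_panel_matrices(panel)
  } else {
    panel
  }
  eval_constraints_pm(pm, constraints, ref_floor)
}

eval_constraints_pm <- function(pm, constraints, ref_floor = 0.01) {
  n <- nrow(constraints)
  value <- numeric(n); satisfied <- logical(n); violation <- numeric(n)
  for (i in seq_len(n)) {
    cs <- constraints[i, ]
    if (cs$feature == "fold") {
      ref <- max(pm_value_at(pm, cs$reference, cs$species, 120), ref_floor)
      fc <- pm_value_at(pm, cs$scenario, cs$species, 120) / ref
      value[i] <- fc
      satisfied[i] <- fc >= cs$lo && fc <= cs$hi
      violation[i] <- band_violation(fc, cs$lo, cs$hi)
    } else if (cs$feature == "transient") {
      s <- pm[[cs$scenario]]
      win <- s$time >= 0
      v <- s$Y[win, cs$species]; tm <- s$time[win]
      pk <- which.max(v)
      ratio <- v[length(v)] / max(v[pk], 1e-12)
      prom_ok <- v[pk] >= 1.5 * v[1] && v[pk] >= 1.5 * v[length(v)]
      in_win <- tm[pk] >= cs$lo && tm[pk] <= cs$hi
      value[i] <- tm[pk]
      satisfied[i] <- prom_ok && ratio <= 0.7 && in_win
      violation[i] <- max(0, ratio - 2 / 3) / (2 / 3) +
        (if (in_win) 0 else 1) + (if (prom_ok) 0 else 1)
    } else if (cs$feature == "sustained") {
      s <- pm[[cs$scenario]]
      win <- s$time >= 0
      v <- s$Y[win, cs$species]
      ratio <- v[length(v)] / max(max(v), 1e-12)
      value[i] <- ratio
      satisfied[i] <- ratio >= cs$lo
      violation[i] <- max(0, cs$lo - ratio) / cs$lo
    } else if (cs$feature == "t50") {
      thr <- 0.5 * pm_value_at(pm, cs$reference, cs$species, 120)
      r <- pm_t50(pm, cs$scenario, cs$species, thr) /
        pm_t50(pm, cs$reference, cs$species, thr)
      value[i] <- r
      satisfied[i] <- is.finite(r) && r >= cs$lo && r <= cs$hi
      violation[i] <- if (is.finite(r)) band_violation(r, cs$lo, cs$hi) else 2
    }
  }
  dplyr::mutate(constraints, value = value, satisfied = satisfied,
                violation = violation)
}

band_violation <- function(x, lo, hi) {
  if (!is.finite(x) || x <= 0) return(2)
  v <- 0
  if (lo > 0 && x < lo) v <- log(lo / x)
  if (is.finite(hi) && x > hi) v <- log(x / hi)
  min(v, 2)
}

pm_t50 <- function(pm, scenario, species, target = NULL) {
  s <- pm[[scenario]]
  win <- s$time >= 0
  v <- s$Y[win, species]; tm <- s$time[win]
  if (is.null(target)) target <- 0.5 * v[length(v)]
  idx <- which(v >= target)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(tm[1])
  tm[i - 1] + (target - v[i - 1]) / (v[i] - v[i - 1]) * (tm[i] - tm[i - 1])
}

# --- randomized search -----------------------------------------------------

#' Default log-uniform search bounds
#'
#' Rates default to `[1e-3, 10]` per minute; dimensionless coupling
#' coefficients (`k_GA`, `k_CA`, `k_SC`, `k_CG`) to `[0.1, 100]`.
#'
#' @return Tibble with columns `param`, `lo`, `hi`.
#' @export
default_bounds <- function() {
  couplings <- c("k_GA", "k_CA", "k_SC", "k_CG")
  tibble(param = PARAM_NAMES,
         lo = ifelse(PARAM_NAMES %in% couplings, 0.1, 1e-3),
         hi = ifelse(PARAM_NAMES %in% couplings, 100, 10))
}

lhs_draws <- function(n, bounds) {
  u <- lhs::randomLHS(n, nrow(bounds))
  lo <- log(bounds$lo); hi <- log(bounds$hi)
  draws <- exp(sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  colnames(draws) <- bounds$param
  draws
}

# lexicographic objective: first minimize violated-constraint count, then the
# sum of squared log fold errors on the two-fold anchors
panel_objective <- function(params, loops, constraints, scenarios, dt = 1) {
  ev <- tryCatch(
    eval_constraints_pm(
      simulate_panel_matrices(params, loops, scenarios, dt = dt),
      constraints),
    error = function(e) NULL
  )
  if (is.null(ev)) {
    return(list(n_violated = nrow(constraints) + 1L, anchor_sse = Inf,
                total_violation = Inf, ev = NULL))
  }
  anchors <- ev[ev$id %in% ANCHOR_IDS, ]
  sse <- sum(log(pmax(anchors$value, 1e-6) / 2)^2)
  list(n_violated = sum(!ev$satisfied), anchor_sse = sse,
       total_violation = sum(ev$violation), ev = ev)
}

obj_better <- function(a, b) {
  if (a$n_violated != b$n_violated) return(a$n_violated < b$n_violated)
  if (a$total_violation != b$total_violation) {
    return(a$total_violation < b$total_violation)
  }
  a$anchor_sse < b$anchor_sse
}

#' Constraint-based randomized calibration search
#'
#' Latin-hypercube sampling of the rate constants in log space, followed by
#' coordinate-wise multiplicative refinement of the best draw.  The
#' objective is lexicographic: first the number of violated constraints,
#' then a continuous total violation, then the squared log-error on the
#' two-fold mRNA anchors, so feasibility is never traded against anchor
#' fit.  Deterministic for a given `seed`.
#'
#' @param seed Integer RNG seed.
#' @param budget Total number of panel evaluations (>= 1); 60% is spent on
#'   the initial Latin-hypercube draws.
#' @param bounds Bounds tibble as [default_bounds()].
#' @param loops Variant to calibrate (default full).
#' @param constraints Constraint tibble.
#' @param start Optional named parameter vector included as an initial
#'   candidate (e.g. to refine a previous result).
#' @param dt Search-time sampling step in minutes (integration accuracy is
#'   re-checked at the end at reporting tolerances).
#' @return Object of class `uprt_calibration`: list with `params`,
#'   `satisfied` (constraint ids), `n_satisfied`, `n_constraints`,
#'   `objective`, `seed`, `budget`, `evaluations`, `constraints` (the
#'   evaluated tibble at the final parameters).
#' @export
calibrate <- function(seed = 1, budget = 200, bounds = default_bounds(),
                      loops = loop_config("full"),
                      constraints = constraint_set(),
                      start = NULL, dt = 1) {
  stopifnot(budget >= 1, nrow(bounds) > 0, all(bounds$lo > 0),
            all(bounds$hi >= bounds$lo))
  set.seed(seed)
  scenarios <- standard_panel()
  n_init <- max(1L, min(budget, ceiling(budget * 0.6)))
  draws <- lhs_draws(n_init, bounds)
  evals <- 0L
  best <- NULL
  consider <- function(p) {
    obj <- panel_objective(p, loops, constraints, scenarios, dt)
    evals <<- evals + 1L
    if (is.null(best) || obj_better(obj, best$obj)) {
      best <<- list(params = p, obj = obj)
    }
  }
  if (!is.null(start)) consider(validate_parameters(start))
  for (i in seq_len(nrow(draws))) {
    if (evals >= budget) break
    consider(setNames(draws[i, ], bounds$param))
  }
  # coordinate-wise multiplicative refinement of the incumbent
  factors <- c(1.6, 1 / 1.6, 1.2, 1 / 1.2, 1.05, 1 / 1.05)
  while (evals < budget) {
    improved <- FALSE
    for (pn in sample(bounds$param)) {
      if (evals >= budget) break
      for (f in factors) {
        if (evals >= budget) break
        cand <- best$params
        cand[pn] <- min(max(cand[pn] * f,
                            bounds$lo[bounds$param == pn]),
                        bounds$hi[bounds$param == pn])
        prev <- best$obj
        consider(cand)
        if (obj_better(best$obj, prev)) {
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  final_ev <- best$obj$ev
  structure(list(
    params = validate_parameters(best$params),
    satisfied = if (is.null(final_ev)) character(0) else
      final_ev$id[final_ev$satisfied],
    n_satisfied = if (is.null(final_ev)) 0L else sum(final_ev$satisfied),
    n_constraints = nrow(constraints),
    objective = best$obj[c("n_violated", "total_violation", "anchor_sse")],
    seed = seed, budget = budget, evaluations = evals,
    constraints = final_ev
  ), class = "uprt_calibration")
}

#' @export
print.uprt_calibration <- function(x, ...) {
  cat(sprintf(
    "Calibration (seed %d, %d evaluations): %d/%d constraints satisfied\n",
    x$seed, x$evaluations, x$n_satisfied, x$n_constraints))
  invisible(x)
}

#' Null-variant feasibility search
#'
#' Draws parameter sets for the null wiring (no GADD34-to-ATF4 or
#' CHOP-to-ATF4 loop) by Latin-hypercube sampling and evaluates the full
#' constraint set for each, recording the maximum number of satisfied
#' constraints and whether any draw jointly satisfies the high-stress
#' constraints together with the guanabenz "ATF4 protein down" constraint.
#' Without the GADD34-to-ATF4 loop, guanabenz acts only on the phosphatase
#' arm, so eIF2alpha-P (and with it ATF4 translation) can only rise under
#' guanabenz; the search operationalizes the infeasibility of the simple
#' wiring.
#'
#' @param seed Integer RNG seed.
#' @param n_draws Number of Latin-hypercube draws (default 10000).
#' @param bounds Bounds tibble as [default_bounds()].
#' @param constraints Constraint tibble.
#' @param dt Sampling step for the search integrations.
#' @return List with `max_satisfied`, `n_constraints`, `any_full_set`,
#'   `any_gb_plus_high` (joint satisfaction described above), `n_draws`,
#'   `seed`, and `best_draw` (parameters of the best draw).
#' @export
null_feasibility_search <- function(seed = 1, n_draws = 10000,
                                    bounds = default_bounds(),
                                    constraints = constraint_set(),
                                    dt = 2) {
  set.seed(seed)
  loops <- loop_config("null")
  scenarios <- standard_panel()
  draws <- lhs_draws(n_draws, bounds)
  high_ids <- constraints$id[startsWith(constraints$id, "high_")]
  max_sat <- -1L
  best_draw <- NULL
  any_full <- FALSE
  any_gb_high <- FALSE
  for (i in seq_len(n_draws)) {
    p <- setNames(draws[i, ], bounds$param)
    ev <- tryCatch(
      eval_constraints_pm(
        simulate_panel_matrices(p, loops, scenarios, dt = dt,
                                rtol = 1e-5, atol = 1e-7),
        constraints),
      error = function(e) NULL
    )
    if (is.null(ev)) next
    ns <- sum(ev$satisfied)
    if (ns > max_sat) {
      max_sat <- ns
      best_draw <- p
    }
    if (ns == nrow(constraints)) any_full <- TRUE
    sat <- setNames(ev$satisfied, ev$id)
    if (all(sat[high_ids]) && sat[["gb_A_down"]]) any_gb_high <- TRUE
  }
  list(max_satisfied = max_sat, n_constraints = nrow(constraints),
       any_full_set = any_full, any_gb_plus_high = any_gb_high,
       n_draws = n_draws, seed = seed, best_draw = best_draw)
}
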