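# The ODE right-hand side and the zero-stress resting state.

#' Right-hand side of the PERK-triangle ODE system
#'
#' Evaluates the time derivatives of the seven state variables: `eP`, the
#' phosphorylated fraction of eIF2alpha (total conserved and scaled to 1);
#' `mA`/`A`, ATF4 mRNA and protein; `mC`/`C`, CHOP mRNA and protein;
#' `mG`/`G`, GADD34 mRNA and protein, all in relative units.
#'
#' The wiring: stress drives eIF2alpha phosphorylation and ATF4
#' transcription; eIF2alpha-P drives ATF4 translation; ATF4 transactivates
#' CHOP and GADD34 mRNAs; proteins are translated proportionally to their
#' mRNAs; CHOP protein is additionally activated by stress; GADD34 enhances
#' ATF4 translation (positive loop) while CHOP inhibits it (negative loop);
#' CHOP enhances GADD34 protein synthesis; GADD34 dephosphorylates
#' eIF2alpha-P.  Each of the four feedback connections can be toggled via
#' `loops`.  Enhancements enter as multiplicative `(1 + k*X)` factors and the
#' single inhibition as `1/(1 + k*X)`; all other kinetics are linear mass
#' action.
#'
#' @param state Named (or canonically ordered) numeric vector of the 7 state
#'   variables `eP, mA, A, mC, C, mG, G`; must be finite, non-negative,
#'   with `eP <= 1`.
#' @param t Time in minutes (the system is autonomous within a scenario
#'   segment; `t` is accepted for integrator compatibility).
#' @param params Parameter vector, see [validate_parameters()].
#' @param loops Loop configuration, see [loop_config()].
#' @param stress Dimensionless ER-stress level `S` in `[0, 1]`.
#' @param iv Intervention state, see [interventions()].
#' @return Named numeric vector of the 7 derivatives (min^-1).
#' @export
uprt_rhs <- function(state, t = 0, params, loops = loop_config("full"),
                     stress = 0, iv = interventions()) {
  state <- check_state(state)
  if (!is.numeric(stress) || length(stress) != 1 || !is.finite(stress) ||
      stress < 0 || stress > 1) {
    stop("`stress` must be a single value in [0, 1]", call. = FALSE)
  }
  p <- as.list(validate_parameters(params))
  L <- as.numeric(loops[LOOP_NAMES])
  gb_scale <- if (isTRUE(iv$gb_active)) iv$eps_gb else 1

  eP <- state[["eP"]]; mA <- state[["mA"]]; A <- state[["A"]]
  mC <- state[["mC"]]; C <- state[["C"]]
  mG <- state[["mG"]]; G <- state[["G"]]
  G_act <- G * gb_scale

  d_eP <- p$k_ph * stress * (1 - eP) -
    (p$k_dp0 + L[4] * p$k_dpG * G_act) * eP
  d_mA <- p$k_smA0 + p$k_smA * stress - p$k_dmA * mA
  d_A <- p$k_sA * mA * eP * (1 + L[1] * p$k_GA * G_act) /
    (1 + L[2] * p$k_CA * C) - p$k_dA * A
  d_mC <- p$k_smC0 + p$k_smC * A - (p$k_dmC + iv$si_chop) * mC
  d_C <- p$k_sC * mC * (1 + p$k_SC * stress) + iv$oe_chop - p$k_dC * C
  d_mG <- p$k_smG0 + p$k_smG * A - (p$k_dmG + iv$si_gadd34) * mG
  d_G <- p$k_sG * mG * (1 + L[3] * p$k_CG * C) + iv$oe_gadd34 - p$k_dG * G

  setNames(c(d_eP, d_mA, d_A, d_mC, d_C, d_mG, d_G), SPECIES)
}

check_state <- function(state) {
  if (length(state) != 7) stop("state must have 7 components", call. = FALSE)
  if (is.null(names(state))) names(state) <- SPECIES else
    state <- state[SPECIES]
  if (any(!is.finite(state))) {
    stop("invalid state: non-finite component", call. = FALSE)
  }
  if (any(state < 0) || state[["eP"]] > 1) {
    stop("invalid state: components must be >= 0 with eP <= 1",
         call. = FALSE)
  }
  state
}

#' Zero-stress resting state
#'
#' The pre-treatment control condition: the steady state of the system at
#' `S = 0` with no interventions.  At zero stress the phosphorylation term
#' vanishes, so `eP = 0` and hence ATF4 protein `A = 0`; the remaining
#' balances are linear and solved in closed form:
#' `mA = k_smA0/k_dmA`, `mC = k_smC0/k_dmC`,
#' `C = k_sC*mC/k_dC`, `mG = k_smG0/k_dmG`,
#' `G = k_sG*mG*(1 + [L3]*k_CG*C)/k_dG`.
#' The residual of the right-hand side at the returned state is checked
#' against `tol`.
#'
#' @inheritParams uprt_rhs
#' @param tol Maximum permitted absolute derivative at the returned state.
#' @return Named numeric state vector (the resting state).
#' @export
resting_state <- function(params, loops = loop_config("full"),
                          tol = 1e-9) {
  p <- as.list(validate_parameters(params))
  L3 <- as.numeric(loops[["chop_to_gadd34"]])
  mA <- p$k_smA0 / p$k_dmA
  mC <- p$k_smC0 / p$k_dmC
  C <- p$k_sC * mC / p$k_dC
  mG <- p$k_smG0 / p$k_dmG
  G <- p$k_sG * mG * (1 + L3 * p$k_CG * C) / p$k_dG
  st <- setNames(c(0, mA, 0, mC, C, mG, G), SPECIES)
  resid <- max(abs(uprt_rhs(st, 0, params, loops, stress = 0)))
  if (resid > tol) {
    stop(sprintf("resting state failed to converge: residual %.3e", resid),
         call. = FALSE)
  }
  st
}
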