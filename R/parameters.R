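# Model parameters, loop configurations and intervention states.

PARAM_NAMES <- c(
  "k_ph", "k_dp0", "k_dpG",
  "k_smA0", "k_smA", "k_dmA",
  "k_sA", "k_GA", "k_CA", "k_dA",
  "k_smC0", "k_smC", "k_dmC",
  "k_sC", "k_SC", "k_dC",
  "k_smG0", "k_smG", "k_dmG",
  "k_sG", "k_CG", "k_dG"
)

# degradation/turnover rates that must be strictly positive so a unique
# non-negative resting state exists at zero stress
DEGRADATION_NAMES <- c("k_dp0", "k_dmA", "k_dA", "k_dmC", "k_dC",
                       "k_dmG", "k_dG")

LOOP_NAMES <- c("gadd34_to_atf4", "chop_to_atf4", "chop_to_gadd34",
                "gadd34_to_eif2aP")

#' Validate a model parameter vector
#'
#' Checks that `params` is a complete named, non-negative rate vector for the
#' PERK-triangle model (units min^-1 on the relative-concentration scale) and
#' that every degradation rate is strictly positive, so that a unique
#' non-negative resting state exists at zero stress.
#'
#' @param params Named numeric vector with entries `k_ph, k_dp0, k_dpG,
#'   k_smA0, k_smA, k_dmA, k_sA, k_GA, k_CA, k_dA, k_smC0, k_smC, k_dmC,
#'   k_sC, k_SC, k_dC, k_smG0, k_smG, k_dmG, k_sG, k_CG, k_dG`.
#' @return The validated parameter vector, invisibly reordered to the
#'   canonical name order.
#' @export
validate_parameters <- function(params) {
  if (is.list(params)) params <- unlist(params)
  if (!is.numeric(params) || is.null(names(params))) {
    stop("`params` must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(PARAM_NAMES, names(params))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  params <- params[PARAM_NAMES]
  if (any(!is.finite(params)) || any(params < 0)) {
    stop("all parameters must be finite and >= 0", call. = FALSE)
  }
  if (any(params[DEGRADATION_NAMES] <= 0)) {
    stop("degradation rates (", paste(DEGRADATION_NAMES, collapse = ", "),
         ") must be > 0", call. = FALSE)
  }
  params
}

#' Loop configuration of a model variant
#'
#' The regulatory wiring contains four toggleable feedback connections:
#' the GADD34-to-ATF4 translational enhancement (`gadd34_to_atf4`), the
#' CHOP-to-ATF4 inhibition (`chop_to_atf4`), the CHOP-to-GADD34 protein-level
#' enhancement (`chop_to_gadd34`) and the GADD34-mediated dephosphorylation
#' of eIF2alpha-P (`gadd34_to_eif2aP`).  The *full* variant has all four on;
#' the *null* variant lacks the two ATF4-directed loops and keeps the other
#' two, i.e. it is the wiring without the newly proposed feedbacks.
#'
#' @param variant `"full"`, `"null"`, or `"custom"`.
#' @param gadd34_to_atf4,chop_to_atf4,chop_to_gadd34,gadd34_to_eif2aP
#'   Logical toggles, used when `variant = "custom"`.
#' @return A named logical vector of length 4 with class `uprt_loops`.
#' @export
loop_config <- function(variant = c("full", "null", "custom"),
                        gadd34_to_atf4 = TRUE, chop_to_atf4 = TRUE,
                        chop_to_gadd34 = TRUE, gadd34_to_eif2aP = TRUE) {
  variant <- match.arg(variant)
  loops <- switch(variant,
    full = c(TRUE, TRUE, TRUE, TRUE),
    null = c(FALSE, FALSE, TRUE, TRUE),
    custom = c(gadd34_to_atf4, chop_to_atf4, chop_to_gadd34,
               gadd34_to_eif2aP)
  )
  loops <- setNames(as.logical(loops), LOOP_NAMES)
  if (any(is.na(loops))) stop("loop toggles must be TRUE/FALSE", call. = FALSE)
  structure(loops, class = c("uprt_loops", class(loops)),
            variant = variant)
}

#' Intervention state
#'
#' Pharmacological / genetic interventions overlaid on a stress program:
#' guanabenz scales the effective GADD34 activity (in both the
#' dephosphorylation and the ATF4-promotion terms) by `eps_gb`; siRNA
#' knockdown adds first-order degradation to the targeted mRNA; constitutive
#' overexpression adds a zeroth-order synthesis term to the targeted protein.
#'
#' @param gb_active Logical; guanabenz present.
#' @param eps_gb Residual GADD34 activity under guanabenz, in `[0, 1)`.
#' @param si_chop,si_gadd34 Extra first-order mRNA degradation rates
#'   (min^-1) from siRNA silencing.
#' @param oe_chop,oe_gadd34 Constitutive protein synthesis rates (relative
#'   units min^-1) from overexpression constructs.
#' @return A list with class `uprt_interventions`.
#' @export
interventions <- function(gb_active = FALSE, eps_gb = 0.1,
                          si_chop = 0, si_gadd34 = 0,
                          oe_chop = 0, oe_gadd34 = 0) {
  rates <- c(si_chop = si_chop, si_gadd34 = si_gadd34,
             oe_chop = oe_chop, oe_gadd34 = oe_gadd34)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("intervention rates must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(eps_gb) || eps_gb < 0 || eps_gb >= 1) {
    stop("eps_gb must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(gb_active = isTRUE(gb_active), eps_gb = eps_gb,
         si_chop = si_chop, si_gadd34 = si_gadd34,
         oe_chop = oe_chop, oe_gadd34 = oe_gadd34),
    class = "uprt_interventions"
  )
}

#' Shipped calibrated parameter set
#'
#' Returns the package's default rate constants for the full model variant.
#' The set was obtained by the constraint-based calibration in
#' [calibrate()] (seeded randomized search plus coordinate refinement) and
#' satisfies the entire shipped [constraint_set()]; the values are stored in
#' `inst/extdata/default_params.yaml` together with the loop toggles.
#'
#' @return Named numeric vector of 22 rate constants (min^-1).
#' @export
default_parameters <- function() {
  cfg <- read_model_config(system.file("extdata", "default_params.yaml",
                                       package = "perktriad"))
  cfg$params
}

# Default scenario-level constants (stress magnitudes, intervention
# strengths).  S_high/S_low are the dimensionless stress inputs standing for
# 10 uM and 0.1 uM thapsigargin; eps_gb is partial GADD34 inhibition by
# guanabenz; oe_* are chosen so that either construct alone at S = 0 at
# least doubles the resting protein level.
uprt_defaults <- function() {
  list(S_high = 1, S_low = 0.22, eps_gb = 0.1,
       si_chop = 0.045, si_gadd34 = 0.045,
       oe_chop = 0.06, oe_gadd34 = 0.017)
}

# pack params + loops + segment-level inputs into the 32-slot vector the
# compiled derivs function expects
pack_parms <- function(params, loops, S = 0, gb_scale = 1,
                       si_chop = 0, si_gadd34 = 0,
                       oe_chop = 0, oe_gadd34 = 0) {
  c(unname(params[PARAM_NAMES]), as.numeric(loops[LOOP_NAMES]),
    S, gb_scale, si_chop, si_gadd34, oe_chop, oe_gadd34)
}
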