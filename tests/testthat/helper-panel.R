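# Shared fixtures: panels are expensive enough to build once per test run.

.cache <- new.env(parent = emptyenv())

cached_panel <- function(variant = "full") {
  key <- paste0("panel_", variant)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- run_panel(default_parameters(), variant)
  }
  .cache[[key]]
}

# a small, fully hand-specified parameter set for unit tests that should not
# depend on the shipped calibration
toy_params <- function(...) {
  p <- c(k_ph = 0.2, k_dp0 = 0.02, k_dpG = 0.5,
         k_smA0 = 0.1, k_smA = 0.1, k_dmA = 0.1,
         k_sA = 0.05, k_GA = 1, k_CA = 0.5, k_dA = 0.1,
         k_smC0 = 0.01, k_smC = 0.05, k_dmC = 0.05,
         k_sC = 0.05, k_SC = 0.5, k_dC = 0.05,
         k_smG0 = 0.05, k_smG = 0.05, k_dmG = 0.05,
         k_sG = 0.05, k_CG = 0.5, k_dG = 0.05)
  mods <- c(...)
  p[names(mods)] <- mods
  p
}

# seeded log-uniform random parameter draws for property tests
random_params <- function(n, seed) {
  b <- default_bounds()
  set.seed(seed)
  u <- matrix(runif(n * nrow(b)), n, nrow(b))
  draws <- exp(sweep(sweep(u, 2, log(b$hi) - log(b$lo), "*"), 2,
                     log(b$lo), "+"))
  colnames(draws) <- b$param
  draws
}

# build a long-format trajectory tibble from a function of time, for
# feature-extraction tests with known shapes
synthetic_tc <- function(f, times = seq(0, 120, by = 0.5),
                         species = "eP", scenario = "TEST") {
  tibble::tibble(scenario = scenario, variant = "custom",
                 species = species, time_min = times,
                 value = vapply(times, f, numeric(1)))
}
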