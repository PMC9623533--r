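# Trajectory features, call tables and model discrimination.

test_that("fold_change divides by the reference and validates it", {
  tc <- synthetic_tc(function(t) 1.2, species = "A")
  expect_equal(fold_change(tc, "A", 60, ref_value = 1.2), 1.0)
  expect_equal(fold_change(tc, "A", 60, ref_value = 0.6), 2.0)
  tc2 <- synthetic_tc(function(t) 2.4, species = "A")
  expect_equal(fold_change(tc2, "A", 120, ref_value = 1.2), 2.0)
  expect_error(fold_change(tc, "A", 60, ref_value = 0), "ref_value")
  expect_error(fold_change(tc, "A", 300, ref_value = 1), "window")
})

test_that("classify_change quantizes fold-changes into call bands", {
  expect_equal(classify_change(1.0), "unchanged")
  expect_equal(classify_change(2.0), "up")
  expect_equal(classify_change(0.5), "down")
  expect_equal(classify_change(c(1.31, 1.29, 0.76)),
               c("up", "unchanged", "down"))
  expect_error(classify_change(1, up_band = 0.9), "down_band")
})

test_that("transient-peak detection separates shapes", {
  rising <- synthetic_tc(function(t) t / 120)
  expect_false(detect_transient_peak(rising, "eP")$transient)
  # triangle 0 -> 1 at 45 min -> 0.1: a hand-checkable transient
  tri <- synthetic_tc(function(t) {
    if (t <= 45) t / 45 else max(1 - (t - 45) * 0.9 / 75, 0.1)
  })
  pk <- detect_transient_peak(tri, "eP")
  expect_true(pk$transient)
  expect_equal(pk$peak_time, 45)
  expect_equal(pk$peak_value, 1)
  expect_error(detect_transient_peak(tri, "eP", window = c(200, 300)),
               "empty")
})

test_that("the calibrated model shows the low-stress transient eIF2a-P peak", {
  pan <- cached_panel("full")
  pk <- detect_transient_peak(pan, "eP", scenario = "LOW")
  expect_true(pk$transient)
  expect_gte(pk$peak_time, 30)
  expect_lte(pk$peak_time, 90)
  # and the excessive-stress response is sustained
  pk_high <- detect_transient_peak(pan, "eP", scenario = "HIGH")
  expect_false(pk_high$transient)
})

test_that("crossing_time interpolates threshold crossings", {
  ramp <- synthetic_tc(function(t) t / 120, species = "A")
  expect_equal(crossing_time(ramp, "A"), 60)            # half of endpoint
  expect_equal(crossing_time(ramp, "A", target = 0.25), 30)
  flat <- synthetic_tc(function(t) 0, species = "A")
  expect_equal(crossing_time(flat, "A", target = 1), NA_real_)
})

test_that("GADD34 mRNA doubles under high stress relative to control", {
  pan <- cached_panel("full")
  ref <- value_at(pan, "mG", 120, scenario = "CONTROL")
  fc <- fold_change(pan, "mG", 120, ref, scenario = "HIGH")
  expect_gte(fc, 1.5)
  expect_lte(fc, 2.5)
})

test_that("build_call_table handles degenerate specs", {
  pan <- cached_panel("full")
  empty <- build_call_table(pan, spec = tibble::tibble(
    scenario = character(), reference = character(),
    species = character(), feature = character()))
  expect_equal(nrow(empty), 0)
  dup <- tibble::tibble(scenario = c("HIGH", "HIGH"),
                        reference = c("CONTROL", "CONTROL"),
                        species = c("mG", "mG"),
                        feature = c("level", "level"))
  expect_error(build_call_table(pan, spec = dup), "duplicate")
  missing <- tibble::tibble(scenario = "NOSUCH", reference = "CONTROL",
                            species = "mG", feature = "level")
  expect_error(build_call_table(pan, spec = missing), "NOSUCH")
})

test_that("CHOP silencing leaves ATF4 unchanged at both molecular levels", {
  obs <- build_call_table(cached_panel("full"))
  atf4 <- obs[obs$scenario == "SI_CHOP_HIGH" & obs$species %in% c("mA", "A"), ]
  expect_equal(nrow(atf4), 2)
  expect_true(all(atf4$call == "unchanged"))
})

test_that("agreement_score counts matching rows and reports diffs", {
  obs <- build_call_table(cached_panel("full"))
  self <- agreement_score(obs, obs)
  expect_equal(self$score, 1.0)
  expect_equal(nrow(self$diff), 0)
  # flip one call out of n: score (n-1)/n and one diff row
  flipped <- obs
  flipped$call[1] <- if (obs$call[1] == "up") "down" else "up"
  ag <- agreement_score(obs, flipped)
  expect_equal(ag$score, (nrow(obs) - 1) / nrow(obs))
  expect_equal(nrow(ag$diff), 1)
  expect_error(agreement_score(obs, obs[-1, ]), "key")
})

test_that("widening the unchanged band never flips up and down calls", {
  pan <- cached_panel("full")
  spec <- expected_calls()[, c("scenario", "reference", "species", "feature")]
  narrow <- build_call_table(pan, spec, up_band = 1.3, down_band = 1 / 1.3)
  wide <- build_call_table(pan, spec, up_band = 2, down_band = 0.5)
  lv <- narrow$feature == "level"
  changed <- lv & narrow$call != wide$call
  expect_true(all(wide$call[changed] == "unchanged"))
})

test_that("the expected matrix stores both provenance variants of ATF4 mRNA", {
  sim <- expected_calls("expected_simulation")
  lab <- expected_calls("expected_experiment")
  keys <- c("scenario", "reference", "species", "feature")
  expect_identical(sim[keys], lab[keys])
  expect_false(anyDuplicated(sim[keys]) > 0)
  ma <- sim$species == "mA" & sim$scenario %in% c("LOW", "HIGH")
  expect_true(all(sim$call[ma] == "up"))
  expect_true(all(lab$call[ma] == "unchanged"))
})

test_that("only the full wiring reproduces the expected call matrix", {
  ag_full <- agreement_score(build_call_table(cached_panel("full")),
                             expected_calls())
  ag_null <- agreement_score(build_call_table(cached_panel("null")),
                             expected_calls())
  expect_equal(ag_full$score, 1.0)
  expect_lt(ag_null$score, 1.0)
  expect_true("A" %in% ag_null$diff$species)
})

test_that("discrimination degenerates correctly", {
  p <- default_parameters()
  # the model's own calls are reproduced perfectly by construction
  own <- build_call_table(cached_panel("full"))
  own$provenance <- "expected_simulation"
  rep1 <- discriminate_models(p, expected = own)
  expect_equal(rep1$full_score, 1.0)
  # with both new-loop coefficients at zero the toggles are inert
  p0 <- p; p0[["k_GA"]] <- 0; p0[["k_CA"]] <- 0
  rep0 <- discriminate_models(p0, expected = own)
  expect_equal(rep0$full_score, rep0$null_score)
  expect_equal(nrow(rep0$discriminating_rows), 0)
})

test_that("tidiers expose scores and diffs as tibbles", {
  ag <- agreement_score(build_call_table(cached_panel("full")),
                        expected_calls())
  expect_s3_class(tidy(ag), "tbl_df")
  g <- glance(ag)
  expect_equal(g$score, 1.0)
  expect_equal(g$n_rows, nrow(expected_calls()))
})
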