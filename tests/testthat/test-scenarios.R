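## The quantitative anchors are asserted in test-acceptance.R; these tests
## cover scenario structure, monotonicity and variant/base consistency.

test_that("scenario registry enumerates the shipped experiments", {
  expect_setequal(scenarioList(),
                  c("fig2_dose", "fig3_duration", "fig4_block_k17",
                    "fig5_sequential", "fig6_hsp70", "fig7_phlpp",
                    "s7_second_synthesis", "s8_dual_degradation"))
  expect_error(runScenario("no_such"), "arg")
})

test_that("duration sweep: down-regulation grows with pulse length", {
  ds <- runDurationSweep()
  expect_equal(ds$metrics$duration_min, c(15, 100, 150, 200, 316.66))
  expect_true(all(diff(ds$metrics$final_total) < 0))
  # minimal at 15 min, moderate (not complete) at 316.66 min
  expect_lt(ds$metrics$loss_fraction[1], 0.05)
  expect_lt(ds$metrics$loss_fraction[5], 0.5)
  expect_gt(ds$metrics$loss_fraction[5], 0.1)
})

test_that("second synthesis pulse reverses down-regulation, most at low dose", {
  s7 <- runSecondSynthesisPulse()
  expect_equal(s7$metrics$amplitude_nM, c(0.0005, 0.005, 0.05, 0.5))
  expect_true(all(s7$metrics$reversal > 0))
  # a second cohort of enzyme always raises the final pool
  expect_true(all(s7$metrics$final_with > s7$metrics$final_without))
  # the recovery index (fraction of the activator-induced loss regained)
  # decreases with stimulation intensity
  expect_true(all(diff(s7$metrics$recovery_index) < 0))
})

test_that("dual-degradation variant reduces to the base model at lambda5 = 0", {
  p <- defaultParams()
  pr <- pkcProtocol(synthesis_pulses = list(pulse(0, 10)),
                    activator_pulses = list(pulse(50, 15, 0.05)),
                    t_end = 120)
  base <- simulatePkc(pr, params = p)
  p0 <- p; p0$lambda5 <- 0
  variant <- simulatePkc(pr, params = p0,
                         network = buildDefaultNetwork(dual_degradation = TRUE))
  expect_equal(variant$states, base$states, tolerance = 1e-10)
})

test_that("the extra membrane sink can only remove mass", {
  base <- runDoseResponse()
  var <- runDualDegradationVariant(lambda5 = 5e-4)
  expect_equal(var$id, "s8_dual_degradation")
  expect_true(all(var$metrics$final_total <=
                  base$metrics$final_total + 1e-6))
  # qualitative dose-response ordering is preserved
  expect_true(all(diff(var$metrics$final_total) < 0))
})

test_that("shipped scenario trajectories stay non-negative", {
  for (res in list(runDoseResponse(amplitudes = c(0.0005, 0.5)),
                   runPhlppBlockSweep(fractions = c(0, 1)))) {
    for (tr in Filter(function(x) inherits(x, "pkc_trajectory"),
                      res$trajectories))
      expect_gt(min(tr$states), -1e-9)
  }
})

test_that("calibration is deterministic and honors the fixed anchors", {
  a <- calibrationAnchors()
  # loosen the bisection tolerances to keep the check cheap
  a$plateau$tol <- 0.5; a$first_drop$tol <- 0.1
  c1 <- calibrateDefaults(anchors = a, seed = 1L)
  c2 <- calibrateDefaults(anchors = a, seed = 1L)
  expect_identical(c1$params, c2$params)
  expect_true(all(abs(c1$residuals$residual) <=
                  c(a$plateau$tol, a$first_drop$tol)))
  # literature degradation rates are held, not searched
  expect_equal(c1$params$lambda1, 1e-3)
  expect_equal(c1$params$lambda3, 1e-3)
  expect_equal(c1$params$lambda4, 8e-5 / 60, tolerance = 1e-10)
  p <- defaultParams(); p$lambda1 <- 2e-3
  expect_error(calibrateDefaults(start = p), "lambda1")
})
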