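test_that("synthesis pulses gate k3 with half-open windows", {
  p <- defaultParams()
  pr <- pkcProtocol(synthesis_pulses = list(pulse(0, 10)), t_end = 100)
  expect_equal(k3At(5, pr, p), p$k3)
  expect_equal(k3At(10, pr, p), 0)  # half-open: off exactly at t_on+duration
  expect_equal(k3At(12, pr, p), 0)
  empty <- pkcProtocol(t_end = 100)
  expect_equal(k3At(5, empty, p), 0)
})

test_that("activator resolution covers pulses and rejects overlap", {
  pr <- pkcProtocol(activator_pulses = list(pulse(50, 15, 0.5)), t_end = 100)
  expect_equal(activatorAt(55, pr), 0.5)
  expect_equal(activatorAt(50, pr), 0.5)
  expect_equal(activatorAt(65, pr), 0)   # boundary, half-open
  expect_equal(activatorAt(66, pr), 0)

  # the dephosphorylation-blocking protocol times its pulses in seconds
  fig4 <- pkcProtocol(
    activator_pulses = lapply(c(4000, 12000, 20000) / 60, pulse,
                              duration = 15, amplitude = 0.5),
    t_end = 470)
  expect_equal(activatorAt(70, fig4), 0.5)
  expect_equal(activatorAt(100, fig4), 0)

  expect_error(
    pkcProtocol(activator_pulses = list(pulse(50, 15, 0.5),
                                        pulse(60, 15, 0.5)), t_end = 100),
    "overlap")
})

test_that("effective dephosphorylation rate folds PHLPP blocking", {
  p <- defaultParams()
  full <- pkcProtocol(phlpp_block = 1, t_end = 100)
  expect_equal(k17EffAt(7, full, p), 0)
  none <- pkcProtocol(t_end = 100)
  expect_equal(k17EffAt(7, none, p), p$k17)
  half <- pkcProtocol(phlpp_block = 0.5, t_end = 100)
  expect_equal(k17EffAt(7, half, p), p$k17 / 2)
  gated <- pkcProtocol(k17_blocks = list(pulse(60, 15)), t_end = 100)
  expect_equal(k17EffAt(70, gated, p), 0)
  expect_equal(k17EffAt(80, gated, p), p$k17)
  expect_error(pkcProtocol(phlpp_block = 1.2, t_end = 100), "0, 1")
})

test_that("HSP70 level scales with the overexpression multiplier", {
  p <- defaultParams()
  expect_equal(hsp70At(pkcProtocol(t_end = 10), p), p$HSP70)
  expect_equal(hsp70At(pkcProtocol(hsp70_multiplier = 200, t_end = 10), p),
               200 * p$HSP70)
  expect_equal(hsp70At(pkcProtocol(hsp70_multiplier = 0, t_end = 10), p), 0)
})

test_that("discontinuity set is the union of pulse and window edges", {
  pr <- pkcProtocol(synthesis_pulses = list(pulse(0, 10)),
                    activator_pulses = list(pulse(50, 15, 0.5)),
                    k17_blocks = list(pulse(50, 15)),
                    t_end = 185)
  expect_equal(breakTimes(pr), c(0, 10, 50, 65, 185))
})
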