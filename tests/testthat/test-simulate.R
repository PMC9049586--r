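test_that("without a synthesis pulse the protein system stays basal", {
  tr <- simulatePkc(pkcProtocol(t_end = 120))
  tot <- conservedMoietyTotal(tr$states)
  expect_true(all(abs(tot) < 1e-9))
  # the transcript redistributes onto polyribosomes but makes no protein
  expect_true(all(tr$states[, "PKC"] == 0))
})

test_that("isolated naive decay matches the closed form with 693 s half-life", {
  p <- defaultParams()
  for (nm in setdiff(names(p), c("lambda1", "T", "PDK1", "mTORC2", "HSP70",
                                 "mRNA0")))
    p[[nm]] <- 0
  y0 <- setNames(numeric(12), pkcSpecies("dynamical")$name)
  y0["PKC"] <- 10
  tr <- simulatePkc(pkcProtocol(t_end = 40), params = p, y0 = y0,
                    output_dt = 0.1)
  expected <- 10 * exp(-p$lambda1 * tr$times * 60)
  expect_equal(tr$states[, "PKC"], expected, tolerance = 1e-6)
  # first crossing of half the initial pool: ln 2 / lambda1 = 693.1 s
  s <- speciesSeries(tr, "PKC")
  t_half <- approx(s$value, s$time, xout = 5)$y * 60
  expect_equal(t_half, log(2) / 1e-3, tolerance = 1e-4)
})

test_that("total moiety is conserved when all sources and sinks are off", {
  p <- conservativeParams()
  pr <- pkcProtocol(synthesis_pulses = list(pulse(0, 10)),
                    activator_pulses = list(pulse(30, 15, 0.05)),
                    t_end = 120)
  tr <- simulatePkc(pr, params = p, y0 = mixedState(60))
  tot <- conservedMoietyTotal(tr$states)
  expect_equal(tot, rep(60, length(tot)), tolerance = 1e-6)
})

test_that("concentrations stay continuous and non-negative across edges", {
  tr <- simulatePkc(pkcProtocol(synthesis_pulses = list(pulse(0, 10)),
                                activator_pulses = list(pulse(50, 15, 0.5)),
                                t_end = 120))
  expect_true(all(tr$states > -1e-9))
  s <- totalPkcSeries(tr)
  # only derivatives jump at protocol edges; the series itself is continuous
  # (bound: local Lipschitz estimate, about 4 ng/ml per min during the
  # high-amplitude degradation phase, times the 1-min bracket)
  for (edge in c(10, 50, 65)) {
    i <- which(s$time == edge)[1]
    expect_lt(abs(s$value[i + 1] - s$value[i - 1]), 5)
  }
  expect_true(all(diff(tr$times) > 0))
})

test_that("solution is stable under grid refinement and tighter tolerance", {
  pr <- pkcProtocol(synthesis_pulses = list(pulse(0, 10)),
                    activator_pulses = list(pulse(50, 15, 0.005)),
                    t_end = 150)
  coarse <- totalPkcSeries(simulatePkc(pr, output_dt = 0.5))
  fine <- totalPkcSeries(simulatePkc(pr, output_dt = 0.25, rtol = 1e-9))
  common <- match(coarse$time, fine$time)
  rel <- abs(coarse$value - fine$value[common]) /
    pmax(max(coarse$value), 1e-12)
  expect_lt(max(rel, na.rm = TRUE), 1e-4)
})

test_that("plateau extraction validates stabilization", {
  flat <- data.frame(time = 0:50, value = 73)
  expect_equal(plateauValue(flat, c(10, 40)), 73)
  rising <- data.frame(time = 0:50, value = (0:50) * 2)
  expect_error(plateauValue(rising, c(10, 40)), "not stabilized")
  expect_error(plateauValue(flat, c(10, 10.5)), "fewer than 3")
})

test_that("half-time of a saturating exponential is tau log 2", {
  tau <- 12
  tt <- seq(0, 120, by = 0.1)
  ser <- data.frame(time = tt, value = 80 * (1 - exp(-tt / tau)))
  expect_equal(halfTime(ser, plateau = 80), tau * log(2), tolerance = 1e-3)
  falling <- data.frame(time = tt, value = 80 * exp(-tt / tau))
  expect_error(halfTime(falling, plateau = 80), "starts at or above")
  low <- data.frame(time = tt, value = rep(1, length(tt)))
  expect_error(halfTime(low, plateau = 80), "never reaches")
})

test_that("drop after a pulse is zero for an unperturbed series", {
  flat <- data.frame(time = seq(0, 200, 0.5), value = 73)
  expect_equal(dropAfterPulse(flat, pulse(50, 15, 1)), 0)
})

test_that("trajectory exports to tidy long format", {
  tr <- simulatePkc(pkcProtocol(t_end = 5), output_dt = 1)
  df <- as.data.frame(tr)
  expect_named(df, c("time_min", "species", "concentration"))
  expect_equal(nrow(df), length(tr$times) * 12)
  expect_setequal(unique(df$species), pkcSpecies("dynamical")$name)
})
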