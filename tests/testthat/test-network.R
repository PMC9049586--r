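test_that("default network has the full reaction and species inventory", {
  net <- buildDefaultNetwork()
  expect_equal(reactionIds(net),
               c(paste0("R", 1:12), "RM"))
  expect_equal(nrow(net$species), 12L)
  expect_equal(nrow(net$clamped), 6L)
  expect_setequal(net$clamped$name,
                  c("T", "PDK1", "mTORC2", "ACT", "PHLPP", "HSP70"))
  variant <- buildDefaultNetwork(dual_degradation = TRUE)
  expect_equal(tail(reactionIds(variant), 1), "RV")
})

test_that("PKC-moiety bookkeeping: synthesis +1, degradation -1, rest 0", {
  mc <- moietyChange(buildDefaultNetwork(dual_degradation = TRUE))
  expect_equal(mc[["R2"]], 1)
  expect_equal(unname(mc[c("R3", "R6", "R11", "RM", "RV")]), rep(-1, 5))
  expect_equal(unname(mc[c("R1", "R4", "R5", "R7", "R8", "R9", "R10", "R12")]),
               rep(0, 8))
})

test_that("mass-action fluxes follow the rate law", {
  net <- buildDefaultNetwork()
  p <- defaultParams()
  cl <- baselineClamped(p)
  y <- setNames(numeric(12), pkcSpecies("dynamical")$name)

  # first-order degradation of the naive species: 50 ng/ml x 0.001/s
  y["PKC"] <- 50
  r3 <- Filter(function(s) s$rate == "lambda1", net$steps)[[1]]
  expect_equal(massActionFlux(r3, y, p, cl), 0.05)

  # empty system carries no flux anywhere
  expect_equal(fluxVector(net, numeric(12), p, cl), rep(0, length(net$steps)))

  # no activator, no activation
  y <- setNames(numeric(12), pkcSpecies("dynamical")$name)
  y["CPKC_PAPHPT"] <- 10
  r9 <- Filter(function(s) s$rate == "k15", net$steps)[[1]]
  cl0 <- cl; cl0[["ACT"]] <- 0
  expect_equal(massActionFlux(r9, y, p, cl0), 0)
  expect_gt(massActionFlux(r9, y, p, cl), 0)

  # bimolecular autophosphorylation is second order in its reactant
  y <- setNames(numeric(12), pkcSpecies("dynamical")$name)
  y["CPKC_PA"] <- 3
  r7 <- Filter(function(s) s$rate == "k9", net$steps)[[1]]
  expect_equal(massActionFlux(r7, y, p, cl), p$k9 * 9)

  bad <- r3; bad$rate <- "k99"
  expect_error(massActionFlux(bad, y, p, cl), "unknown rate constant")
})

test_that("hand-coded RHS equals the stoichiometry-matrix oracle", {
  p <- defaultParams()
  for (dual in c(FALSE, TRUE)) {
    net <- buildDefaultNetwork(dual)
    pp <- p
    pp$lambda5 <- if (dual) 3e-4 else 0
    cl <- baselineClamped(pp)
    for (y in randomStates(100)) {
      expect_equal(pkcDerivatives(y, pp, cl), stoichRHS(net, y, pp, cl),
                   tolerance = 1e-13)
    }
  }
})

test_that("moiety-weighted derivative reduces to synthesis minus sinks", {
  p <- defaultParams()
  p$lambda5 <- 2e-4
  net <- buildDefaultNetwork(dual_degradation = TRUE)
  w <- net$species$moiety
  cl <- baselineClamped(p)
  for (y in randomStates(25, seed = 7)) {
    names(y) <- net$species$name
    lhs <- sum(w * pkcDerivatives(y, p, cl))
    rhs <- p$k3 * y[["C1"]] - p$lambda1 * y[["PKC"]] -
      p$lambda2 * y[["PKC_PA"]] - p$lambda4 * y[["CPKC_PAPHPT"]] -
      p$lambda3 * y[["PKC_A"]] - p$lambda5 * y[["PKC_PAPHPT_act"]]
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("conserved moiety total weights complexes twice", {
  y <- setNames(numeric(12), pkcSpecies("dynamical")$name)
  expect_equal(conservedMoietyTotal(y), 0)
  y["C3"] <- 5
  expect_equal(conservedMoietyTotal(y), 10)
  y["mRNA"] <- 100; y["C1"] <- 40  # no protein moiety
  expect_equal(conservedMoietyTotal(y), 10)
  m <- rbind(y, 2 * y)
  expect_equal(conservedMoietyTotal(m), c(10, 20))
})

test_that("parameter validation names the offending entry", {
  p <- defaultParams()
  expect_equal(p$lambda1, 1e-3)
  expect_equal(p$lambda3, 1e-3)
  expect_equal(p$lambda4, 8e-5 / 60, tolerance = 1e-10)
  p$lambda1 <- -1
  expect_error(validateParams(p), "lambda1")
  p <- defaultParams(); p$k1 <- NULL
  expect_error(validateParams(p), "missing parameters: k1")
  p <- defaultParams(); p$k21 <- 1
  expect_error(validateParams(p), "unknown parameters: k21")
})

test_that("network serializes to YAML and back-reads consistently", {
  net <- buildDefaultNetwork()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeNetworkYaml(net, f)
  doc <- yaml::read_yaml(f)
  expect_length(doc$steps, length(net$steps))
  expect_equal(doc$steps[[1]]$rate, "k1")
  expect_equal(vapply(doc$species, `[[`, "", "name"), net$species$name)
})
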