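test_that("the expected sampled spectrum has the right limits", {
  # neutral limit: exactly proportional to 1/i, and the small-gamma
  # quadrature converges to it
  expect_equal(expectedSfsSelected(0, 10), 1 / (1:9))
  g <- expectedSfsSelected(1e-6, 10)
  expect_equal(g, 1 / (1:9), tolerance = 1e-6)

  # strong purifying selection piles essentially all mass on singletons
  gDel <- expectedSfsSelected(-2000, 20)
  expect_gt(gDel[1] / sum(gDel), 0.99)

  # beneficial alleles flatten the spectrum towards ~1/(q(1-q)): the
  # high-frequency tail is far heavier than the neutral 1/i decay
  gBen <- expectedSfsSelected(250, 20)
  expect_gt(gBen[19] / gBen[1], 10 * (1 / 19))

  # independent quadrature oracle: integrate the textbook form of the
  # sojourn density (no kernel reformulation, single adaptive pass)
  for (gam in c(3, -12, 40)) {
    a <- expectedSfsSelected(gam, 12)
    direct <- vapply(1:11, function(i) {
      stats::integrate(function(q)
        (1 - exp(-gam * (1 - q))) / (q * (1 - q) * (1 - exp(-gam))) *
          stats::dbinom(i, 12, q),
        0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
    }, numeric(1))
    expect_equal(a, direct, tolerance = 1e-6)
  }
})

test_that("generated datasets are reproducible and linear in theta", {
  cfg <- syntheticConfig(nGenes = 50, seed = 99)
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(cfg)
  flat <- function(g) c(sfsCounts(sfsN(g)), sfsCounts(sfsS(g)),
                        dN(g), dS(g))
  expect_identical(lapply(s1$records, flat), lapply(s2$records, flat))
  expect_identical(s1$truth@realizedAlpha, s2$truth@realizedAlpha)

  # expected polymorphism scales linearly with theta and gene length
  lam1 <- impMKT:::syntheticIntensities(syntheticConfig(nGenes = 1))
  lam10 <- impMKT:::syntheticIntensities(
    syntheticConfig("theta0.01", nGenes = 1))
  expect_equal(lam10$lamPs, 10 * lam1$lamPs, tolerance = 1e-10)
  expect_equal(lam10$lamPn, 10 * lam1$lamPn, tolerance = 1e-10)
  lamLong <- impMKT:::syntheticIntensities(
    syntheticConfig(nGenes = 1, mnPerGene = 2250, msPerGene = 750))
  expect_equal(lamLong$lamPs, 2 * lam1$lamPs, tolerance = 1e-10)
  expect_equal(lamLong$lamPn, 2 * lam1$lamPn, tolerance = 1e-10)
})

test_that("the realized adaptive fraction tracks its target", {
  sim <- simulateDataset(syntheticConfig(nGenes = 2000, seed = 12))
  tr <- sim$truth
  total <- sum(tr@perGene$dn_adaptive) + sum(tr@perGene$dn_nonadaptive)
  expect_equal(realizedAlpha(tr),
               sum(tr@perGene$dn_adaptive) / total)
  # binomial interval around the 0.4 target
  se <- sqrt(0.4 * 0.6 / total)
  expect_lt(abs(realizedAlpha(tr) - 0.4), 4 * se)
  # the truth exposes the expected deleterious load below any cutoff
  expect_gt(expectedPwdBelowCutoff(tr, 0.15), 0)
  expect_lte(expectedPwdBelowCutoff(tr, 0.15),
             expectedPwdBelowCutoff(tr, 0.35))
})

test_that("estimator bias shrinks and ranks correctly on baseline data", {
  sim <- simulateDataset(syntheticConfig(nGenes = 1000, seed = 8))
  pool <- poolRecords(sim$records)
  aMkt <- alphaEstimate(standardMKT(pool))
  aImp15 <- alphaEstimate(impMKT(pool, 0.15))
  aImp35 <- alphaEstimate(impMKT(pool, 0.35))
  expect_lt(aMkt, aImp15)
  expect_lte(aImp15, aImp35 + 0.02)
  expect_lt(abs(aImp35 - realizedAlpha(sim$truth)), abs(aMkt -
    realizedAlpha(sim$truth)))

  # a more leptokurtic DFE (smaller beta) means fewer weakly deleterious
  # variants, hence less underestimation for the plain test
  simLep <- simulateDataset(syntheticConfig("beta0.1", nGenes = 1000,
                                            seed = 8))
  aMktLep <- alphaEstimate(standardMKT(poolRecords(simLep$records)))
  expect_gt(aMktLep, aMkt)
})

test_that("presets mirror the scenario grid and reject unknown names", {
  cfg <- syntheticConfig("beta0.1", nGenes = 10)
  expect_equal(cfg@beta, 0.1)
  expect_equal(cfg@pA, 0.00115)
  base <- syntheticConfig(nGenes = 10)
  expect_equal(base@theta, 0.001)
  expect_equal(base@gammaDel, -2000)
  expect_equal(base@gammaBen, 250)
  expect_equal(base@pA, 0.00021)
  expect_equal(base@alphaTarget, 0.4)
  expect_equal(base@sampleSize, 20L)
  expect_equal(base@mnPerGene, 1125)
  expect_equal(base@msPerGene, 375)
  expect_error(syntheticConfig("nope"), "unknown preset")
  expect_error(syntheticConfig(nGenes = 10, gammaDel = 5), "positive")
})
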