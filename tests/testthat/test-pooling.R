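test_that("pooling sums counts and leaves alpha of identical genes fixed", {
  g <- table2Gene()
  pool <- poolRecords(rep(list(g), 5))
  expect_equal(pN(pool), 5 * pN(g))
  expect_equal(dS(pool), 5 * dS(g))
  expect_equal(mN(pool), 5 * mN(g))

  # the pooling identity holds for every method
  for (fn in list(standardMKT,
                  function(x) fwwMKT(x, 0.15),
                  function(x) eMKT(x, 0.15),
                  function(x) impMKT(x, 0.15),
                  function(x) impMKTHigh(x, 0.15, 0.85))) {
    expect_equal(alphaEstimate(fn(pool)), alphaEstimate(fn(g)),
                 tolerance = 1e-12)
  }

  # an all-zero gene contributes nothing
  zero <- GeneVariation("zero", SFS(rep(0, 19), 20), SFS(rep(0, 19), 20),
                        0, 0, 10, 10)
  both <- poolRecords(list(g, zero))
  expect_equal(alphaEstimate(standardMKT(both)),
               alphaEstimate(standardMKT(g)), tolerance = 1e-12)

  expect_error(poolRecords(list(g, randomRecord(10))), "mixed")
})

test_that("pooling can reverse per-gene conclusions (Simpson's paradox)", {
  mk <- function(id, pn, ps, dn, ds) {
    scale <- function(total) {
      v <- rep(0, 19)
      v[1:4] <- c(total %/% 4 + total %% 4, rep(total %/% 4, 3))
      v
    }
    GeneVariation(id, SFS(scale(pn), 20), SFS(scale(ps), 20), dn, ds,
                  100, 100)
  }
  g1 <- mk("g1", 100, 110, 10, 1)
  g2 <- mk("g2", 1, 2, 60, 100)
  a1 <- alphaEstimate(standardMKT(g1))
  a2 <- alphaEstimate(standardMKT(g2))
  aPool <- alphaEstimate(standardMKT(poolRecords(list(g1, g2))))
  expect_gt(a1, 0)
  expect_gt(a2, 0)
  expect_lt(aPool, 0)
})

test_that("bootstrap pools are reproducible and collapse for one gene", {
  set.seed(31)
  recs <- replicate(40, randomRecord(20, lambda = 3), simplify = FALSE)
  r1 <- bootstrapPools(recs, poolSizes = c(1, 5, 25), replicates = 50,
                       seed = 77, method = "imp", cutoff = 0.15)
  r2 <- bootstrapPools(recs, poolSizes = c(1, 5, 25), replicates = 50,
                       seed = 77, method = "imp", cutoff = 0.15)
  expect_identical(r1, r2)
  r3 <- bootstrapPools(recs, poolSizes = c(1, 5, 25), replicates = 50,
                       seed = 78, method = "imp", cutoff = 0.15)
  expect_false(identical(r1$alpha_mean, r3$alpha_mean))

  # percentile band brackets the mean where all replicates analyzable
  full <- r1$fraction_analyzable == 1
  expect_true(all(r1$alpha_p2_5[full] <= r1$alpha_mean[full] + 1e-12))
  expect_true(all(r1$alpha_p97_5[full] >= r1$alpha_mean[full] - 1e-12))

  # resampling a single-gene list collapses to the point estimate
  one <- bootstrapPools(list(table2Gene()), poolSizes = c(1, 3),
                        replicates = 20, seed = 5, method = "mkt")
  aStd <- alphaEstimate(standardMKT(table2Gene()))
  expect_equal(one$alpha_mean, rep(aStd, 2), tolerance = 1e-12)
  expect_equal(one$alpha_p2_5, one$alpha_p97_5, tolerance = 1e-12)

  # mean polymorphism grows linearly with pool size
  expect_equal(r1$mean_pn[r1$pool_size == 25] /
                 r1$mean_pn[r1$pool_size == 1], 25, tolerance = 0.35)
})

test_that("analyzable fraction rises with pool size on sparse data", {
  # sparse neutral-ish genes: singletons only, often missing P_S or D
  set.seed(41)
  sparse <- replicate(60, {
    GeneVariation(paste0("s", sample.int(1e6, 1)),
                  SFS(c(stats::rpois(1, 0.8), rep(0, 18)), 20),
                  SFS(c(stats::rpois(1, 0.8), stats::rpois(1, 0.4),
                        stats::rpois(1, 0.4), rep(0, 16)), 20),
                  dN = stats::rpois(1, 0.7), dS = stats::rpois(1, 0.7),
                  mN = 300, mS = 100)
  }, simplify = FALSE)
  out <- bootstrapPools(sparse, poolSizes = c(1, 10, 50),
                        replicates = 100, seed = 2, method = "imp",
                        cutoff = 0.15)
  expect_true(all(diff(out$fraction_analyzable) >= 0))
  expect_lt(out$fraction_analyzable[1], 1)
})
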