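test_that("the Fisher surface matches the enumeration oracle and flags
          degenerate margins", {
  expect_equal(mktFisher(c(11, 17, 15, 8))$p, fisherOracle(11, 17, 15, 8))
  expect_equal(mktFisher(c(10, 10, 10, 10))$p, 1)
  deg <- mktFisher(c(0, 0, 3, 5))
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
  expect_error(mktFisher(c(1.4, 2, 3, 4)), "integer")

  set.seed(5)
  for (rep in 1:50) {
    cells <- stats::rpois(4, sample(1:6, 1))
    expect_equal(mktFisher(cells)$p,
                 fisherOracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("the standard test reproduces the worked example", {
  res <- standardMKT(table2Gene())
  expect_equal(unname(contingencyTable(res)[, 1]), c(11, 17))
  expect_equal(round(pValue(res), 3), 0.093)
  expect_equal(alphaEstimate(res), 1 - (11 / 17) * (8 / 15),
               tolerance = 1e-12)
  expect_equal(excludedFraction(res), 0)

  # balanced ratios: alpha 0 and a flat P-value
  gEq <- GeneVariation("eq", SFS(c(4, 4, 2), 4), SFS(c(4, 4, 2), 4),
                       10, 10, 50, 50)
  resEq <- standardMKT(gEq)
  expect_equal(alphaEstimate(resEq), 0)
  expect_equal(pValue(resEq), 1)
})

test_that("genes with empty margins are screened out", {
  g0 <- GeneVariation("z", SFS(c(1, 1, 1)), SFS(c(0, 0, 0)), 5, 5, 9, 3)
  expect_false(isAnalyzable(standardMKT(g0)))
  expect_equal(classifyGene(standardMKT(g0)), "non-analyzable")
  gD <- GeneVariation("z", SFS(c(1, 1, 1)), SFS(c(1, 1, 1)), 0, 5, 9, 3)
  expect_false(isAnalyzable(standardMKT(gD)))
  expect_false(isAnalyzable(impMKT(gD, 0.15)))
  # synonymous polymorphism only below the cutoff: cutoff methods refuse
  gHi <- GeneVariation("z", SFS(c(1, 1, rep(0, 17)), 20),
                       SFS(c(2, 1, rep(0, 17)), 20), 5, 5, 9, 3)
  expect_false(isAnalyzable(fwwMKT(gHi, 0.5)))
  expect_false(isAnalyzable(impMKT(gHi, 0.5)))
  expect_true(isAnalyzable(standardMKT(gHi)))
})

test_that("the cutoff test removes both classes and books the data loss", {
  res <- fwwMKT(table2Gene(), 0.15)
  expect_equal(unname(contingencyTable(res)),
               matrix(c(4, 11, 15, 8), 2, 2))
  expect_equal(round(pValue(res), 3), 0.045)
  expect_equal(excludedFraction(res), 13 / 28)

  # a cutoff below one copy removes nothing
  resLow <- fwwMKT(table2Gene(), 0.01)
  resStd <- standardMKT(table2Gene())
  expect_equal(contingencyTable(resLow), contingencyTable(resStd))
  expect_equal(alphaEstimate(resLow), alphaEstimate(resStd))
})

test_that("the neutral-fraction decomposition follows its formulas", {
  res <- eMKT(table2Gene(), 0.15)
  # f = 6/17; 11 * 6/17 + 4 = 7.882 -> cell 8
  expect_equal(res@fNeutral, 6 / 17)
  expect_equal(res@pneut, 11 * 6 / 17 + 4, tolerance = 1e-12)
  expect_equal(contingencyTable(res)[1, 1], 8)

  # no synonymous sites below the cutoff: below-cutoff P_N all deleterious
  sN <- SFS(c(3, 2, 1, 1, rep(0, 15)), 20)
  sS <- SFS(c(0, 0, 2, 2, 1, rep(0, 14)), 20)
  g <- GeneVariation("g", sN, sS, 6, 4, 50, 50)
  r0 <- eMKT(g, 0.15)
  expect_equal(r0@pneut, bandCounts(g, 0.15)@pnHigh)

  # alternative below-only reading is exposed and differs when flagged
  rAlt <- eMKT(table2Gene(), 0.15, pnBelowOnly = TRUE)
  expect_equal(rAlt@pneut, 7 * 6 / 17 + 4, tolerance = 1e-12)

  # identical N and S shapes: the decomposition changes nothing
  s <- SFS(c(6, 4, 2, 1, rep(0, 15)), 20)
  gSame <- GeneVariation("s", s, s, 10, 10, 50, 50)
  expect_equal(alphaEstimate(eMKT(gSame, 0.15)),
               alphaEstimate(standardMKT(gSame)), tolerance = 1e-12)
})

test_that("the imputation reproduces the worked value and clamps", {
  b <- new("BandCounts", pnLow = 7, pnHigh = 4, psLow = 6, psHigh = 11,
           cutoff = 0.15)
  imp <- imputePwd(b)
  expect_equal(imp$pwd, 7 - 4 * 6 / 11, tolerance = 1e-12)
  expect_equal(round(imp$pwd), 5)
  expect_false(imp$clamped)

  # proportional bands impute zero
  b0 <- new("BandCounts", pnLow = 6, pnHigh = 3, psLow = 4, psHigh = 2,
            cutoff = 0.15)
  expect_equal(imputePwd(b0)$pwd, 0)

  # more constraint below than above: clamped to zero, flagged
  bNeg <- new("BandCounts", pnLow = 1, pnHigh = 9, psLow = 5, psHigh = 5,
              cutoff = 0.15)
  impNeg <- imputePwd(bNeg)
  expect_equal(impNeg$pwd, 0)
  expect_true(impNeg$clamped)
  expect_lt(impNeg$unclamped, 0)

  bNA <- new("BandCounts", pnLow = 3, pnHigh = 1, psLow = 2, psHigh = 0,
             cutoff = 0.15)
  expect_error(imputePwd(bNA), "undefined")
})

test_that("the imputed test removes only P_wd and keeps P_S intact", {
  g <- table2Gene()
  res <- impMKT(g, 0.15)
  expect_equal(unname(contingencyTable(res)),
               matrix(c(6, 17, 15, 8), 2, 2))
  expect_equal(round(pValue(res), 3), 0.017)
  expect_equal(alphaEstimate(res),
               1 - ((11 - (7 - 4 * 6 / 11)) / 17) * (8 / 15),
               tolerance = 1e-12)
  expect_equal(excludedFraction(res), 5 / 28)

  # impMKT always loses no more polymorphism than the cutoff test
  set.seed(13)
  for (rep in 1:20) {
    r <- randomRecord(20)
    cut <- sample(c(0.05, 0.15, 0.25, 0.35), 1)
    ri <- impMKT(r, cut); rf <- fwwMKT(r, cut)
    if (isAnalyzable(ri) && isAnalyzable(rf))
      expect_lte(excludedFraction(ri), excludedFraction(rf) + 1e-12)
  }

  # a zero imputation reproduces the standard test bit for bit
  sN <- SFS(c(1, 1, 2, 2, rep(0, 15)), 20)
  sS <- SFS(c(2, 2, 2, 2, rep(0, 15)), 20)
  gz <- GeneVariation("gz", sN, sS, 7, 5, 50, 50)
  expect_equal(imputePwd(gz, 0.15)$pwd, 0)
  expect_identical(contingencyTable(impMKT(gz, 0.15)),
                   contingencyTable(standardMKT(gz)))
  expect_equal(alphaEstimate(impMKT(gz, 0.15)),
               alphaEstimate(standardMKT(gz)), tolerance = 1e-12)

  # empty below-cutoff band: every method agrees on alpha
  sN2 <- SFS(c(0, 0, 0, 2, 3, 1, rep(0, 13)), 20)
  sS2 <- SFS(c(0, 0, 0, 3, 2, 2, rep(0, 13)), 20)
  g2 <- GeneVariation("g2", sN2, sS2, 9, 6, 50, 50)
  a <- alphaEstimate(standardMKT(g2))
  expect_equal(alphaEstimate(fwwMKT(g2, 0.15)), a, tolerance = 1e-12)
  expect_equal(alphaEstimate(eMKT(g2, 0.15)), a, tolerance = 1e-12)
  expect_equal(alphaEstimate(impMKT(g2, 0.15)), a, tolerance = 1e-12)
})

test_that("the high-frequency variant moves the excess into divergence", {
  g <- table2Gene()
  # nothing above 0.85 in the worked example: reduces to the mid-band
  # imputation with divergence untouched
  rh <- impMKTHigh(g, 0.15, 0.85)
  bMid <- bandCounts(g, 0.15)
  expect_equal(contingencyTable(rh)[1, 2], 15)  # D_N unchanged
  expect_equal(rh@pwd, imputePwd(bMid)$pwd, tolerance = 1e-12)

  # constructed high-frequency excess: mid band has equal N/S ratio r = 1,
  # high band carries E extra nonsynonymous copies
  E <- 4
  sN <- SFS(c(2, 1, 0, 3, 2, 2, rep(0, 11), 1, 1 + E), 20)
  sS <- SFS(c(1, 1, 0, 3, 2, 2, rep(0, 11), 1, 1), 20)
  gh <- GeneVariation("gh", sN, sS, 10, 10, 50, 50)
  rhE <- impMKTHigh(gh, 0.15, 0.9)
  expect_equal(contingencyTable(rhE)[1, 2], 10 + E)
  # and the removed high excess leaves the polymorphism cell accordingly
  expect_equal(rhE@pneut, pN(gh) - rhE@pwd - E, tolerance = 1e-12)

  # no signal anywhere: reduces to the standard test
  s <- SFS(c(2, 2, 2, 2, rep(0, 15)), 20)
  gn <- GeneVariation("gn", s, s, 5, 5, 50, 50)
  expect_equal(alphaEstimate(impMKTHigh(gn, 0.15, 0.85)),
               alphaEstimate(standardMKT(gn)), tolerance = 1e-12)

  expect_error(impMKTHigh(g, 0.5, 0.2), "smaller")
  gEmpty <- GeneVariation("e", SFS(c(5, rep(0, 18)), 20),
                          SFS(c(5, rep(0, 18)), 20), 3, 3, 10, 10)
  expect_false(isAnalyzable(impMKTHigh(gEmpty, 0.15, 0.85)))
})

test_that("purifying-selection fractions follow the decomposition", {
  st <- dStats(table2Gene(mN = 500, mS = 200), 0.15)
  expect_equal(st$d, 1 - (11 / 17) * (200 / 500), tolerance = 1e-12)
  expect_equal(st$dw, ((7 - 4 * 6 / 11) / 17) * (200 / 500),
               tolerance = 1e-12)
  expect_equal(st$d + st$dw + st$d0, 1, tolerance = 1e-12)

  # matched densities with zero imputation: d = 0, d0 = 1
  sN <- SFS(c(2, 2, 4, 4, rep(0, 15)), 20)
  sS <- SFS(c(1, 1, 2, 2, rep(0, 15)), 20)
  gFlat <- GeneVariation("f", sN, sS, 1, 1, 100, 50)
  stFlat <- dStats(gFlat, 0.15)
  expect_equal(stFlat$d, 0, tolerance = 1e-12)
  expect_equal(stFlat$dw, 0, tolerance = 1e-12)
  expect_equal(stFlat$d0, 1, tolerance = 1e-12)

  set.seed(17)
  for (rep in 1:10) {
    r <- randomRecord(20)
    if (pS(r) > 0 && bandCounts(r, 0.15)@psHigh > 0) {
      s <- dStats(r, 0.15)
      expect_equal(s$d + s$dw + s$d0, 1, tolerance = 1e-12)
      expect_gte(s$dw, 0)
    }
  }
})

test_that("gene classification uses significance and the sign of alpha", {
  g <- table2Gene()
  expect_equal(classifyGene(impMKT(g, 0.15), 0.05), "positive")
  expect_equal(classifyGene(standardMKT(g), 0.05), "non-significant")
  # negative selection: polymorphism excess
  gNeg <- GeneVariation("n", SFS(c(20, 10, 5), 4), SFS(c(3, 2, 1), 4),
                        2, 6, 50, 50)
  expect_equal(classifyGene(standardMKT(gNeg), 0.05), "negative")
})

test_that("the batch runner emits one labelled row per gene and method", {
  recs <- list(table2Gene(), randomRecord(20))
  out <- runMKT(recs, methods = c("mkt", "fww", "imp"), cutoff = 0.15,
                bh = TRUE)
  expect_equal(nrow(out), 6)
  expect_setequal(unique(out$method), c("mkt", "fww", "imp"))
  w <- out[out$gene_id == "worked_example" & out$method == "imp", ]
  expect_equal(w$pn_cell, 6)
  expect_equal(w$pwd, 7 - 4 * 6 / 11, tolerance = 1e-12)
  expect_true(all(out$p_bh >= out$p_value, na.rm = TRUE))
  expect_error(runMKT(recs, methods = "nonsense"))
})
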