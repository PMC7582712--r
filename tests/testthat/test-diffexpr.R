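cellLevels <- c("WT.control", "WT.drought", "Fld.control", "Fld.drought")
cellFactor <- function(nReps = 2)
  factor(rep(cellLevels, each = nReps), levels = cellLevels)

test_that("cell means and pooled residual variance follow hand arithmetic", {
  ## replicates {a, a} everywhere: zero residual variance
  m0 <- matrix(rep(c(5, 5, 7, 7, 1, 1, 3, 3), 2), 2, byrow = TRUE)
  fit0 <- fitCellMeans(m0, cellFactor())
  expect_equal(unname(fit0$s2), c(0, 0))
  ## cell values {1, 3}: mean 2, residual SS contribution 2
  m1 <- matrix(c(1, 3, 2, 2, 5, 5, 0, 0), 1)
  fit1 <- fitCellMeans(m1, cellFactor())
  expect_equal(unname(fit1$means[1, ]), c(2, 2, 5, 0))
  expect_equal(fit1$df, 4L)
  expect_equal(unname(fit1$s2), 2 / 4)
  expect_error(fitCellMeans(m1[, 1:4, drop = FALSE],
                            factor(cellLevels, levels = cellLevels)),
               "degrees of freedom")
})

test_that("residual variances are unbiased for the generating variance", {
  set.seed(42)
  sigma2 <- 0.3
  m <- matrix(rnorm(10000 * 8, sd = sqrt(sigma2)), 10000, 8)
  fit <- fitCellMeans(m, cellFactor())
  ## mean of s2 within 3 SE of sigma^2 (s2 ~ sigma^2 chi^2_4 / 4)
  se <- sigma2 * sqrt(2 / 4) / sqrt(10000)
  expect_lt(abs(mean(fit$s2) - sigma2), 3 * se)
})

test_that("prior estimation handles the degenerate and formula cases", {
  expect_equal(estimatePrior(rep(0.07, 200), df = 4),
               list(d0 = Inf, s0sq = 0.07))
  expect_equal(squeezeVariance(3, df = 4, d0 = 4, s0sq = 1), 2)
  expect_equal(squeezeVariance(c(1, 9), df = 4, d0 = Inf, s0sq = 5),
               c(5, 5))
  expect_error(estimatePrior(c(0.1, -0.1), df = 4), "positive")
  ## moderated variance lies between the prior and the observed variance
  set.seed(3)
  s2 <- rexp(500) + 0.01
  sv <- squeezeVariance(s2, 4, 4, 0.05)
  expect_true(all(sv >= pmin(s2, 0.05) & sv <= pmax(s2, 0.05)))
})

test_that("moderated t behaves at the null and flags degenerate variance", {
  mt <- moderatedT(beta = 0, s2Post = 0.1, varFactor = 1, df = 4, d0 = 4)
  expect_equal(mt$t, 0)
  expect_equal(mt$p, 1)
  bad <- moderatedT(beta = c(1, 1), s2Post = c(0, 0.1), varFactor = 1,
                    df = 4, d0 = 4)
  expect_identical(bad$error, c(TRUE, FALSE))
  expect_true(is.na(bad$t[1]))
})

test_that("BH q-values match the hand example and the step-up definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.3), 0.3)
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  ## brute-force step-up oracle on random vectors
  stepUp <- function(p) {
    m <- length(p)
    ps <- sort(p)
    vapply(p, function(pi) {
      j <- which(ps >= pi - 1e-15)
      min(1, min(ps[j] * m / j))
    }, numeric(1))
  }
  set.seed(7)
  for (i in 1:50) {
    p <- round(runif(sample(1:12, 1)), 3)
    expect_equal(bhFdr(p), stepUp(p))
  }
  ## monotone non-decreasing in p
  p <- sort(runif(30))
  expect_true(all(diff(bhFdr(p)) >= -1e-12))
  expect_true(all(bhFdr(p) >= p))
})

test_that("state calls use strict thresholds", {
  expect_identical(callState(log2(2.5), 0.01), "U")
  expect_identical(callState(log2(2), 0.001), "N")   # strict ">"
  expect_identical(callState(log2(0.4), 0.2), "N")   # fails FDR
  expect_identical(callState(log2(0.4), 0.01), "D")
  expect_identical(callState(log2(0.5), 0.001), "N") # strict "<"
})

test_that("the moderated fit agrees with the limma reference pipeline", {
  cfg <- simulationConfig(nProbes = 3000, fracUnexpressed = 0,
                          classTable = defaultClassTable(fracUnexpressed = 0),
                          seed = 19)
  fae <- simulateExpression(cfg, scale = "log2")
  fit <- moderatedFit(fae)
  m <- SummarizedExperiment::assay(fae, "intensity")
  cell <- designCells(fae)
  design <- stats::model.matrix(~ 0 + cell)
  colnames(design) <- levels(cell)
  cm <- limma::makeContrasts(
    FldVsWT.control = Fld.control - WT.control,
    FldVsWT.drought = Fld.drought - WT.drought,
    DroughtVsControl.Fld = Fld.drought - Fld.control,
    DroughtVsControl.WT = WT.drought - WT.control,
    levels = design)
  ref <- limma::eBayes(limma::contrasts.fit(limma::lmFit(m, design), cm))
  expect_equal(fit@d0, ref$df.prior, tolerance = 1e-6)
  expect_equal(fit@s0sq, ref$s2.prior, tolerance = 1e-6)
  expect_equal(unname(logFoldChanges(fit)), unname(ref$coefficients),
               tolerance = 1e-10)
  expect_equal(unname(fit@t), unname(ref$t), tolerance = 1e-8)
  expect_equal(unname(pValues(fit)), unname(ref$p.value), tolerance = 1e-8)
})

test_that("clean-simulation recovery meets the power the design targets", {
  ## planted effects of 3 log2 units, two replicates per cell
  cfg <- simulationConfig(nProbes = 10000, fracUnexpressed = 0,
                          classTable = defaultClassTable(fracUnexpressed = 0),
                          seed = 23)
  fae <- simulateExpression(cfg, scale = "log2")
  fit <- moderatedFit(fae)
  tr <- groundTruth(fae)
  st <- contrastStates(fit)
  trueStates <- do.call(rbind, strsplit(tr$pattern, ""))
  nonNull <- trueStates != "N"
  expect_gte(mean(st[nonNull] == trueStates[nonNull]), 0.90)
  nullProbe <- tr$class == "null"
  called <- rowSums(st != "N") > 0
  expect_lte(mean(called[nullProbe]), 0.01)
})
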