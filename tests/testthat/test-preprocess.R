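test_that("quantile normalization matches the hand-computed example", {
  out <- quantileNormalize(cbind(c(1, 3), c(2, 4)))
  expect_equal(out, cbind(c(1.5, 3.5), c(1.5, 3.5)))
})

test_that("quantile normalization equalizes distributions and is idempotent", {
  set.seed(5)
  m <- matrix(rlnorm(400 * 6, 5, 1), 400, 6)
  q1 <- quantileNormalize(m)
  ## identical sorted vectors in every column, equal means
  ref <- sort(q1[, 1])
  for (j in 2:6) expect_equal(sort(q1[, j]), ref)
  expect_equal(colMeans(q1), rep(mean(colMeans(m)), 6),
               ignore_attr = TRUE)
  ## within-column rank order preserved
  for (j in 1:6) expect_identical(order(q1[, j]), order(m[, j]))
  ## idempotence, and no-op on already-identical columns
  expect_equal(quantileNormalize(q1), q1)
  same <- cbind(m[, 1], m[, 1])
  expect_equal(quantileNormalize(same), same, ignore_attr = TRUE)
  expect_error(quantileNormalize(m[, 1, drop = FALSE]), "2 columns")
  m[1, 1] <- NA
  expect_error(quantileNormalize(m), "missing")
})

test_that("normexp corrected values are positive, monotone and shift-invariant", {
  params <- c(mu = 80, sigma = 12, alpha = 500)
  x <- sort(c(seq(-50, 400, by = 7), 10000))
  y <- normexpSignal(x, params)
  expect_true(all(y > 0))
  expect_true(all(diff(y) > 0))
  ## adding c to mu and to every x leaves the correction unchanged
  shifted <- normexpSignal(x + 37, c(mu = 80 + 37, sigma = 12, alpha = 500))
  expect_equal(shifted, y)
  ## strong-signal asymptote: corrected ~ x - mu - sigma^2/alpha
  big <- 1e6
  expect_equal(normexpSignal(big, params),
               big - params[["mu"]] - params[["sigma"]]^2 / params[["alpha"]],
               tolerance = 1e-9)
})

test_that("normexp parameters are recovered from model-form data", {
  set.seed(21)
  truth <- c(mu = 120, sigma = 18, alpha = 900)
  x <- simulateNormexpColumn(40000, truth["mu"], truth["sigma"],
                             truth["alpha"])
  est <- normexpFit(x)
  expect_lt(abs(est["mu"] / truth["mu"] - 1), 0.15)
  expect_lt(abs(est["sigma"] / truth["sigma"] - 1), 0.15)
  expect_lt(abs(est["alpha"] / truth["alpha"] - 1), 0.15)
  expect_error(normexpFit(rep(5, 100)), "degenerate")
})

test_that("normexp fit and correction agree with the limma reference", {
  set.seed(8)
  x <- simulateNormexpColumn(20000, 100, 15, 600)
  est <- normexpFit(x)
  ref <- limma::normexp.fit(x, method = "mle")$par  # (mu, log sigma, log alpha)
  expect_equal(unname(est["mu"]), ref[1], tolerance = 0.02)
  expect_equal(unname(est["sigma"]), exp(ref[2]), tolerance = 0.05)
  expect_equal(unname(est["alpha"]), exp(ref[3]), tolerance = 0.05)
  mine <- normexpSignal(x, est)
  theirs <- limma::normexp.signal(ref, x)
  expect_equal(mine, theirs, tolerance = 0.02)
})

test_that("quantile normalization agrees with the limma reference", {
  set.seed(13)
  m <- matrix(rlnorm(300 * 5), 300, 5)
  expect_equal(quantileNormalize(m), limma::normalizeQuantiles(m),
               ignore_attr = TRUE)
})

test_that("log2 transform is exact and guarded", {
  expect_equal(log2Transform(matrix(c(8, 1), 1)), matrix(c(3, 0), 1))
  x <- matrix(rexp(20) + 0.1, 4)
  expect_equal(2^log2Transform(x), x)
  expect_error(log2Transform(matrix(c(1, 0), 1)), "positive")
})

test_that("expression filter applies the strict 10%-above-background rule", {
  bg <- 100
  ## probe A exactly 1.10 x background everywhere: excluded (strict)
  ## probe B 2 x background in one cell, at background elsewhere: kept
  ## probe C below threshold everywhere: excluded
  cells <- rbind(A = rep(1.10 * bg, 4),
                 B = c(2 * bg, bg, bg, bg),
                 C = rep(1.05 * bg, 4))
  fae <- cellValueFae(cells)
  res <- filterExpressed(fae, backgroundMu = rep(bg, 8))
  expect_identical(unname(res$mask), c(FALSE, TRUE, FALSE))
  expect_identical(rownames(res$experiment), "B")
  ## a probe above 1.1 x the largest background in every cell survives
  cells2 <- rbind(D = rep(1.2 * 110, 4))
  res2 <- filterExpressed(cellValueFae(cells2),
                          backgroundMu = rep(c(90, 110), 4))
  expect_true(all(res2$mask))
})

test_that("the default synthetic configuration passes about 75% of probes", {
  cfg <- tinyConfig(nProbes = 4000, seed = 3)
  pre <- preprocessArrays(simulateExpression(cfg))
  expect_lt(abs(mean(pre$mask) - 0.75), 0.03)
  expect_identical(intensityScale(pre$experiment), "log2")
  ## background-corrected values feeding the pipeline stayed positive
  expect_true(all(is.finite(SummarizedExperiment::assay(pre$experiment))))
})
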