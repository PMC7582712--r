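test_that("simulation is bit-identical under a fixed seed", {
  cfg <- tinyConfig(nProbes = 400, seed = 9)
  a <- simulateExpression(cfg)
  b <- simulateExpression(cfg)
  expect_identical(SummarizedExperiment::assay(a, "intensity"),
                   SummarizedExperiment::assay(b, "intensity"))
  expect_identical(groundTruth(a), groundTruth(b))
  expect_identical(simulateAnnotation(cfg, groundTruth(a)),
                   simulateAnnotation(cfg, groundTruth(b)))
  sm <- simulateMetabolites(seed = 4)
  expect_identical(sm$table, simulateMetabolites(seed = 4)$table)
})

test_that("configuration invariants are enforced", {
  ct <- defaultClassTable()
  ct$proportion[1] <- ct$proportion[1] + 0.1
  expect_error(simulationConfig(classTable = ct), "sum to 1")
  expect_error(simulationConfig(nReps = 1), "nReps")
  bad <- defaultClassTable()
  bad$e1[1] <- bad$e1[1] + 1  # breaks cell-mean consistency
  expect_error(simulationConfig(classTable = bad), "e1 \\+ e3")
  expect_error(
    simulationConfig(plantedEnrichment = data.frame(
      bin = "1.1", class = "no_such_class", odds = 8)),
    "unknown class")
})

test_that("zero planted effects give an all-null truth", {
  ct <- defaultClassTable(fracUnexpressed = 0)
  ct[, c("e1", "e2", "e3", "e4")] <- 0
  cfg <- simulationConfig(nProbes = 300, fracUnexpressed = 0,
                          classTable = ct, seed = 2)
  tr <- groundTruth(simulateExpression(cfg, scale = "log2"))
  expect_true(all(tr$pattern == "NNNN"))
})

test_that("raw intensities are positive and class masses are respected", {
  cfg <- tinyConfig(nProbes = 5000, seed = 31)
  fae <- simulateExpression(cfg)
  v <- SummarizedExperiment::assay(fae, "intensity")
  expect_true(all(v > 0))
  tr <- groundTruth(fae)
  ## unexpressed fraction is apportioned exactly
  expect_equal(mean(tr$class == "unexpressed"), 0.25, tolerance = 1e-3)
  ## non-null pattern mass matches the configured class mass within
  ## binomial error (assignment itself is deterministic apportionment)
  ct <- cfg@classTable
  planted <- sum(ct$proportion[ct$class != "null"])
  expect_equal(mean(tr$pattern != "NNNN"), planted, tolerance = 0.01)
  ## unexpressed and null probes have no planted pattern
  expect_true(all(tr$pattern[tr$class %in% c("null", "unexpressed")] ==
                    "NNNN"))
})

test_that("simulated gene variances follow the scaled inverse chi-square prior", {
  cfg <- simulationConfig(nProbes = 10000, fracUnexpressed = 0,
                          classTable = defaultClassTable(fracUnexpressed = 0),
                          seed = 77)
  tr <- groundTruth(simulateExpression(cfg, scale = "log2"))
  ## E log sigma^2 = log(d0 * s0sq / 2) - digamma(d0 / 2)
  analytic <- log(cfg@d0True * cfg@s0sqTrue / 2) - digamma(cfg@d0True / 2)
  se <- sqrt(trigamma(cfg@d0True / 2) / nrow(tr))
  expect_lt(abs(mean(log(tr$sigma2)) - analytic), 3 * se)
})

test_that("annotation coverage and planted enrichment behave as configured", {
  cfg <- tinyConfig(nProbes = 6000, seed = 12)
  tr <- groundTruth(simulateExpression(cfg))
  ann <- simulateAnnotation(cfg, tr)
  expect_gte(annotationCoverage(ann, tr$probe_id), 0.80)
  ## planted 8-fold odds: membership rate in the planted bin is much
  ## higher inside the planted class than outside
  inClass <- tr$probe_id[tr$class == "ameliorated_repression"]
  hit <- ann$probe_id[ann$bin_code == "1.1"]
  rateIn <- mean(inClass %in% hit)
  rateOut <- mean(setdiff(tr$probe_id, inClass) %in% hit)
  expect_gt(rateIn, 3 * rateOut)
  ## no planted enrichment -> rates indistinguishable scale
  cfg0 <- tinyConfig(nProbes = 6000, seed = 12,
                     plantedEnrichment = data.frame(
                       bin = character(), class = character(),
                       odds = numeric()))
  ann0 <- simulateAnnotation(cfg0, tr)
  rate0 <- mean(inClass %in% ann0$probe_id[ann0$bin_code == "1.1"])
  expect_lt(abs(rate0 - cfg0@binBaseRate), 0.03)
})

test_that("log2-scale simulation refuses unexpressed probes", {
  expect_error(simulateExpression(tinyConfig(), scale = "log2"),
               "fracUnexpressed")
})
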