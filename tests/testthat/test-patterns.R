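test_that("taxonomy encodes the cluster semantics of the 2x2 design", {
  ## drought response shared by both genotypes
  expect_identical(classifyTaxonomy("NNUU"), "shared_induced")
  expect_identical(classifyTaxonomy("NNDD"), "shared_repressed")
  ## WT drought response absent in Fld
  expect_identical(classifyTaxonomy("NNNU"), "abolished_induction")
  expect_identical(classifyTaxonomy("NDNU"), "abolished_induction")
  expect_identical(classifyTaxonomy("NUND"), "abolished_repression")
  ## drought response in both but attenuated (genotypes separate under
  ## drought), versus truly shared above
  expect_identical(classifyTaxonomy("NDUU"), "ameliorated_induction")
  expect_identical(classifyTaxonomy("NUDD"), "ameliorated_repression")
  ## Fld effect opposing the drought response
  expect_identical(classifyTaxonomy("UNDN"), "opposed_fld_up_drought_down")
  expect_identical(classifyTaxonomy("UUDD"), "opposed_fld_up_drought_down")
  ## priming: Fld moves the gene where drought moves it in WT
  expect_identical(classifyTaxonomy("UNNU"), "primed_up_saturated")
  expect_identical(classifyTaxonomy("UUUU"), "primed_up_additive")
  expect_identical(classifyTaxonomy("DNND"), "primed_down_saturated")
  expect_identical(classifyTaxonomy("DDDD"), "primed_down_additive")
  ## Fld-responsive without any drought response
  expect_identical(classifyTaxonomy("UUNN"), "fld_only")
  expect_identical(classifyTaxonomy("NDNN"), "fld_only")
  expect_identical(classifyTaxonomy("NNNN"), "unaffected")
})

test_that("the taxonomy is total and single-valued over all 81 patterns", {
  tab <- patternTaxonomyTable()
  expect_identical(nrow(tab), 81L)
  expect_identical(anyDuplicated(tab$pattern), 0L)
  labels <- c("unaffected", "shared_induced", "shared_repressed",
              "abolished_induction", "ameliorated_induction",
              "abolished_repression", "ameliorated_repression",
              "opposed_fld_up_drought_down", "primed_up_saturated",
              "primed_up_additive", "primed_down_saturated",
              "primed_down_additive", "fld_only", "other")
  expect_true(all(tab$taxonomy %in% labels))
  ## every non-residual label is realized by at least one pattern
  expect_true(all(labels %in% tab$taxonomy))
  expect_identical(tab$taxonomy[tab$pattern == "NNNN"], "unaffected")
  expect_identical(sum(tab$taxonomy == "unaffected"), 1L)
})

test_that("pattern assignment partitions probes like a brute-force grouping", {
  set.seed(11)
  states <- matrix(sample(c("U", "D", "N"), 400 * 4, replace = TRUE,
                          prob = c(0.2, 0.2, 0.6)), 400, 4,
                   dimnames = list(sprintf("p%03d", 1:400), NULL))
  res <- assignPatterns(states)
  a <- res$assignment
  ## partition: every probe in exactly one cluster
  expect_identical(nrow(a), 400L)
  expect_true(all(table(a$probe_id) == 1))
  expect_lte(sum(res$clusters$size > 0), 81L)
  ## brute-force oracle: group probe ids by their pattern string
  oracle <- split(rownames(states), apply(states, 1, paste, collapse = ""))
  mine <- split(a$probe_id, a$pattern)
  expect_identical(mine[order(names(mine))], oracle[order(names(oracle))])
  ## identical patterns share a cluster id; distinct patterns do not
  expect_identical(length(unique(a$cluster_id)),
                   length(unique(a$pattern)))
  ## cluster ids ordered by descending size
  expect_true(all(diff(res$clusters$size[res$clusters$size > 0]) <= 0))
  ## the all-N cluster is listed even when empty
  allU <- matrix("U", 3, 4)
  expect_true("NNNN" %in% assignPatterns(allU)$clusters$pattern)
  states[1, 1] <- NA
  expect_error(assignPatterns(states), "missing|invalid")
})

test_that("Venn counts partition the drought responses", {
  st <- rbind(a = c("N", "N", "U", "U"),
              b = c("N", "N", "N", "U"),
              c = c("N", "N", "U", "N"),
              d = c("N", "N", "D", "D"),
              e = c("N", "N", "D", "U"),
              f = c("N", "N", "N", "N"))
  v <- droughtVennCounts(st)
  expect_identical(v$induced, c(both = 1L, wt_only = 2L, fld_only = 1L))
  expect_identical(v$repressed, c(both = 1L, wt_only = 0L, fld_only = 1L))
  ## sums are consistent with per-contrast DE counts
  expect_identical(unname(v$induced["both"] + v$induced["wt_only"]),
                   sum(st[, 4] == "U"))
  z <- droughtVennCounts(matrix("N", 5, 4))
  expect_true(all(unlist(z) == 0))
})

test_that("priming summary counts exactly the primed taxonomy classes", {
  st <- rbind(matrix(rep(c("U", "N", "N", "U"), 30), 30, byrow = TRUE),
              matrix(rep(c("D", "D", "D", "D"), 12), 12, byrow = TRUE),
              matrix(rep(c("N", "N", "U", "U"), 50), 50, byrow = TRUE),
              matrix("N", 20, 4))
  rownames(st) <- sprintf("p%03d", seq_len(nrow(st)))
  res <- assignPatterns(st)
  pr <- primingSummary(res)
  expect_identical(pr$count, 42L)
  ## disjoint from shared/abolished probes
  shared <- res$assignment$probe_id[startsWith(res$assignment$taxonomy,
                                               "shared")]
  expect_length(intersect(pr$probes, shared), 0)
  expect_identical(primingSummary(assignPatterns(matrix("N", 4, 4)))$count,
                   0L)
})

test_that("Fld-effect counts nest the 4-fold sets inside the 2-fold sets", {
  st <- rbind(c("U", "N", "N", "N"), c("U", "N", "N", "N"),
              c("D", "N", "N", "N"), c("N", "N", "N", "N"))
  lfc <- cbind(c(log2(5), log2(3), log2(0.2), 0), 0, 0, 0)
  fc <- fldEffectCounts(st, lfc)
  expect_identical(fc, c(induced_2x = 2L, induced_4x = 1L,
                         repressed_2x = 1L, repressed_4x = 1L))
  expect_true(fc["induced_4x"] <= fc["induced_2x"])
  zero <- fldEffectCounts(matrix("N", 0, 4), matrix(0, 0, 4))
  expect_true(all(zero == 0))
})
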