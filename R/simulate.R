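#' Default planted pattern-class table
#'
#' One row per planted taxonomy class plus the null (all-unaffected)
#' class. `proportion` is the fraction of all probes; per-contrast log2
#' effects `e1..e4` follow the canonical contrast order and satisfy the
#' cell-mean consistency constraint `e1 + e3 == e2 + e4`. Default class
#' masses mirror the focal cluster sizes of the motivating potato
#' drought study on a 42,034-probe array, with the four primed classes
#' summing to 300 probes at that array size. Every affected state
#' carries at least `effectSize` (default 3) log2 units so state calls
#' are recoverable at two replicates per cell; in the ameliorated
#' classes the genotypes separate under drought (C2 opposed to the
#' drought direction by `attenuation` log2 units), which by cell-mean
#' consistency makes the WT drought response `effectSize + attenuation`.
#' The proportions are fixed study conditions and do not depend on the
#' simulated array size.
#'
#' @param effectSize absolute log2 effect of a fully affected state.
#' @param attenuation log2 units by which Fld attenuates the WT drought
#'   response in the ameliorated classes.
#' @param fracUnexpressed fraction of probes carrying background only
#'   (the remaining mass goes to the null class).
#' @return `data.frame` with columns `class`, `proportion`, `e1..e4`.
#' @examples
#' defaultClassTable()[, 1:2]
#' @export
defaultClassTable <- function(effectSize = 3, attenuation = 3,
                              fracUnexpressed = 0.25) {
  m <- effectSize; h <- attenuation
  refProbes <- 42034  # reference array size of the emulated design
  tab <- rbind(
    data.frame(class = "shared_induced",        count = 601, e1 = 0,  e2 = 0,  e3 = m,  e4 = m),
    data.frame(class = "shared_repressed",      count = 929, e1 = 0,  e2 = 0,  e3 = -m, e4 = -m),
    data.frame(class = "abolished_induction",   count = 546, e1 = 0,  e2 = -m, e3 = 0,  e4 = m),
    data.frame(class = "ameliorated_induction", count = 274, e1 = 0,  e2 = -h, e3 = m,  e4 = m + h),
    data.frame(class = "abolished_repression",  count = 528, e1 = 0,  e2 = m,  e3 = 0,  e4 = -m),
    data.frame(class = "ameliorated_repression", count = 263, e1 = 0, e2 = h, e3 = -m, e4 = -m - h),
    data.frame(class = "opposed_control",       count = 240, e1 = m,  e2 = 0,  e3 = -m, e4 = 0),
    data.frame(class = "opposed_both",          count = 150, e1 = m,  e2 = m,  e3 = -m, e4 = -m),
    data.frame(class = "primed_up_saturated",   count = 80,  e1 = m,  e2 = 0,  e3 = 0,  e4 = m),
    data.frame(class = "primed_up_additive",    count = 37,  e1 = m,  e2 = m,  e3 = m,  e4 = m),
    data.frame(class = "primed_down_saturated", count = 130, e1 = -m, e2 = 0,  e3 = 0,  e4 = -m),
    data.frame(class = "primed_down_additive",  count = 53,  e1 = -m, e2 = -m, e3 = -m, e4 = -m),
    data.frame(class = "fld_only",              count = 300, e1 = m,  e2 = m,  e3 = 0,  e4 = 0))
  prop <- tab$count / refProbes
  nullProp <- 1 - fracUnexpressed - sum(prop)
  if (nullProp < 0)
    stop("planted class mass exceeds the expressed fraction")
  out <- data.frame(class = c(tab$class, "null"),
                    proportion = c(prop, nullProp),
                    e1 = c(tab$e1, 0), e2 = c(tab$e2, 0),
                    e3 = c(tab$e3, 0), e4 = c(tab$e4, 0))
  rownames(out) <- NULL
  out
}

#' Create a simulation configuration
#'
#' Supplies the study conditions emulated by the generator: a 2 genotype
#' x 2 treatment design with two arrays per cell, 42,034 probes of which
#' 25\% are near-background unexpressed, gene-wise log2 variances drawn
#' from a scaled inverse chi-square prior (d0 = 4, s0sq = 0.05), a
#' uniform baseline log2 intensity on [6, 14] spanning the expression
#' filter boundary, an additive truncated-normal background and a
#' MapMan-style annotation model with one planted 8-fold-odds category
#' enrichment.
#'
#' @param nProbes,nReps array size and replicates per design cell.
#' @param fracUnexpressed fraction of probes carrying background only.
#' @param classTable planted class table; see [defaultClassTable()].
#' @param d0True,s0sqTrue variance-prior parameters (log2 scale).
#' @param baselineRange uniform range of the baseline log2 intensity.
#' @param bgMu,bgSigma,bgAlpha background model; see
#'   [SimulationConfig-class].
#' @param nCategories,binBaseRate annotation model: number of leaf bins
#'   and the baseline per-bin membership probability.
#' @param plantedEnrichment `data.frame(bin, class, odds)` of planted
#'   category enrichments.
#' @param seed integer seed.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nProbes = 2000, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nProbes = 42034L,
                             nReps = 2L,
                             fracUnexpressed = 0.25,
                             classTable = defaultClassTable(
                               fracUnexpressed = fracUnexpressed),
                             d0True = 4,
                             s0sqTrue = 0.05,
                             baselineRange = c(6, 14),
                             bgMu = 200,
                             bgSigma = 2,
                             bgAlpha = 1000,
                             nCategories = 40L,
                             binBaseRate = 0.045,
                             plantedEnrichment = data.frame(
                               bin = "1.1",
                               class = "ameliorated_repression",
                               odds = 8),
                             seed = 1L) {
  new("SimulationConfig",
      nProbes = as.integer(nProbes), nReps = as.integer(nReps),
      fracUnexpressed = fracUnexpressed, classTable = classTable,
      d0True = d0True, s0sqTrue = s0sqTrue,
      baselineRange = as.numeric(baselineRange),
      bgMu = bgMu, bgSigma = bgSigma, bgAlpha = bgAlpha,
      nCategories = as.integer(nCategories), binBaseRate = binBaseRate,
      plantedEnrichment = plantedEnrichment,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d probes, %d reps/cell, %.0f%% unexpressed\n",
              object@nProbes, object@nReps, 100 * object@fracUnexpressed))
  cat(sprintf("  variance prior: d0 = %g, s0sq = %g; seed = %d\n",
              object@d0True, object@s0sqTrue, object@seed))
  cat(sprintf("  %d planted classes, %d leaf bins, %d planted enrichment(s)\n",
              sum(object@classTable$class != "null"), object@nCategories,
              nrow(object@plantedEnrichment)))
  invisible(NULL)
})

## deterministic integer apportionment of n among proportions
## (floor + largest remainders)
.apportion <- function(props, n) {
  target <- props * n
  counts <- floor(target)
  short <- n - sum(counts)
  if (short > 0) {
    frac <- target - counts
    idx <- order(frac, decreasing = TRUE)[seq_len(short)]
    counts[idx] <- counts[idx] + 1
  }
  as.integer(counts)
}

.stateFromEffect <- function(e) ifelse(e > 1, "U", ifelse(e < -1, "D", "N"))

## N(mu, sigma) truncated to (0, Inf), by inverse cdf
.rtruncnormPos <- function(n, mu, sigma) {
  p0 <- stats::pnorm(0, mu, sigma)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mu, sigma)
}

#' Simulate a factorial microarray experiment with planted ground truth
#'
#' Draws, per probe, a class label (planted pattern classes, null, or
#' unexpressed), a baseline log2 intensity, a gene-wise variance from the
#' scaled inverse chi-square prior, and four cell means shifted by the
#' class's contrast effects. Arrays are generated as
#' `2^(log2 signal) + background` with additive truncated-normal
#' background; unexpressed probes carry background only. The planted
#' truth (class, ternary pattern, cell means, variance) is attached as
#' `rowData`.
#'
#' @param config a [SimulationConfig-class].
#' @param scale `"raw"` (default; intensity-scale data ready for
#'   background correction) or `"log2"` (noise-plus-signal log2 matrix
#'   with no background component; requires `fracUnexpressed = 0`, used
#'   for calibration studies of the modelling stage alone).
#' @return A [FactorialArrayExperiment-class] with ground truth in
#'   `rowData`; retrieve it with [groundTruth()].
#' @examples
#' cfg <- simulationConfig(nProbes = 500, seed = 42)
#' fae <- simulateExpression(cfg)
#' table(groundTruth(fae)$class)[1:3]
#' @export
simulateExpression <- function(config, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (scale == "log2" && config@fracUnexpressed > 0)
    stop("log2-scale simulation has no background model; ",
         "set fracUnexpressed = 0")
  set.seed(config@seed)
  n <- config@nProbes
  ct <- config@classTable

  counts <- .apportion(c(ct$proportion, config@fracUnexpressed), n)
  classes <- c(ct$class, "unexpressed")
  lab <- sample(rep.int(classes, counts))

  idx <- match(lab, ct$class)          # NA for unexpressed
  expressed <- !is.na(idx)

  baseline <- stats::runif(n, config@baselineRange[1], config@baselineRange[2])
  sigma2 <- config@d0True * config@s0sqTrue / stats::rchisq(n, config@d0True)

  ## cell offsets in canonical cell order WT.C, WT.D, Fld.C, Fld.D
  offsets <- cbind(0, ct$e4, ct$e1, ct$e1 + ct$e3)
  mu <- matrix(NA_real_, n, 4, dimnames = list(NULL, .CELLS))
  mu[expressed, ] <- baseline[expressed] + offsets[idx[expressed], ]

  design <- expand.grid(replicate = seq_len(config@nReps),
                        treatment = .TREATMENTS, genotype = .GENOTYPES,
                        stringsAsFactors = FALSE)[, 3:1]
  cell <- paste(design$genotype, design$treatment, sep = ".")
  nArrays <- nrow(design)

  values <- matrix(NA_real_, n, nArrays)
  for (j in seq_len(nArrays)) {
    sig <- mu[, cell[j]] + stats::rnorm(n, 0, sqrt(sigma2))
    if (scale == "log2") {
      values[, j] <- sig
    } else {
      bg <- .rtruncnormPos(n, config@bgMu, config@bgSigma)
      v <- bg
      v[expressed] <- v[expressed] + 2^sig[expressed]
      values[, j] <- v
    }
  }
  rownames(values) <- sprintf("probe_%06d", seq_len(n))

  pat <- rep("NNNN", n)
  pat[expressed] <- paste0(.stateFromEffect(ct$e1)[idx[expressed]],
                           .stateFromEffect(ct$e2)[idx[expressed]],
                           .stateFromEffect(ct$e3)[idx[expressed]],
                           .stateFromEffect(ct$e4)[idx[expressed]])
  truth <- data.frame(class = lab, pattern = pat,
                      mu_WT.control = mu[, 1], mu_WT.drought = mu[, 2],
                      mu_Fld.control = mu[, 3], mu_Fld.drought = mu[, 4],
                      sigma2 = ifelse(expressed, sigma2, NA_real_))
  FactorialArrayExperiment(values, design, scale = scale, rowData = truth)
}

#' Bin vocabulary of the synthetic annotation
#'
#' Leaf bins are spread over ten top-level plant functional groups with
#' MapMan-style dot-separated codes (`"1"`, `"1.1"`, ...).
#'
#' @param nCategories number of leaf bins.
#' @return `data.frame` with `bin_code`, `bin_name`, `parent_code`,
#'   `parent_name` for each leaf.
#' @keywords internal
.binVocabulary <- function(nCategories) {
  tops <- c("photosynthesis", "minor CHO metabolism", "glycolysis",
            "cell wall", "amino acid metabolism", "stress",
            "hormone metabolism", "RNA", "protein", "transport")
  per <- ceiling(nCategories / length(tops))
  top <- rep(seq_along(tops), each = per)[seq_len(nCategories)]
  sub <- stats::ave(top, top, FUN = seq_along)
  data.frame(bin_code = paste(top, sub, sep = "."),
             bin_name = paste(tops[top], sub, sep = "."),
             parent_code = as.character(top),
             parent_name = tops[top])
}

#' Simulate a probe-to-functional-category annotation
#'
#' Assigns leaf bins to probes independently with a baseline membership
#' probability; for each planted enrichment the membership odds of the
#' stated bin among probes of the stated class are multiplied by the
#' stated factor. With the default 40 leaf bins at base rate 0.045 the
#' expected fraction of annotated probes is about 84\%, emulating
#' annotation coverage above 80\%.
#'
#' @param config a [SimulationConfig-class].
#' @param truth ground-truth `data.frame` from [groundTruth()] (needs
#'   `probe_id` and `class` columns).
#' @return Long-format `data.frame(probe_id, bin_code, bin_name)` of
#'   leaf-bin memberships (ancestor closure is applied downstream by
#'   [expandAnnotation()]).
#' @examples
#' cfg <- simulationConfig(nProbes = 300, seed = 3)
#' ann <- simulateAnnotation(cfg, groundTruth(simulateExpression(cfg)))
#' head(ann)
#' @export
simulateAnnotation <- function(config, truth) {
  stopifnot(is(config, "SimulationConfig"))
  if (!all(c("probe_id", "class") %in% colnames(truth)))
    stop("truth must have probe_id and class columns")
  pe <- config@plantedEnrichment
  known <- c(config@classTable$class, "unexpressed")
  if (nrow(pe) && !all(pe$class %in% known))
    stop("plantedEnrichment refers to unknown class name(s)")
  set.seed(config@seed + 1L)
  vocab <- .binVocabulary(config@nCategories)
  if (nrow(pe) && !all(pe$bin %in% vocab$bin_code))
    stop("plantedEnrichment refers to unknown bin code(s)")
  n <- nrow(truth)
  r <- config@binBaseRate
  prob <- matrix(r, n, config@nCategories)
  for (i in seq_len(nrow(pe))) {
    rows <- truth$class == pe$class[i]
    col <- match(pe$bin[i], vocab$bin_code)
    odds <- pe$odds[i] * r / (1 - r)
    prob[rows, col] <- odds / (1 + odds)
  }
  member <- matrix(stats::runif(n * config@nCategories), n) < prob
  hit <- which(member, arr.ind = TRUE)
  out <- data.frame(probe_id = truth$probe_id[hit[, 1]],
                    bin_code = vocab$bin_code[hit[, 2]],
                    bin_name = vocab$bin_name[hit[, 2]])
  out[order(out$probe_id, out$bin_code), , drop = FALSE]
}

#' Fraction of probes with at least one functional-category assignment
#'
#' @param annotation long-format annotation `data.frame` (`probe_id`).
#' @param probes character vector of probe ids forming the denominator.
#' @return proportion in [0, 1].
#' @export
annotationCoverage <- function(annotation, probes) {
  mean(probes %in% annotation$probe_id)
}

#' Draw one array column from the normal + exponential convolution model
#'
#' Used to validate background-correction parameter estimation against a
#' known-truth sample: observed intensity = Normal(mu, sigma) background
#' plus Exponential(mean alpha) signal.
#'
#' @param n number of probes.
#' @param mu,sigma,alpha model parameters.
#' @return numeric vector of length `n`.
#' @export
simulateNormexpColumn <- function(n, mu, sigma, alpha) {
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / alpha)
}

#' Simulate a qPCR Ct table
#'
#' Ct values follow `Ct = baseline(gene) + offset(sample) -
#' log2(relative expression) + noise`, so perfect doubling per cycle is
#' assumed. The reference gene has relative expression 1 in every
#' sample. Relative expressions are taken per condition against the
#' calibrator condition.
#'
#' @param foldChanges genes x conditions matrix of relative expression
#'   versus the calibrator condition (rownames = genes, colnames =
#'   conditions; values for the calibrator column are normalized away).
#' @param nBioReps,nTechReps biological and technical replicates per
#'   condition (defaults mirror 5 biological x 2 technical).
#' @param noiseSd technical noise sd in cycles.
#' @param refGene reference (normalizer) gene id, added automatically.
#' @param calibrator calibrator condition (default first column).
#' @param sampleOffsetSd sd of the per-biological-sample Ct offset
#'   (loading differences; cancel through the reference gene).
#' @param seed integer seed.
#' @return `data.frame(gene, condition, bio_rep, tech_rep, ct)` with
#'   attributes `reference` and `calibrator`.
#' @examples
#' fc <- matrix(c(1, 2), 1, 2,
#'              dimnames = list("geneA", c("control", "drought")))
#' ct <- simulateQpcr(fc, noiseSd = 0, sampleOffsetSd = 0, seed = 1)
#' head(ct)
#' @export
simulateQpcr <- function(foldChanges, nBioReps = 5L, nTechReps = 2L,
                         noiseSd = 0.15, refGene = "EF1a",
                         calibrator = colnames(foldChanges)[1],
                         sampleOffsetSd = 0.3, seed = 1L) {
  foldChanges <- as.matrix(foldChanges)
  if (any(foldChanges <= 0)) stop("fold changes must be positive")
  if (is.null(rownames(foldChanges)) || is.null(colnames(foldChanges)))
    stop("foldChanges needs gene rownames and condition colnames")
  if (!calibrator %in% colnames(foldChanges))
    stop("calibrator condition not found")
  set.seed(as.integer(seed))
  rel <- sweep(foldChanges, 1, foldChanges[, calibrator], "/")
  rel <- rbind(rel, matrix(1, 1, ncol(rel),
                           dimnames = list(refGene, colnames(rel))))
  genes <- rownames(rel)
  conditions <- colnames(rel)
  baseCt <- stats::setNames(stats::runif(length(genes), 18, 26), genes)
  grid <- expand.grid(tech_rep = seq_len(nTechReps),
                      bio_rep = seq_len(nBioReps),
                      gene = genes, condition = conditions,
                      stringsAsFactors = FALSE)[, 4:1]
  offKey <- paste(grid$condition, grid$bio_rep)
  offs <- stats::setNames(
    stats::rnorm(length(unique(offKey)), 0, sampleOffsetSd), unique(offKey))
  grid$ct <- baseCt[grid$gene] + offs[offKey] -
    log2(rel[cbind(grid$gene, grid$condition)]) +
    stats::rnorm(nrow(grid), 0, noiseSd)
  structure(grid, reference = refGene, calibrator = calibrator)
}

#' Simulate a metabolite concentration table
#'
#' Amino acid concentrations (per g fresh weight) for the four design
#' cells, with multiplicative log-normal replicate noise. Defaults plant
#' the drought-induced nitrogen-cycling signature of wild-type leaves: a
#' 4.3-fold increase of the Gln/Glu ratio and a 1.9-fold increase of the
#' Asn/Asp ratio under drought in WT, with no change in the Fld
#' genotype; proline rises under drought in both genotypes (more in WT).
#'
#' @param nReps samples per design cell.
#' @param noiseCv coefficient of variation of replicate noise (0 for
#'   noise-free planted values).
#' @param glnGluFold,asnAspFold named numeric (`WT`, `Fld`): planted
#'   drought fold-change of each ratio per genotype.
#' @param seed integer seed.
#' @return list with `table` (metabolite x sample concentration matrix)
#'   and `design` (`data.frame(sample_id, genotype, treatment,
#'   replicate)`).
#' @examples
#' sim <- simulateMetabolites(noiseCv = 0, seed = 1)
#' sim$table[, 1:4]
#' @export
simulateMetabolites <- function(nReps = 5L, noiseCv = 0.1,
                                glnGluFold = c(WT = 4.3, Fld = 1),
                                asnAspFold = c(WT = 1.9, Fld = 1),
                                seed = 1L) {
  set.seed(as.integer(seed))
  ## cell order WT.C, WT.D, Fld.C, Fld.D; units: micromol / g FW
  base <- rbind(
    Glu  = c(6,   6,   6,   6),
    Gln  = c(3,   3 * glnGluFold["WT"], 3, 3 * glnGluFold["Fld"]),
    Asp  = c(4,   4,   4,   4),
    Asn  = c(2,   2 * asnAspFold["WT"], 2, 2 * asnAspFold["Fld"]),
    Pro  = c(0.5, 6,   0.9, 2.5),
    Ser  = c(2,   3.2, 2,   3.2),
    Gly  = c(1.5, 2.4, 1.5, 2.4),
    Thr  = c(1,   2.5, 1,   1.6),
    Ala  = c(2,   2,   2.6, 2.6),
    GABA = c(1,   1,   1,   1))
  colnames(base) <- .CELLS
  design <- expand.grid(replicate = seq_len(nReps),
                        treatment = .TREATMENTS, genotype = .GENOTYPES,
                        stringsAsFactors = FALSE)[, 3:1]
  cell <- paste(design$genotype, design$treatment, sep = ".")
  design <- cbind(sample_id = paste(design$genotype,
                                    ifelse(design$treatment == "control",
                                           "C", "D"),
                                    design$replicate, sep = "."),
                  design)
  m <- base[, cell, drop = FALSE]
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    noise <- matrix(stats::rlnorm(length(m), -sdlog^2 / 2, sdlog),
                    nrow(m), ncol(m))
    m <- m * noise
  }
  colnames(m) <- design$sample_id
  list(table = m, design = design)
}
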