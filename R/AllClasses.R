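#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData assayNames rowData<- assay<-
#' @importFrom S4Vectors DataFrame metadata SimpleList metadata<-
#' @importFrom stats rnorm runif rexp rchisq rlnorm sd var
NULL

## canonical factor levels of the 2x2 design
.GENOTYPES  <- c("WT", "Fld")
.TREATMENTS <- c("control", "drought")

## canonical cell labels, in the plotting order of the field
## (WT.control, WT.drought, Fld.control, Fld.drought)
.CELLS <- c("WT.control", "WT.drought", "Fld.control", "Fld.drought")

## canonical contrast order:
##   C1 Fld vs WT under control, C2 Fld vs WT under drought,
##   C3 drought vs control in Fld, C4 drought vs control in WT
.CONTRASTS <- c("FldVsWT.control", "FldVsWT.drought",
                "DroughtVsControl.Fld", "DroughtVsControl.WT")
.CONTRAST_CELLS <- list(
  FldVsWT.control      = c(plus = "Fld.control", minus = "WT.control"),
  FldVsWT.drought      = c(plus = "Fld.drought", minus = "WT.drought"),
  DroughtVsControl.Fld = c(plus = "Fld.drought", minus = "Fld.control"),
  DroughtVsControl.WT  = c(plus = "WT.drought",  minus = "WT.control"))

#' Container for a 2x2 factorial single-channel microarray experiment
#'
#' `FactorialArrayExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment] for probe-by-array intensity
#' data from a genotype (WT vs Fld) by treatment (control vs drought)
#' factorial design. `colData` must carry `genotype`, `treatment` and
#' `replicate` columns; all four design cells must be populated. The assay
#' named `"intensity"` holds raw (strictly positive) or log2 intensities,
#' with the scale recorded in `metadata(x)$scale`.
#'
#' @slot .S4 methods inherited from `SummarizedExperiment`.
#' @seealso [FactorialArrayExperiment()] for the constructor,
#'   [intensityScale()], [designCells()].
#' @export
setClass("FactorialArrayExperiment",
         contains = "SummarizedExperiment")

setValidity("FactorialArrayExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  needed <- c("genotype", "treatment", "replicate")
  if (!all(needed %in% colnames(cd)))
    return(sprintf("colData must contain columns: %s",
                   paste(needed, collapse = ", ")))
  if (!all(as.character(cd$genotype) %in% .GENOTYPES))
    msg <- c(msg, sprintf("genotype levels must be in {%s}",
                          paste(.GENOTYPES, collapse = ", ")))
  if (!all(as.character(cd$treatment) %in% .TREATMENTS))
    msg <- c(msg, sprintf("treatment levels must be in {%s}",
                          paste(.TREATMENTS, collapse = ", ")))
  cells <- paste(cd$genotype, cd$treatment, sep = ".")
  if (!all(.CELLS %in% cells))
    msg <- c(msg, "all four genotype x treatment cells must have arrays")
  sc <- metadata(object)$scale
  if (is.null(sc) || !sc %in% c("raw", "log2"))
    msg <- c(msg, "metadata(x)$scale must be \"raw\" or \"log2\"")
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay \"intensity\" is required")
  else if (identical(sc, "raw")) {
    v <- assay(object, "intensity")
    if (any(!is.finite(v)) || any(v <= 0))
      msg <- c(msg, "raw intensities must be finite and strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Simulation settings for the synthetic factorial microarray generator
#'
#' Bundles every tunable of the generator: array dimensions, the planted
#' pattern-class table, the variance prior on the log2 scale, the additive
#' normal background, the annotation model and the planted category
#' enrichments. Build instances with [simulationConfig()], which supplies
#' the default study conditions.
#'
#' @slot nProbes number of probes on the array.
#' @slot nReps arrays per genotype x treatment cell.
#' @slot fracUnexpressed proportion of probes carrying background only.
#' @slot classTable `data.frame` with columns `class`, `proportion` and
#'   per-contrast log2 effects `e1..e4` (constrained to `e1+e3 == e2+e4`
#'   so the four cell means exist).
#' @slot d0True,s0sqTrue scaled inverse chi-square prior for gene-wise
#'   variances on the log2 scale.
#' @slot baselineRange range of the uniform baseline log2 intensity.
#' @slot bgMu,bgSigma mean and sd of the additive normal background
#'   (intensity units, truncated positive).
#' @slot bgAlpha mean of the exponential signal component used when
#'   drawing columns from the exact normal+exponential convolution model
#'   (background-correction validation; the expression generator itself
#'   uses the log-scale signal model).
#' @slot nCategories number of leaf functional bins.
#' @slot binBaseRate per-leaf-bin baseline membership probability.
#' @slot plantedEnrichment `data.frame` with columns `bin`, `class`,
#'   `odds`: membership odds multiplier for `bin` among probes of `class`.
#' @slot seed integer seed making every generator call reproducible.
#' @export
setClass("SimulationConfig",
         representation(nProbes = "integer",
                        nReps = "integer",
                        fracUnexpressed = "numeric",
                        classTable = "data.frame",
                        d0True = "numeric",
                        s0sqTrue = "numeric",
                        baselineRange = "numeric",
                        bgMu = "numeric",
                        bgSigma = "numeric",
                        bgAlpha = "numeric",
                        nCategories = "integer",
                        binBaseRate = "numeric",
                        plantedEnrichment = "data.frame",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  ct <- object@classTable
  needed <- c("class", "proportion", "e1", "e2", "e3", "e4")
  if (!all(needed %in% colnames(ct)))
    return(sprintf("classTable needs columns %s", paste(needed, collapse = ", ")))
  if (anyDuplicated(ct$class))
    msg <- c(msg, "classTable classes must be unique")
  tot <- sum(ct$proportion) + object@fracUnexpressed
  if (abs(tot - 1) > 1e-8)
    msg <- c(msg, sprintf(
      "class proportions plus fracUnexpressed must sum to 1 (got %.6f)", tot))
  if (any(ct$proportion < 0) || object@fracUnexpressed < 0 ||
      object@fracUnexpressed > 1)
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (any(abs(ct$e1 + ct$e3 - ct$e2 - ct$e4) > 1e-8))
    msg <- c(msg, "contrast effects must satisfy e1 + e3 == e2 + e4")
  if (object@nReps < 2L)
    msg <- c(msg, "nReps must be >= 2")
  if (object@nProbes < 1L)
    msg <- c(msg, "nProbes must be positive")
  scales <- c(d0True = object@d0True, s0sqTrue = object@s0sqTrue,
              bgMu = object@bgMu, bgSigma = object@bgSigma,
              bgAlpha = object@bgAlpha, binBaseRate = object@binBaseRate)
  if (any(scales <= 0))
    msg <- c(msg, sprintf("scale parameters must be strictly positive (%s)",
                          paste(names(scales)[scales <= 0], collapse = ", ")))
  if (length(object@baselineRange) != 2L ||
      diff(object@baselineRange) <= 0)
    msg <- c(msg, "baselineRange must be an increasing pair")
  pe <- object@plantedEnrichment
  if (nrow(pe)) {
    if (!all(c("bin", "class", "odds") %in% colnames(pe)))
      msg <- c(msg, "plantedEnrichment needs columns bin, class, odds")
    else if (!all(pe$class %in% ct$class))
      msg <- c(msg, sprintf("plantedEnrichment refers to unknown class(es): %s",
                            paste(setdiff(pe$class, ct$class), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Moderated linear-model fit for the four factorial contrasts
#'
#' Holds, per probe, the four cell means on the log2 scale, the residual
#' variance with its degrees of freedom, the empirical-Bayes prior
#' (`d0`, `s0sq`), the posterior (moderated) variances and, per contrast,
#' the log2 fold-change, moderated t, two-sided p, BH-adjusted q and the
#' ternary expression state over \{U, D, N\}. Created by [moderatedFit()].
#'
#' @slot cellMeans probes x 4 matrix of cell means (log2).
#' @slot coefficients probes x 4 matrix of contrast log2 fold-changes.
#' @slot s2 residual variances; `df` their degrees of freedom.
#' @slot d0,s0sq empirical-Bayes prior degrees of freedom and variance.
#' @slot s2Post moderated (posterior) variances.
#' @slot varFactor unscaled variance factor of each contrast
#'   (sum of 1/n over the two cells).
#' @slot t,p,q probes x 4 matrices of moderated t, p and BH q.
#' @slot states probes x 4 character matrix over \{U, D, N\}.
#' @slot thresholds list with `fcUp`, `fcDown`, `alpha`.
#' @export
setClass("ModeratedFit",
         representation(cellMeans = "matrix",
                        coefficients = "matrix",
                        s2 = "numeric",
                        df = "numeric",
                        d0 = "numeric",
                        s0sq = "numeric",
                        s2Post = "numeric",
                        varFactor = "numeric",
                        t = "matrix",
                        p = "matrix",
                        q = "matrix",
                        states = "matrix",
                        thresholds = "list"))

setValidity("ModeratedFit", function(object) {
  n <- nrow(object@coefficients)
  msg <- character()
  if (ncol(object@coefficients) != 4L)
    msg <- c(msg, "exactly four contrasts expected")
  for (slot in c("t", "p", "q", "states"))
    if (!all(dim(slot(object, slot)) == dim(object@coefficients)))
      msg <- c(msg, sprintf("slot %s has wrong dimensions", slot))
  if (length(object@s2) != n || length(object@s2Post) != n)
    msg <- c(msg, "variance vectors must have one entry per probe")
  if (any(object@q < object@p - 1e-12, na.rm = TRUE))
    msg <- c(msg, "q must dominate p elementwise")
  if (any(object@q > 1 + 1e-12 | object@q < 0, na.rm = TRUE))
    msg <- c(msg, "q must lie in [0, 1]")
  ok <- object@states %in% c("U", "D", "N")
  if (!all(ok)) msg <- c(msg, "states must be U, D or N")
  if (length(msg)) msg else TRUE
})
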