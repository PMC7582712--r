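#' Construct a FactorialArrayExperiment
#'
#' @param intensities numeric matrix, probes x arrays. Strictly positive
#'   when `scale = "raw"`.
#' @param design `data.frame` with one row per array and columns
#'   `genotype` (`"WT"`/`"Fld"`), `treatment` (`"control"`/`"drought"`)
#'   and `replicate`. Row order must match the columns of `intensities`;
#'   if it has a `sample_id` column it is matched against the column
#'   names instead.
#' @param scale `"raw"` or `"log2"`.
#' @param rowData optional probe-level annotation (e.g. ground truth).
#'
#' @return A [FactorialArrayExperiment-class] object.
#' @examples
#' design <- expand.grid(replicate = 1:2,
#'                       treatment = c("control", "drought"),
#'                       genotype  = c("WT", "Fld"))
#' m <- matrix(rexp(800, 1 / 100) + 50, 100, 8,
#'             dimnames = list(sprintf("probe_%03d", 1:100), NULL))
#' fae <- FactorialArrayExperiment(m, design)
#' designCells(fae)
#' @export
FactorialArrayExperiment <- function(intensities, design,
                                     scale = c("raw", "log2"),
                                     rowData = NULL) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  design <- as.data.frame(design)
  if (nrow(design) != ncol(intensities))
    stop("design must have one row per array column")
  if ("sample_id" %in% colnames(design) && !is.null(colnames(intensities))) {
    idx <- match(colnames(intensities), design$sample_id)
    if (anyNA(idx)) stop("design sample_id does not cover all array columns")
    design <- design[idx, , drop = FALSE]
  }
  design$genotype <- factor(as.character(design$genotype), levels = .GENOTYPES)
  design$treatment <- factor(as.character(design$treatment),
                             levels = .TREATMENTS)
  if (anyNA(design$genotype) || anyNA(design$treatment))
    stop("genotype/treatment levels must be WT/Fld and control/drought")
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste(design$genotype,
                                   ifelse(design$treatment == "control",
                                          "C", "D"),
                                   design$replicate, sep = ".")
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("probe_%06d", seq_len(nrow(intensities)))
  se <- SummarizedExperiment(
    assays = SimpleList(intensity = intensities),
    colData = DataFrame(design, row.names = colnames(intensities)))
  if (!is.null(rowData)) rowData(se) <- DataFrame(rowData)
  metadata(se)$scale <- scale
  new("FactorialArrayExperiment", se)
}

#' Accessors for FactorialArrayExperiment
#'
#' `intensityScale` returns `"raw"` or `"log2"`; `designCells` the
#' genotype-by-treatment cell of each array as a factor with the four
#' canonical levels; `designTable` the design as a plain `data.frame`;
#' `groundTruth` the planted per-probe truth (`rowData`) for simulated
#' objects.
#'
#' @param x a [FactorialArrayExperiment-class].
#' @name FactorialArrayExperiment-accessors
NULL

#' @rdname FactorialArrayExperiment-accessors
#' @export
setMethod("intensityScale", "FactorialArrayExperiment",
          function(x) metadata(x)$scale)

#' @rdname FactorialArrayExperiment-accessors
#' @export
setMethod("designCells", "FactorialArrayExperiment", function(x) {
  cd <- colData(x)
  factor(paste(cd$genotype, cd$treatment, sep = "."), levels = .CELLS)
})

#' @rdname FactorialArrayExperiment-accessors
#' @export
setMethod("designTable", "FactorialArrayExperiment", function(x) {
  cd <- as.data.frame(colData(x))
  cbind(sample_id = rownames(cd), cd, row.names = NULL)
})

#' @rdname FactorialArrayExperiment-accessors
#' @export
setMethod("groundTruth", "FactorialArrayExperiment", function(x) {
  rd <- as.data.frame(rowData(x))
  if (!nrow(rd) || !"class" %in% colnames(rd))
    stop("no ground truth attached; object was not produced by ",
         "simulateExpression()")
  cbind(probe_id = rownames(x), rd, row.names = NULL)
})

setMethod("show", "FactorialArrayExperiment", function(object) {
  cat(sprintf("FactorialArrayExperiment: %d probes x %d arrays (%s scale)\n",
              nrow(object), ncol(object), intensityScale(object)))
  print(table(designCells(object)))
  if ("class" %in% colnames(rowData(object)))
    cat("ground truth attached (see groundTruth())\n")
  invisible(NULL)
})

#' Canonical contrasts of the 2x2 design
#'
#' Returns the four pairwise comparisons in canonical order:
#' C1 Fld vs WT under control, C2 Fld vs WT under drought, C3 drought vs
#' control in Fld, C4 drought vs control in WT. Each entry names the
#' `plus` and `minus` design cell of the log2 fold-change.
#'
#' @return named list of length 4.
#' @examples
#' canonicalContrasts()
#' @export
canonicalContrasts <- function() .CONTRAST_CELLS
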