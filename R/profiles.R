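#' Row-wise standardized scores
#'
#' Standardizes each metabolite row to mean 0 and sample-sd 1 (the
#' scale of a standardized-score heatmap). Rows with no variation
#' cannot be standardized; they are returned as `NA` and flagged.
#'
#' @param m numeric matrix (metabolites x samples).
#' @return matrix of z-scores with attribute `constantRows` naming any
#'   degenerate rows (also warned about).
#' @examples
#' standardizeRows(rbind(a = c(1, 2, 3)))
#' @export
standardizeRows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 samples")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  bad <- sd == 0
  out <- (m - mu) / ifelse(bad, NA_real_, sd)
  if (any(bad)) {
    warning(sprintf("constant row(s) cannot be standardized: %s",
                    paste(rownames(m)[bad], collapse = ", ")))
  }
  attr(out, "constantRows") <- rownames(m)[bad]
  out
}

#' Nitrogen-cycling amino acid ratios
#'
#' Computes the Gln/Glu and Asn/Asp ratios per sample, averages them
#' per genotype x treatment cell, and reports the drought fold-change
#' (stressed mean / control mean) per genotype. These ratios are the
#' customary markers of leaf nitrogen mobilization.
#'
#' @param m metabolite x sample concentration matrix with rownames
#'   including `Gln`, `Glu`, `Asn`, `Asp`.
#' @param design `data.frame` with `sample_id`, `genotype`, `treatment`
#'   matching the columns of `m`.
#' @return `list(cellMeans, folds)`: per-cell mean ratios
#'   (`data.frame(cell, gln_glu, asn_asp)`) and per-genotype drought
#'   folds (`data.frame(genotype, gln_glu_fold, asn_asp_fold)`).
#' @examples
#' sim <- simulateMetabolites(noiseCv = 0, seed = 1)
#' nitrogenRatios(sim$table, sim$design)$folds
#' @export
nitrogenRatios <- function(m, design) {
  m <- as.matrix(m)
  needed <- c("Gln", "Glu", "Asn", "Asp")
  if (!all(needed %in% rownames(m)))
    stop(sprintf("metabolite table must contain rows: %s",
                 paste(needed, collapse = ", ")))
  design <- as.data.frame(design)
  if (!is.null(design$sample_id) && !is.null(colnames(m))) {
    idx <- match(colnames(m), design$sample_id)
    if (anyNA(idx)) stop("design does not cover all samples")
    design <- design[idx, , drop = FALSE]
  }
  if (nrow(design) != ncol(m))
    stop("design must have one row per sample column")
  ok <- m["Glu", ] > 0 & m["Asp", ] > 0
  if (!all(ok)) {
    warning(sprintf("excluding %d sample(s) with zero denominator",
                    sum(!ok)))
    m <- m[, ok, drop = FALSE]
    design <- design[ok, , drop = FALSE]
  }
  glnGlu <- m["Gln", ] / m["Glu", ]
  asnAsp <- m["Asn", ] / m["Asp", ]
  cell <- factor(paste(design$genotype, design$treatment, sep = "."),
                 levels = .CELLS)
  cm <- data.frame(cell = .CELLS,
                   gln_glu = as.numeric(tapply(glnGlu, cell, mean)),
                   asn_asp = as.numeric(tapply(asnAsp, cell, mean)),
                   row.names = NULL)
  fold <- function(ratios, geno) {
    d <- cm[cm$cell == paste0(geno, ".drought"), ratios]
    c <- cm[cm$cell == paste0(geno, ".control"), ratios]
    d / c
  }
  folds <- data.frame(genotype = .GENOTYPES,
                      gln_glu_fold = c(fold("gln_glu", "WT"),
                                       fold("gln_glu", "Fld")),
                      asn_asp_fold = c(fold("asn_asp", "WT"),
                                       fold("asn_asp", "Fld")),
                      row.names = NULL)
  list(cellMeans = cm, folds = folds)
}
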