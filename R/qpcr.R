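.ctColumns <- c("gene", "condition", "bio_rep", "tech_rep", "ct")

## mean Ct per (gene, condition, bio_rep) after averaging technical reps
.ctBioMeans <- function(ct) {
  stopifnot(all(.ctColumns %in% colnames(ct)))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and positive")
  stats::aggregate(ct ~ gene + condition + bio_rep, data = ct, FUN = mean)
}

## delta Ct (gene minus reference) per biological replicate and condition
.deltaCt <- function(ct, gene, reference) {
  bm <- .ctBioMeans(ct)
  g <- bm[bm$gene == gene, ]
  r <- bm[bm$gene == reference, ]
  if (!nrow(r)) stop(sprintf("reference gene '%s' not measured", reference))
  if (!nrow(g)) stop(sprintf("gene '%s' not measured", gene))
  m <- merge(g, r, by = c("condition", "bio_rep"),
             suffixes = c("_gene", "_ref"))
  if (!nrow(m)) stop("gene and reference share no samples")
  m$delta_ct <- m$ct_gene - m$ct_ref
  m[, c("condition", "bio_rep", "delta_ct")]
}

#' Relative expression by the delta-delta-Ct method
#'
#' Technical replicates are averaged first; per biological replicate
#' the gene's Ct is normalized against the reference gene
#' (`dCt = Ct_gene - Ct_ref`), then the condition is referenced to the
#' calibrator condition (`ddCt = mean dCt(condition) - mean
#' dCt(calibrator)`). Relative expression is `2^-ddCt`, assuming
#' perfect per-cycle doubling. Per-replicate values (each replicate's
#' dCt against the calibrator mean) quantify the spread.
#'
#' @param ct long-format Ct table with columns `gene`, `condition`,
#'   `bio_rep`, `tech_rep`, `ct` (e.g. from [simulateQpcr()]).
#' @param gene target gene id.
#' @param condition condition whose expression is sought.
#' @param reference reference (normalizer) gene id; defaults to the
#'   table's `reference` attribute.
#' @param calibrator calibrator condition; defaults to the table's
#'   `calibrator` attribute.
#' @return `list(estimate, ddCt, perReplicate)`.
#' @examples
#' fc <- matrix(c(1, 2), 1, 2,
#'              dimnames = list("geneA", c("control", "drought")))
#' ct <- simulateQpcr(fc, noiseSd = 0, sampleOffsetSd = 0, seed = 1)
#' deltaDeltaCt(ct, "geneA", "drought")$estimate  # 2
#' @export
deltaDeltaCt <- function(ct, gene, condition,
                         reference = attr(ct, "reference"),
                         calibrator = attr(ct, "calibrator")) {
  if (is.null(reference)) stop("reference gene must be given")
  if (is.null(calibrator)) stop("calibrator condition must be given")
  d <- .deltaCt(ct, gene, reference)
  if (!condition %in% d$condition)
    stop(sprintf("condition '%s' not measured for gene '%s'",
                 condition, gene))
  if (!calibrator %in% d$condition)
    stop(sprintf("calibrator '%s' not measured for gene '%s'",
                 calibrator, gene))
  dCond <- d$delta_ct[d$condition == condition]
  dCal <- d$delta_ct[d$condition == calibrator]
  ddct <- mean(dCond) - mean(dCal)
  list(estimate = 2^(-ddct), ddCt = ddct,
       perReplicate = 2^(-(dCond - mean(dCal))))
}

#' Relative expression of every gene and condition
#'
#' Applies [deltaDeltaCt()] over the full Ct table.
#'
#' @inheritParams deltaDeltaCt
#' @return `data.frame(gene, condition, rel_expr, ddCt)`.
#' @export
relativeExpression <- function(ct, reference = attr(ct, "reference"),
                               calibrator = attr(ct, "calibrator")) {
  genes <- setdiff(unique(ct$gene), reference)
  conditions <- unique(ct$condition)
  grid <- expand.grid(gene = genes, condition = conditions,
                      stringsAsFactors = FALSE)
  res <- mapply(function(g, cc) {
    d <- deltaDeltaCt(ct, g, cc, reference, calibrator)
    c(d$estimate, d$ddCt)
  }, grid$gene, grid$condition)
  data.frame(grid, rel_expr = res[1, ], ddCt = res[2, ], row.names = NULL)
}

#' Ternary states from qPCR delta-Ct values
#'
#' Calls induced/repressed/unaffected per gene and condition against
#' the calibrator, using a Welch t-test on the per-replicate dCt values
#' together with the fold-change thresholds used for the arrays.
#'
#' @inheritParams deltaDeltaCt
#' @param fcUp,fcDown,alpha state-call thresholds as in [callState()].
#' @return `data.frame(gene, condition, rel_expr, p, state)`.
#' @export
qpcrStates <- function(ct, reference = attr(ct, "reference"),
                       calibrator = attr(ct, "calibrator"),
                       fcUp = 2, fcDown = 0.5, alpha = 0.05) {
  genes <- setdiff(unique(ct$gene), reference)
  conditions <- setdiff(unique(ct$condition), calibrator)
  out <- lapply(genes, function(g) {
    d <- .deltaCt(ct, g, reference)
    dCal <- d$delta_ct[d$condition == calibrator]
    do.call(rbind, lapply(conditions, function(cc) {
      dCond <- d$delta_ct[d$condition == cc]
      fc <- 2^(-(mean(dCond) - mean(dCal)))
      p <- tryCatch(stats::t.test(dCond, dCal)$p.value,
                    error = function(e) 1)
      state <- if (p < alpha && fc > fcUp) "U"
               else if (p < alpha && fc < fcDown) "D" else "N"
      data.frame(gene = g, condition = cc, rel_expr = fc, p = p,
                 state = state)
    }))
  })
  do.call(rbind, out)
}

#' Microarray versus qPCR concordance class
#'
#' Compares the four per-contrast fold-changes and state calls of one
#' gene between platforms: `strict` if all four states agree and every
#' fold-change pair agrees within a ratio tolerance;
#' `quantitative_shift` if all states agree but at least one
#' fold-change differs beyond tolerance; `cluster_reassigned` if any
#' state call differs (a state flip moves the gene to another pattern
#' cluster).
#'
#' @param arrayFc,qpcrFc fold-changes (linear scale) over the same four
#'   comparisons.
#' @param arrayStates,qpcrStates ternary state calls over the same four
#'   comparisons.
#' @param tolerance maximal fold-ratio still counted as agreement
#'   (default 1.5).
#' @return one of `"strict"`, `"quantitative_shift"`,
#'   `"cluster_reassigned"`.
#' @examples
#' concordanceClass(c(2.5, 1, 1, 3), c(2.4, 1, 1, 3.2),
#'                  c("U","N","N","U"), c("U","N","N","U"))
#' @export
concordanceClass <- function(arrayFc, qpcrFc, arrayStates, qpcrStates,
                             tolerance = 1.5) {
  if (length(arrayFc) != 4 || length(qpcrFc) != 4 ||
      length(arrayStates) != 4 || length(qpcrStates) != 4)
    stop("all four comparisons are required")
  if (any(!is.finite(arrayFc)) || any(!is.finite(qpcrFc)) ||
      any(arrayFc <= 0) || any(qpcrFc <= 0))
    stop("fold-changes must be positive and finite")
  stopifnot(tolerance >= 1)
  if (any(arrayStates != qpcrStates)) return("cluster_reassigned")
  ratio <- pmax(arrayFc / qpcrFc, qpcrFc / arrayFc)
  if (any(ratio > tolerance)) return("quantitative_shift")
  "strict"
}
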