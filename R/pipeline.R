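#' Run the full factorial microarray pipeline
#'
#' Orchestrates preprocess, differential expression, pattern clustering
#' and functional enrichment end to end, either on a simulated
#' experiment (pass a [SimulationConfig-class]) or on user data (pass a
#' raw-scale [FactorialArrayExperiment-class] plus an annotation
#' table). All stages are deterministic given the configuration seed,
#' so identical inputs reproduce identical artifacts.
#'
#' @param x a `SimulationConfig` (simulate mode) or a raw-scale
#'   `FactorialArrayExperiment`.
#' @param annotation probe-to-bin annotation `data.frame`; simulated
#'   automatically in simulate mode when omitted.
#' @param threshold expression-filter margin (default 0.10).
#' @param fcUp,fcDown,alpha DE thresholds as in [moderatedFit()].
#' @param outDir optional directory; when given, all result tables are
#'   written as TSV (matrix + design, per-contrast DE tables, cluster
#'   membership, cluster sizes, Venn counts, the 81-row
#'   pattern-taxonomy reference, enrichment results, run summary).
#' @param verbose print stage-level progress with probe counts.
#' @return list with elements `experiment` (filtered log2 object),
#'   `params`, `mask`, `fit`, `patterns`, `venn`, `priming`,
#'   `fldEffect`, `enrichment`, `annotation` and `summary` (named
#'   numeric vector of headline counts).
#' @examples
#' res <- runPipeline(simulationConfig(nProbes = 1500, seed = 9))
#' res$summary
#' @export
runPipeline <- function(x, annotation = NULL, threshold = 0.10,
                        fcUp = 2, fcDown = 0.5, alpha = 0.05,
                        outDir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is(x, "SimulationConfig")) {
    say("simulate: %d probes x %d arrays", x@nProbes, 4L * x@nReps)
    fae <- simulateExpression(x)
    if (is.null(annotation))
      annotation <- simulateAnnotation(x, groundTruth(fae))
  } else if (is(x, "FactorialArrayExperiment")) {
    fae <- x
  } else stop("x must be a SimulationConfig or FactorialArrayExperiment")
  if (is.null(annotation))
    stop("an annotation table is required outside simulate mode")

  pre <- preprocessArrays(fae, threshold = threshold)
  say("preprocess: %d / %d probes pass the expression filter",
      sum(pre$mask), length(pre$mask))
  fit <- moderatedFit(pre$experiment, fcUp = fcUp, fcDown = fcDown,
                      alpha = alpha)
  say("diffexpr: prior d0 = %.3g, s0sq = %.4g", fit@d0, fit@s0sq)

  states <- contrastStates(fit)
  pat <- assignPatterns(states)
  venn <- droughtVennCounts(states)
  priming <- primingSummary(pat)
  fldEff <- fldEffectCounts(states, logFoldChanges(fit))
  say("patterns: %d non-empty clusters, %d primed probes",
      sum(pat$clusters$size > 0), priming$count)

  universe <- rownames(pre$experiment)
  deLists <- list()
  for (k in seq_len(ncol(states))) {
    nm <- colnames(states)[k]
    deLists[[paste0(nm, ".induced")]] <- universe[states[, k] == "U"]
    deLists[[paste0(nm, ".repressed")]] <- universe[states[, k] == "D"]
  }
  enrich <- enrichGeneLists(deLists, annotation, universe, alpha = alpha)
  say("enrichment: %d significant list x bin pairs",
      sum(enrich$significant))

  deCounts <- colSums(states != "N")
  summary <- c(n_probes = length(pre$mask), n_expressed = sum(pre$mask),
               stats::setNames(deCounts, paste0("de_", names(deCounts))),
               stats::setNames(venn$induced,
                               paste0("venn_induced_", names(venn$induced))),
               stats::setNames(venn$repressed,
                               paste0("venn_repressed_",
                                      names(venn$repressed))),
               n_clusters = sum(pat$clusters$size > 0),
               primed = priming$count, fldEff)

  res <- list(experiment = pre$experiment, params = pre$params,
              mask = pre$mask, fit = fit, patterns = pat, venn = venn,
              priming = priming, fldEffect = fldEff, enrichment = enrich,
              annotation = annotation, summary = summary)
  if (!is.null(outDir)) .writePipelineArtifacts(res, fae, outDir)
  res
}

.writePipelineArtifacts <- function(res, fae, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outDir, ...)
  wt <- function(d, f) utils::write.table(d, p(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  writeIntensityTSV(fae, p("intensity_matrix.tsv"), p("design.tsv"))
  writeAnnotationTSV(res$annotation, p("annotation.tsv"))
  for (nm in contrastNames(res$fit))
    wt(contrastTable(res$fit, nm), sprintf("de_%s.tsv", nm))
  wt(res$patterns$assignment, "cluster_membership.tsv")
  wt(res$patterns$clusters, "cluster_sizes.tsv")
  venn <- rbind(data.frame(direction = "induced",
                           t(res$venn$induced)),
                data.frame(direction = "repressed",
                           t(res$venn$repressed)))
  wt(venn, "venn_counts.tsv")
  wt(patternTaxonomyTable(), "pattern_taxonomy_reference.tsv")
  wt(res$enrichment, "enrichment.tsv")
  wt(data.frame(quantity = names(res$summary),
                value = unname(res$summary)), "summary.tsv")
  invisible(outDir)
}
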