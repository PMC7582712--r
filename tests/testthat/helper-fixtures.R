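## shared fixtures, all built in code

## small simulated experiment reused across tests
tinyConfig <- function(nProbes = 800, seed = 101, ...) {
  simulationConfig(nProbes = nProbes, seed = seed, ...)
}

## a raw-scale experiment with hand-set intensities: one value per cell,
## replicated identically within cells
cellValueFae <- function(cellValues, nReps = 2) {
  cells <- c("WT.control", "WT.drought", "Fld.control", "Fld.drought")
  stopifnot(ncol(cellValues) == 4)
  design <- expand.grid(replicate = seq_len(nReps),
                        treatment = c("control", "drought"),
                        genotype = c("WT", "Fld"))[, 3:1]
  cell <- paste(design$genotype, design$treatment, sep = ".")
  m <- cellValues[, match(cell, cells), drop = FALSE]
  colnames(m) <- NULL
  FactorialArrayExperiment(m, design)
}

## a minimal long-format Ct table
ctRow <- function(gene, condition, bio, tech, ct) {
  data.frame(gene = gene, condition = condition, bio_rep = bio,
             tech_rep = tech, ct = ct)
}
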