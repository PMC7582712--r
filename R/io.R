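#' Write / read an intensity matrix with its design table
#'
#' The matrix TSV has a `probe_id` column plus one column per array
#' (header row with sample ids); the design TSV has columns
#' `sample_id`, `genotype`, `treatment`, `replicate`.
#'
#' @param x a [FactorialArrayExperiment-class].
#' @param matrixPath,designPath file paths.
#' @return `writeIntensityTSV` invisibly returns the paths;
#'   `readIntensityTSV` returns a `FactorialArrayExperiment`.
#' @export
writeIntensityTSV <- function(x, matrixPath, designPath) {
  stopifnot(is(x, "FactorialArrayExperiment"))
  m <- assay(x, "intensity")
  utils::write.table(
    data.frame(probe_id = rownames(m), m, check.names = FALSE),
    matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(designTable(x)[, c("sample_id", "genotype",
                                        "treatment", "replicate")],
                     designPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrixPath, designPath))
}

#' @rdname writeIntensityTSV
#' @param scale intensity scale of the stored values.
#' @export
readIntensityTSV <- function(matrixPath, designPath,
                             scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(matrixPath, check.names = FALSE)
  design <- utils::read.delim(designPath)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$probe_id
  FactorialArrayExperiment(m, design, scale = scale)
}

#' Write / read a probe-to-bin annotation table
#'
#' Mirrors the GoMapMan mapping-file structure: tab-separated
#' `probe_id`, `bin_code`, `bin_name`.
#'
#' @param annotation annotation `data.frame`.
#' @param path file path.
#' @export
writeAnnotationTSV <- function(annotation, path) {
  utils::write.table(annotation[, c("probe_id", "bin_code", "bin_name")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAnnotationTSV
#' @export
readAnnotationTSV <- function(path) {
  ann <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("probe_id", "bin_code") %in% colnames(ann)))
  ann
}

#' Parse a GEO series-matrix file
#'
#' Reads the plain-text series-matrix format: metadata lines prefixed
#' `!`, and a probe x sample value block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`.
#'
#' @param path path to an (uncompressed) series-matrix file.
#' @return `list(values, sampleInfo)`: the numeric matrix (probes x
#'   samples, GSM accessions as column names) and a `data.frame` of the
#'   `!Sample_*` metadata fields (one row per sample).
#' @export
readGEOSeriesMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1 || length(end) != 1 || end <= begin + 1)
    stop("no series-matrix table block found")
  tab <- utils::read.delim(text = lines[(begin + 1):(end - 1)],
                           check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  meta <- lines[startsWith(lines, "!Sample_")]
  sampleInfo <- NULL
  if (length(meta)) {
    fields <- lapply(strsplit(meta, "\t"), function(x) gsub("^\"|\"$", "", x))
    keys <- make.unique(sub("^!Sample_", "", vapply(fields, `[`, "", 1)))
    vals <- lapply(fields, `[`, -1)
    keep <- lengths(vals) == ncol(values)
    sampleInfo <- data.frame(stats::setNames(vals[keep], keys[keep]),
                             check.names = FALSE)
    rownames(sampleInfo) <- colnames(values)
  }
  list(values = values, sampleInfo = sampleInfo)
}

#' Convert a parsed GEO series matrix into an experiment object
#'
#' @param geo result of [readGEOSeriesMatrix()].
#' @param design design table (`genotype`, `treatment`, `replicate`,
#'   optional `sample_id` matching the GSM column names).
#' @param scale intensity scale of the stored values (series matrices
#'   typically hold normalized log2 values).
#' @return a [FactorialArrayExperiment-class].
#' @export
geoSeriesToExperiment <- function(geo, design, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  FactorialArrayExperiment(geo$values, design, scale = scale)
}
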