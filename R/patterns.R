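.STATES <- c("U", "D", "N")

.TAXONOMY_LABELS <- c(
  "unaffected", "shared_induced", "shared_repressed",
  "abolished_induction", "ameliorated_induction",
  "abolished_repression", "ameliorated_repression",
  "opposed_fld_up_drought_down",
  "primed_up_saturated", "primed_up_additive",
  "primed_down_saturated", "primed_down_additive",
  "fld_only", "other")

.splitPattern <- function(pattern) {
  if (any(nchar(pattern) != 4) ||
      any(!strsplit(paste(pattern, collapse = ""), "")[[1]] %in% .STATES))
    stop("patterns must be 4-character strings over {U, D, N}")
  do.call(rbind, strsplit(pattern, ""))
}

#' Biological taxonomy of a ternary contrast pattern
#'
#' Maps each 4-symbol pattern over \{U, D, N\} (contrast order C1..C4)
#' to one of 14 mutually exclusive labels encoding the drought/Fld
#' response semantics: unchanged genes; drought responses shared by both
#' genotypes; WT drought responses abolished or ameliorated by Fld; Fld
#' effects opposing the drought response; genes primed by Fld (modulated
#' under control conditions in the same direction as the WT drought
#' response, either already saturated or further shifted by drought);
#' genes responding to Fld only; and a residual class. Rules are applied
#' in fixed precedence (unaffected, primed, opposed, abolished,
#' ameliorated, shared, fld_only, other); ameliorated precedes shared
#' because the two differ exactly in whether the genotypes separate
#' under drought (C2 opposing the drought direction).
#'
#' @param pattern character vector of 4-character patterns, e.g.
#'   `"NNUU"`.
#' @return character vector of taxonomy labels.
#' @examples
#' classifyTaxonomy(c("NNUU", "NNNU", "UNNU", "NDUU"))
#' @export
classifyTaxonomy <- function(pattern) {
  s <- .splitPattern(pattern)
  c1 <- s[, 1]; c2 <- s[, 2]; c3 <- s[, 3]; c4 <- s[, 4]
  out <- rep("other", length(pattern))
  dirLab <- function(x, up, down) ifelse(x == "U", up, down)

  unaff <- c1 == "N" & c2 == "N" & c3 == "N" & c4 == "N"
  primed <- !unaff & c1 != "N" & c4 == c1 & (c3 == "N" | c3 == c4)
  opposed <- !unaff & !primed & c1 != "N" &
    ((c4 != "N" & c4 != c1) | (c3 != "N" & c3 != c1))
  done <- unaff | primed | opposed
  abol <- !done & c1 == "N" & c4 != "N" & c3 == "N"
  done <- done | abol
  amel <- !done & c4 != "N" & c3 == c4 & c2 != "N" & c2 != c4
  done <- done | amel
  shared <- !done & c1 == "N" & c3 == c4 & c3 != "N"
  done <- done | shared
  fldOnly <- !done & (c1 != "N" | c2 != "N") & c3 == "N" & c4 == "N"

  out[unaff] <- "unaffected"
  out[primed] <- paste0("primed_",
                        ifelse(c1[primed] == "U", "up", "down"), "_",
                        ifelse(c3[primed] == "N", "saturated", "additive"))
  out[opposed] <- "opposed_fld_up_drought_down"
  out[abol] <- dirLab(c4[abol], "abolished_induction", "abolished_repression")
  out[amel] <- dirLab(c4[amel], "ameliorated_induction",
                      "ameliorated_repression")
  out[shared] <- dirLab(c3[shared], "shared_induced", "shared_repressed")
  out[fldOnly] <- "fld_only"
  out
}

#' Reference table of all 81 ternary patterns
#'
#' Emits the complete pattern-to-taxonomy mapping as a documentation
#' artifact, so any alternative reading of a cluster's semantics is a
#' one-line change against an explicit table. Opposed patterns carry a
#' note: the motivating study describes two opposed clusters (8 and 9)
#' whose separating symbols are not recoverable from its text, so both
#' map to the single opposed label here.
#'
#' @return `data.frame(pattern, C1, C2, C3, C4, taxonomy, note)` with
#'   exactly 81 rows.
#' @examples
#' tab <- patternTaxonomyTable()
#' table(tab$taxonomy)
#' @export
patternTaxonomyTable <- function() {
  g <- expand.grid(C4 = .STATES, C3 = .STATES, C2 = .STATES, C1 = .STATES,
                   stringsAsFactors = FALSE)[, 4:1]
  pattern <- apply(g, 1, paste, collapse = "")
  o <- order(pattern)
  g <- g[o, , drop = FALSE]; pattern <- pattern[o]
  taxonomy <- classifyTaxonomy(pattern)
  note <- ifelse(taxonomy == "opposed_fld_up_drought_down",
                 "opposed variants are not separated further", "")
  data.frame(pattern = pattern, g, taxonomy = taxonomy, note = note,
             row.names = NULL)
}

#' Group probes by identical ternary contrast patterns
#'
#' Probes sharing the same state call in all four comparisons form one
#' cluster. Cluster ids are dense integers ordered by descending
#' cluster size (ties broken lexicographically on the pattern string);
#' the all-N pattern is always listed, labelled `unaffected`.
#'
#' @param states probes x 4 character matrix over \{U, D, N\} with probe
#'   rownames (e.g. [contrastStates()]).
#' @return `list(assignment, clusters)`: per-probe
#'   `data.frame(probe_id, pattern, cluster_id, taxonomy)` and the
#'   cluster-level `data.frame(cluster_id, pattern, size, taxonomy)`.
#' @examples
#' st <- rbind(a = c("N","N","U","U"), b = c("N","N","U","U"),
#'             c = c("N","N","N","N"))
#' assignPatterns(st)$clusters
#' @export
assignPatterns <- function(states) {
  states <- as.matrix(states)
  if (ncol(states) != 4) stop("state table must have 4 contrast columns")
  if (anyNA(states) || !all(states %in% .STATES))
    stop("missing or invalid state call")
  if (is.null(rownames(states)))
    rownames(states) <- sprintf("probe_%06d", seq_len(nrow(states)))
  pattern <- apply(states, 1, paste, collapse = "")
  sizes <- table(pattern)
  pats <- union(names(sizes), "NNNN")
  size <- as.integer(sizes[pats]); size[is.na(size)] <- 0L
  o <- order(-size, pats)
  clusters <- data.frame(cluster_id = seq_along(o), pattern = pats[o],
                         size = size[o],
                         taxonomy = classifyTaxonomy(pats[o]),
                         row.names = NULL)
  id <- stats::setNames(clusters$cluster_id, clusters$pattern)
  assignment <- data.frame(probe_id = rownames(states), pattern = pattern,
                           cluster_id = as.integer(id[pattern]),
                           taxonomy = clusters$taxonomy[id[pattern]],
                           row.names = NULL)
  list(assignment = assignment, clusters = clusters)
}

#' Venn partition of drought responses between genotypes
#'
#' Counts of probes induced (repressed) by drought in both genotypes,
#' in WT only, or in the Fld genotype only, from the C3 (drought effect
#' in Fld) and C4 (drought effect in WT) state calls.
#'
#' @param states probes x 4 state matrix (contrast order C1..C4).
#' @return `list(induced, repressed)`, each a named integer vector
#'   `(both, wt_only, fld_only)`.
#' @examples
#' st <- rbind(c("N","N","U","U"), c("N","N","N","U"))
#' droughtVennCounts(st)
#' @export
droughtVennCounts <- function(states) {
  states <- as.matrix(states)
  if (ncol(states) != 4) stop("state table must have 4 contrast columns")
  c3 <- states[, 3]; c4 <- states[, 4]
  one <- function(sym) c(both = sum(c4 == sym & c3 == sym),
                         wt_only = sum(c4 == sym & c3 != sym),
                         fld_only = sum(c3 == sym & c4 != sym))
  list(induced = one("U"), repressed = one("D"))
}

#' Summary of primed probes
#'
#' The primed set is the union of the four `primed_*` taxonomy classes:
#' probes whose modulation by Fld under control conditions proceeds in
#' the same direction as their drought response in wild type.
#'
#' @param assignment per-probe assignment from [assignPatterns()]
#'   (element `assignment`, or the list itself).
#' @return `list(count, probes)`.
#' @export
primingSummary <- function(assignment) {
  if (is.list(assignment) && !is.data.frame(assignment))
    assignment <- assignment$assignment
  primed <- startsWith(assignment$taxonomy, "primed_")
  list(count = sum(primed), probes = assignment$probe_id[primed])
}

#' Counts of Fld-responsive genes under control conditions
#'
#' From the C1 contrast (Fld vs WT under control): numbers of induced
#' probes (state U), of those exceeding 4-fold, of repressed probes
#' (state D), and of those below 0.25-fold. The 4-fold sets are nested
#' within the 2-fold sets by construction.
#'
#' @param states probes x 4 state matrix; `lfc` matching log2
#'   fold-change matrix.
#' @return named integer vector `(induced_2x, induced_4x, repressed_2x,
#'   repressed_4x)`.
#' @export
fldEffectCounts <- function(states, lfc) {
  states <- as.matrix(states); lfc <- as.matrix(lfc)
  stopifnot(all(dim(states) == dim(lfc)), ncol(states) == 4)
  u <- states[, 1] == "U"; d <- states[, 1] == "D"
  c(induced_2x = sum(u), induced_4x = sum(u & lfc[, 1] > 2),
    repressed_2x = sum(d), repressed_4x = sum(d & lfc[, 1] < -2))
}
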