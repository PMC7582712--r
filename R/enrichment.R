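#' Ancestor bins of hierarchical MapMan-style codes
#'
#' Dot-separated bin codes imply a hierarchy: `"1.2.3"` has ancestors
#' `"1.2"` and `"1"`.
#'
#' @param code character vector of bin codes.
#' @return list of character vectors of proper ancestors (possibly
#'   empty).
#' @export
binAncestors <- function(code) {
  lapply(strsplit(code, ".", fixed = TRUE), function(parts) {
    k <- length(parts)
    if (k < 2) character()
    else vapply(seq_len(k - 1),
                function(i) paste(parts[seq_len(i)], collapse = "."),
                character(1))
  })
}

#' Close an annotation under the bin hierarchy
#'
#' Adds, for every probe-bin membership, memberships in all ancestor
#' bins, so that a child bin's gene set is always contained in its
#' parent's. Ancestor bin names are derived from the first child seen
#' (name truncated at the last dot) unless already present.
#'
#' @param annotation `data.frame(probe_id, bin_code, bin_name)`.
#' @return expanded, de-duplicated annotation `data.frame`.
#' @examples
#' ann <- data.frame(probe_id = "p1", bin_code = "1.2",
#'                   bin_name = "photosynthesis.2")
#' expandAnnotation(ann)
#' @export
expandAnnotation <- function(annotation) {
  stopifnot(all(c("probe_id", "bin_code") %in% colnames(annotation)))
  if (!"bin_name" %in% colnames(annotation))
    annotation$bin_name <- annotation$bin_code
  anc <- binAncestors(annotation$bin_code)
  nAnc <- lengths(anc)
  extra <- data.frame(
    probe_id = rep(annotation$probe_id, nAnc),
    bin_code = unlist(anc),
    bin_name = rep(sub("\\.[^.]*$", "", annotation$bin_name), nAnc))
  out <- rbind(annotation[, c("probe_id", "bin_code", "bin_name")], extra)
  out <- out[!duplicated(out[, c("probe_id", "bin_code")]), , drop = FALSE]
  out[order(out$probe_id, out$bin_code), , drop = FALSE]
}

#' One-sided Fisher over-representation p-value
#'
#' Upper-tail hypergeometric probability `P(X >= k)` for drawing `k`
#' category members in a list of size `K` from a universe of `N` probes
#' of which `M` belong to the category.
#'
#' @param k,K,M,N contingency values (vectorized); must satisfy
#'   `k <= min(K, M)` and `K, M <= N`.
#' @return p-values.
#' @examples
#' fisherOverRepresentation(3, 4, 4, 8)  # 17/70
#' @export
fisherOverRepresentation <- function(k, K, M, N) {
  if (any(k < 0) || any(k > pmin(K, M)) || any(K > N) || any(M > N))
    stop("invalid contingency table: need k <= min(K, M) and K, M <= N")
  stats::phyper(k - 1, M, N - M, K, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p p-values in [0, 1].
#' @return `min(1, p * length(p))`.
#' @export
bonferroniAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  pmin(1, p * length(p))
}

#' Functional-category over-representation of gene lists
#'
#' PageMan-style one-sided Fisher tests of every hierarchical bin in
#' every gene list against the universe of expressed probes, with
#' Bonferroni control across the bins tested within each list.
#' Annotation is closed under the bin hierarchy first; bins with fewer
#' than `minM` members in the universe are skipped as untestable.
#'
#' @param lists named list of probe-id vectors (e.g. induced and
#'   repressed sets, or clusters), each contained in `universe`.
#' @param annotation `data.frame(probe_id, bin_code, bin_name)`.
#' @param universe character vector of expressed probe ids.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param minM minimum universe category size tested (default 3).
#' @return `data.frame(list, bin_code, bin_name, k, K, M, N, p, p_adj,
#'   significant)` sorted by adjusted p within list.
#' @examples
#' ann <- data.frame(probe_id = c("a", "b", "c"), bin_code = "1.1",
#'                   bin_name = "photosynthesis.1")
#' enrichGeneLists(list(de = c("a", "b")), ann,
#'                 universe = c("a", "b", "c", "d"), minM = 1)
#' @export
enrichGeneLists <- function(lists, annotation, universe, alpha = 0.05,
                            minM = 3) {
  stopifnot(is.list(lists), length(universe) > 0)
  if (is.null(names(lists)) || any(names(lists) == ""))
    names(lists) <- paste0("list", seq_along(lists))
  for (nm in names(lists))
    if (!all(lists[[nm]] %in% universe))
      stop(sprintf("list '%s' is not contained in the universe", nm))
  ann <- expandAnnotation(annotation)
  ann <- ann[ann$probe_id %in% universe, , drop = FALSE]
  N <- length(universe)
  binSize <- table(ann$bin_code)
  testable <- names(binSize)[binSize >= minM]
  binName <- ann$bin_name[match(testable, ann$bin_code)]
  members <- split(ann$probe_id, ann$bin_code)[testable]
  out <- lapply(names(lists), function(nm) {
    lst <- unique(lists[[nm]])
    K <- length(lst)
    if (K == 0 || length(testable) == 0)
      return(NULL)
    k <- vapply(members, function(m) sum(lst %in% m), integer(1))
    M <- as.integer(binSize[testable])
    p <- fisherOverRepresentation(k, K, M, N)
    padj <- bonferroniAdjust(p)
    data.frame(list = nm, bin_code = testable, bin_name = binName,
               k = k, K = K, M = M, N = N, p = p, p_adj = padj,
               significant = padj < alpha, row.names = NULL)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(list = character(), bin_code = character(),
                      bin_name = character(), k = integer(), K = integer(),
                      M = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical())
  out[order(match(out$list, names(lists)), out$p_adj, out$p), , drop = FALSE]
}
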