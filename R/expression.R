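# Tissue/cell-type expression specificity (entropy-based score on a
# cluster-level expression matrix) and Simpson co-expression overlap.

#' Aggregate per-cell expression into a cluster-level matrix
#'
#' Entry (gene, cluster) is the sum of the gene's normalized per-cell
#' expression over the cluster's cells, plus a pseudocount of 1. Empty
#' clusters (factor levels with no cells) get the pseudocount only.
#'
#' @param expr genes x cells numeric matrix of normalized expression.
#' @param clusters cluster assignment per cell (factor or character;
#'   factor levels define the cluster set).
#' @return genes x clusters matrix (all entries >= 1).
#' @export
cluster_expression <- function(expr, clusters) {
  stopifnot(is.matrix(expr), ncol(expr) == length(clusters))
  clusters <- as.factor(clusters)
  sums <- t(rowsum(t(expr), clusters))  # genes x observed clusters
  out <- matrix(0, nrow(expr), nlevels(clusters),
                dimnames = list(rownames(expr), levels(clusters)))
  out[, colnames(sums)] <- sums
  out + 1
}

#' Tissue/cell-type expression specificity score
#'
#' With cluster fractions `f_c = Exp_c / sum(Exp)`, the score is
#' `sum_c f_c * log2(f_c / mean(f))`, i.e. `log2(C) - H(f)` where `H` is the
#' Shannon entropy in bits. It is 0 when expression is identical across all
#' `C` clusters and `log2(C)` when expression is confined to one cluster.
#'
#' @param x a gene's cluster expression vector (from [cluster_expression()];
#'   all entries > 0), or a genes x clusters matrix for the vectorized form.
#' @return numeric score in `[0, log2(C)]` (vector when `x` is a matrix).
#' @export
tcess <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, tcess))
  stopifnot(all(x >= 0), length(x) >= 2)
  C <- length(x)
  if (max(x) == min(x)) return(0)  # identical expression: exactly 0
  f <- x / sum(x)
  pos <- f > 0
  min(max(sum(f[pos] * log2(C * f[pos])), 0), log2(C))
}

#' Clusters in which a gene is considered expressed
#'
#' A gene is expressed in a cluster when its cpm there is strictly greater
#' than `fraction` of its maximum cpm across all clusters.
#'
#' @param cpm_row a gene's cpm values across clusters (pseudocount-free).
#' @param fraction expression threshold as a fraction of the maximum.
#' @return indices (or names, if `cpm_row` is named) of expressed clusters;
#'   empty for an all-zero gene.
#' @export
expressed_clusters <- function(cpm_row, fraction = 0.10) {
  stopifnot(all(cpm_row >= 0))
  mx <- max(cpm_row)
  if (mx == 0) return(if (is.null(names(cpm_row))) integer(0) else character(0))
  idx <- which(cpm_row > fraction * mx)
  if (is.null(names(cpm_row))) idx else names(cpm_row)[idx]
}

#' Simpson co-expression index of two expressed-cluster sets
#'
#' `|A intersect B| / min(|A|, |B|)` — the number of clusters expressing
#' both genes over the number of clusters where the more tissue-specific
#' gene (smaller expressed set) is expressed. Undefined (NA, flagged) when
#' either set is empty.
#'
#' @param set_a,set_b expressed-cluster sets ([expressed_clusters()]).
#' @return list with `simpson` (NA when undefined), `n_shared`, `n_a`,
#'   `n_b`, `defined`.
#' @export
simpson_coexpression <- function(set_a, set_b) {
  n_a <- length(unique(set_a)); n_b <- length(unique(set_b))
  shared <- length(intersect(set_a, set_b))
  if (n_a == 0 || n_b == 0) {
    return(list(simpson = NA_real_, n_shared = shared, n_a = n_a, n_b = n_b,
                defined = FALSE))
  }
  list(simpson = shared / min(n_a, n_b), n_shared = shared,
       n_a = n_a, n_b = n_b, defined = TRUE)
}
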