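## Conditional clustering-quality metrics.
##
## All scores are ratios of Shannon entropies computed from the true-type x
## inferred-cluster contingency table, so the logarithm base cancels; the
## natural log is used throughout, with the convention 0 * log 0 = 0.

entropy_ <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Contingency table of true types against inferred clusters
#'
#' Entry `(c, k)` counts the cells of true type `c` assigned to cluster
#' `k`. Row and column labels are ordered by first appearance in the input
#' vectors, which keeps the table deterministic without imposing an
#' alphabetical order.
#'
#' @param true_labels,pred_labels Equal-length label vectors.
#' @return An integer matrix with row names the true types and column names
#'   the clusters, of class `contingency`.
#' @export
contingency <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop_("label vectors have different lengths (", length(true_labels),
          " vs ", length(pred_labels), ")")
  if (length(true_labels) == 0L) stop_("need at least one cell")
  tab <- table(factor(true_labels, levels = unique(as.character(true_labels))),
               factor(pred_labels, levels = unique(as.character(pred_labels))))
  out <- unclass(as.matrix(tab))
  names(dimnames(out)) <- NULL
  class(out) <- c("contingency", class(out))
  out
}

as_contingency <- function(A) {
  if (inherits(A, "contingency")) return(A)
  A <- as.matrix(A)
  if (!is.numeric(A) || any(A < 0) || any(A != round(A)))
    stop_("'A' must be a matrix of non-negative integer counts")
  if (sum(A) == 0) stop_("contingency table is empty")
  if (is.null(rownames(A))) rownames(A) <- seq_len(nrow(A))
  if (is.null(colnames(A))) colnames(A) <- seq_len(ncol(A))
  A
}

resolve_level <- function(A, level, margin) {
  labs <- dimnames(A)[[margin]]
  if (is.character(level)) {
    i <- match(level, labs)
    if (is.na(i)) stop_("unknown ", c("type", "cluster")[margin], ": ", level)
    return(i)
  }
  i <- as.integer(level)
  if (i < 1L || i > dim(A)[margin]) stop_("index out of range: ", level)
  i
}

#' Conditional entropy of the cluster assignment within one cell type
#'
#' `H(K | C = c)`: the Shannon entropy of the distribution of cells of the
#' focal type `c` across the inferred clusters, using the focal row's total
#' as the normalizer. Zero when the type occupies a single cluster.
#'
#' @param A A [contingency()] table (or plain count matrix).
#' @param type Row label or index of the focal cell type.
#' @return Non-negative entropy (nats).
#' @export
h_clusters_given_type <- function(A, type) {
  A <- as_contingency(A)
  i <- resolve_level(A, type, 1L)
  row <- A[i, ]
  if (sum(row) == 0) stop_("cell type '", rownames(A)[i], "' has no cells")
  entropy_(row)
}

#' Conditional entropy of the true types within one cluster
#'
#' `H(C | K = k)`: the Shannon entropy of the true-type composition of
#' cluster `k`, using the focal column's total as the normalizer. Zero for
#' a pure cluster.
#'
#' @param A A [contingency()] table (or plain count matrix).
#' @param cluster Column label or index of the focal cluster.
#' @return Non-negative entropy (nats).
#' @export
h_types_given_cluster <- function(A, cluster) {
  A <- as_contingency(A)
  j <- resolve_level(A, cluster, 2L)
  col <- A[, j]
  if (sum(col) == 0) stop_("cluster '", colnames(A)[j], "' is empty")
  entropy_(col)
}

#' Marginal entropies of the type and cluster distributions
#'
#' @param A A [contingency()] table (or plain count matrix).
#' @return Named numeric vector `c(H_types, H_clusters)` (nats).
#' @export
marginal_entropies <- function(A) {
  A <- as_contingency(A)
  c(H_types = entropy_(rowSums(A)), H_clusters = entropy_(colSums(A)))
}

#' Conditional homogeneity, completeness and V-measure for a focal type
#'
#' Clustering quality "zoomed in" on one (typically rare) cell type rather
#' than averaged over all of them:
#' \describe{
#'   \item{conditional completeness}{`1 - H(K | C = c) / H(K)` — 1 when all
#'     cells of the focal type sit in a single cluster.}
#'   \item{conditional homogeneity}{`1 - H(C | K = k*) / H(C)` with
#'     `k* = argmax_k a_ck` the focal type's modal cluster (ties broken by
#'     the smallest column index) — 1 when that cluster is pure.}
#'   \item{conditional V-measure}{the harmonic mean of the two, defined as
#'     0 if either score is 0.}
#' }
#' If a normalizer `H(K)` or `H(C)` is zero (a single cluster, or a single
#' type), the corresponding score is defined as 1, matching the limit
#' convention of the classical V-measure. Because `H(K | C = c)` can exceed
#' `H(K)` in unbalanced tables, scores are clipped to \[0, 1\].
#'
#' @param A A [contingency()] table (or plain count matrix), or a vector of
#'   true labels if `pred` is supplied.
#' @param type Row label or index of the focal cell type.
#' @param pred Optional vector of predicted labels; when given, `A` is
#'   interpreted as the true labels and the table is built internally.
#' @return An object of class `conditional_scores`: a list with
#'   `completeness`, `homogeneity`, `v_measure`, `focal_type` and
#'   `modal_cluster`.
#' @examples
#' A <- contingency(rep(c("a", "b"), c(4, 2)), rep(c(1, 2), c(4, 2)))
#' conditional_scores(A, "a")
#' @export
conditional_scores <- function(A, type, pred = NULL) {
  if (!is.null(pred)) A <- contingency(A, pred)
  A <- as_contingency(A)
  i <- resolve_level(A, type, 1L)
  if (sum(A[i, ]) == 0)
    stop_("cell type '", rownames(A)[i], "' has no cells")
  H <- marginal_entropies(A)
  kstar <- which.max(A[i, ])  # which.max takes the first (smallest) index
  comp <- if (H[["H_clusters"]] == 0) 1 else
    1 - h_clusters_given_type(A, i) / H[["H_clusters"]]
  hom <- if (H[["H_types"]] == 0) 1 else
    1 - h_types_given_cluster(A, kstar) / H[["H_types"]]
  comp <- min(max(comp, 0), 1)
  hom <- min(max(hom, 0), 1)
  v <- if (comp == 0 || hom == 0) 0 else 2 * comp * hom / (comp + hom)
  structure(list(completeness = comp, homogeneity = hom, v_measure = v,
                 focal_type = rownames(A)[i],
                 modal_cluster = colnames(A)[kstar]),
            class = "conditional_scores")
}

#' @export
print.conditional_scores <- function(x, ...) {
  cat(sprintf(paste0("Conditional scores for type '%s' ",
                     "(modal cluster '%s'):\n"),
              x$focal_type, x$modal_cluster))
  cat(sprintf("  completeness %.4f  homogeneity %.4f  V-measure %.4f\n",
              x$completeness, x$homogeneity, x$v_measure))
  invisible(x)
}

#' Classical (unconditional) V-measure
#'
#' The standard homogeneity/completeness/V-measure of a clustering against
#' reference labels, provided for comparison alongside the conditional
#' scores: homogeneity `1 - H(C|K)/H(C)`, completeness `1 - H(K|C)/H(K)`,
#' and their harmonic mean, with a degenerate normalizer giving a score of
#' 1.
#'
#' @param A A [contingency()] table (or plain count matrix), or a vector of
#'   true labels if `pred` is supplied.
#' @param pred Optional vector of predicted labels (see
#'   [conditional_scores()]).
#' @return Named numeric vector `c(homogeneity, completeness, v_measure)`.
#' @export
v_measure <- function(A, pred = NULL) {
  if (!is.null(pred)) A <- contingency(A, pred)
  A <- as_contingency(A)
  N <- sum(A)
  H <- marginal_entropies(A)
  ## H(C|K) = sum_k p(k) H(C | K = k), and symmetrically
  HCgK <- sum(vapply(seq_len(ncol(A)), function(j)
    if (sum(A[, j]) == 0) 0 else sum(A[, j]) / N * entropy_(A[, j]),
    numeric(1)))
  HKgC <- sum(vapply(seq_len(nrow(A)), function(i)
    if (sum(A[i, ]) == 0) 0 else sum(A[i, ]) / N * entropy_(A[i, ]),
    numeric(1)))
  hom <- if (H[["H_types"]] == 0) 1 else 1 - HCgK / H[["H_types"]]
  comp <- if (H[["H_clusters"]] == 0) 1 else 1 - HKgC / H[["H_clusters"]]
  v <- if (hom + comp == 0) 0 else 2 * hom * comp / (hom + comp)
  c(homogeneity = hom, completeness = comp, v_measure = v)
}
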