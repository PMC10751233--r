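#' Group cells by identical binary signatures
#'
#' Every cell with the same binary on/off signature across the markers is
#' assigned to the same cluster, so the cluster space has at most `2^P`
#' members and only observed signatures become clusters. Cluster ids are
#' consecutive integers assigned deterministically: decreasing cluster
#' size, ties broken by lexicographic signature order.
#'
#' @param signatures Cells x markers 0/1 matrix (e.g. from
#'   [predict.rarity()] with `type = "signature"` or from [binarize()]).
#'   Row names are used as cell ids; column names as marker names.
#' @param min_size Optional minimum cluster size. Cells in clusters smaller
#'   than this are marked unassigned (`NA` cluster id) rather than merged,
#'   preserving the one-signature-per-cluster guarantee.
#' @return An object of class `signature_clusters`: a list with
#'   `cluster` (integer vector, one id per cell, named by cell id; `NA` for
#'   unassigned), `signatures` (K x P 0/1 matrix, row `k` is the signature
#'   of cluster `k`), and `sizes` (integer vector of cluster sizes).
#' @export
assign_clusters <- function(signatures, min_size = 0L) {
  S <- signatures
  if (is.data.frame(S)) S <- as.matrix(S)
  if (!is.matrix(S) || !all(S %in% c(0L, 1L)))
    stop_("'signatures' must be a 0/1 matrix")
  storage.mode(S) <- "integer"
  if (is.null(rownames(S))) rownames(S) <- sprintf("cell_%05d",
                                                   seq_len(nrow(S)))
  if (is.null(colnames(S))) colnames(S) <- paste0("M", seq_len(ncol(S)))
  key <- apply(S, 1L, paste0, collapse = "")
  tab <- table(key)
  ## order: size decreasing, then lexicographic signature string
  ord <- order(-as.integer(tab), names(tab))
  keys <- names(tab)[ord]
  ids <- stats::setNames(seq_along(keys), keys)
  cluster <- ids[key]
  names(cluster) <- rownames(S)
  sig <- do.call(rbind, lapply(strsplit(keys, ""), as.integer))
  dimnames(sig) <- list(seq_along(keys), colnames(S))
  sizes <- as.integer(tab[keys])
  names(sizes) <- seq_along(keys)
  if (min_size > 0L) {
    drop <- which(sizes < min_size)
    if (length(drop)) cluster[cluster %in% drop] <- NA_integer_
  }
  structure(list(cluster = cluster, signatures = sig, sizes = sizes,
                 min_size = as.integer(min_size)),
            class = "signature_clusters")
}

#' @export
print.signature_clusters <- function(x, n = 10L, ...) {
  k <- nrow(x$signatures)
  cat(sprintf("<signature_clusters> %d cells in %d clusters (P = %d)\n",
              length(x$cluster), k, ncol(x$signatures)))
  show <- utils::head(seq_len(k), n)
  df <- data.frame(cluster = show, size = x$sizes[show],
                   signature = apply(x$signatures[show, , drop = FALSE], 1L,
                                     paste0, collapse = ""),
                   row.names = NULL)
  print(df)
  if (k > n) cat("  ... and", k - n, "more clusters\n")
  invisible(x)
}

#' Hamming distance between two binary signatures
#'
#' @param a,b Binary vectors of equal length.
#' @return The number of positions at which they differ.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b))
    stop_("signatures have different lengths (", length(a), " vs ",
          length(b), ")")
  sum(a != b)
}

#' Query all observed clusters within a Hamming ball
#'
#' Retrieves every observed cluster whose signature differs from the
#' reference signature in at most `radius` markers. With radius 0 this
#' finds the exact-match cluster (if observed); with radius P it returns
#' every cluster. Useful for interactive exploration: e.g. starting from a
#' CD45-only reference, radius 1 additionally retrieves signatures that
#' co-express one further marker such as CD68 (macrophages).
#'
#' @param assignment A [assign_clusters()] object.
#' @param reference Binary reference signature of length P; may be named by
#'   marker, in which case it is aligned to the assignment's marker order.
#' @param radius Non-negative integer Hamming radius, at most P.
#' @return A data frame with one row per matching cluster: `cluster`,
#'   `distance`, `size`, `signature` (as a compact 0/1 string), sorted by
#'   distance then decreasing size. The matching signature matrix is
#'   attached as attribute `"signatures"`.
#' @export
hamming_ball_query <- function(assignment, reference, radius = 1L) {
  stopifnot(inherits(assignment, "signature_clusters"))
  P <- ncol(assignment$signatures)
  if (!is.null(names(reference))) {
    if (!setequal(names(reference), colnames(assignment$signatures)))
      stop_("reference marker names do not match the assignment")
    reference <- reference[colnames(assignment$signatures)]
  }
  if (length(reference) != P)
    stop_("'reference' must have length ", P)
  if (radius < 0L || radius > P)
    stop_("'radius' must be between 0 and ", P)
  d <- colSums(t(assignment$signatures) != as.numeric(reference))
  keep <- which(d <= radius)
  ord <- keep[order(d[keep], -assignment$sizes[keep])]
  out <- data.frame(cluster = as.integer(ord),
                    distance = as.integer(d[ord]),
                    size = as.integer(assignment$sizes[ord]),
                    signature = apply(assignment$signatures[ord, ,
                                                            drop = FALSE],
                                      1L, paste0, collapse = ""),
                    row.names = NULL)
  attr(out, "signatures") <- assignment$signatures[ord, , drop = FALSE]
  out
}

#' Build a marker on/off constraint
#'
#' A constraint requires selected markers to be "on", others to be "off",
#' and leaves the rest unconstrained ("any"). Markers are referenced by
#' name so constraints are robust to panel column order.
#'
#' @param markers Character vector of all marker names (length P).
#' @param on,off Character vectors of marker names required to be
#'   expressed / not expressed; must be disjoint subsets of `markers`.
#' @return A character vector of length P over `{"on", "off", "any"}`,
#'   named by marker, of class `marker_constraint`.
#' @export
marker_constraint <- function(markers, on = character(), off = character()) {
  unknown <- setdiff(c(on, off), markers)
  if (length(unknown))
    stop_("unknown marker(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(on, off)))
    stop_("markers cannot be both on and off: ",
          paste(intersect(on, off), collapse = ", "))
  cons <- stats::setNames(rep("any", length(markers)), markers)
  cons[on] <- "on"
  cons[off] <- "off"
  class(cons) <- "marker_constraint"
  cons
}

constraint_matches <- function(signatures, constraint) {
  cons <- unclass(constraint)
  if (!setequal(names(cons), colnames(signatures)))
    stop_("constraint marker names do not match the signature matrix")
  cons <- cons[colnames(signatures)]
  ok <- rep(TRUE, nrow(signatures))
  for (j in seq_along(cons)) {
    if (cons[j] == "on") ok <- ok & signatures[, j] == 1L
    if (cons[j] == "off") ok <- ok & signatures[, j] == 0L
  }
  ok
}

#' Select cells whose cluster signature satisfies a marker constraint
#'
#' Gating on inferred signatures: returns all cells belonging to any
#' cluster whose binary signature has the required markers on and the
#' forbidden markers off; "any" positions are unconstrained. This is how
#' known cell types are interrogated, e.g. selecting epithelial cells as
#' E-cadherin+/pan-cytokeratin+/CD45-.
#'
#' @param assignment A [assign_clusters()] object.
#' @param constraint A [marker_constraint()].
#' @return Character vector of cell ids (possibly empty).
#' @export
select_cells <- function(assignment, constraint) {
  stopifnot(inherits(assignment, "signature_clusters"),
            inherits(constraint, "marker_constraint"))
  hit <- which(constraint_matches(assignment$signatures, constraint))
  names(assignment$cluster)[assignment$cluster %in% hit]
}

#' Refine a selection by splitting on one additional marker
#'
#' Partitions the cells selected by a base constraint according to the
#' on/off state of one further marker that the base constraint leaves
#' unconstrained. The two parts are disjoint and their union is exactly the
#' base selection.
#'
#' @param assignment A [assign_clusters()] object.
#' @param constraint Base [marker_constraint()].
#' @param split_marker Name of a marker whose base requirement is "any".
#' @return A list with components `on` and `off`, each a character vector
#'   of cell ids.
#' @export
refine_selection <- function(assignment, constraint, split_marker) {
  stopifnot(inherits(constraint, "marker_constraint"))
  if (!split_marker %in% names(constraint))
    stop_("unknown marker: ", split_marker)
  if (constraint[[split_marker]] != "any")
    stop_("'", split_marker, "' is already constrained to ",
          constraint[[split_marker]])
  markers <- names(constraint)
  on_c <- marker_constraint(markers, on = c(markers[constraint == "on"],
                                            split_marker),
                            off = markers[constraint == "off"])
  off_c <- marker_constraint(markers, on = markers[constraint == "on"],
                             off = c(markers[constraint == "off"],
                                     split_marker))
  list(on = select_cells(assignment, on_c),
       off = select_cells(assignment, off_c))
}

#' Per-cluster intensity summaries
#'
#' One row per cluster with its size, signature, and per-marker mean and
#' median observed intensities — the table behind cluster heatmaps and
#' boxplots used to verify that inferred signatures track the actual
#' intensity levels.
#'
#' @param assignment A [assign_clusters()] object.
#' @param x The cells x markers intensity matrix (or `cell_dataset`) the
#'   assignment was derived from; rows are matched to cells by id.
#' @return A data frame with columns `cluster`, `size`, `signature`,
#'   `mean.<marker>` and `median.<marker>` for every marker.
#' @export
cluster_summary <- function(assignment, x) {
  stopifnot(inherits(assignment, "signature_clusters"))
  X <- as_intensity_matrix(x)
  cells <- names(assignment$cluster)
  if (!all(cells %in% rownames(X)))
    stop_("intensity matrix does not contain all assigned cells")
  X <- X[cells, , drop = FALSE]
  if (!identical(colnames(X), colnames(assignment$signatures)))
    X <- X[, colnames(assignment$signatures), drop = FALSE]
  ks <- seq_len(nrow(assignment$signatures))
  mstat <- function(f) t(vapply(ks, function(k)
    apply(X[assignment$cluster == k, , drop = FALSE], 2L, f),
    numeric(ncol(X))))
  mu <- mstat(mean)
  md <- mstat(stats::median)
  colnames(mu) <- paste0("mean.", colnames(X))
  colnames(md) <- paste0("median.", colnames(X))
  data.frame(cluster = ks, size = as.integer(assignment$sizes[ks]),
             signature = apply(assignment$signatures, 1L, paste0,
                               collapse = ""),
             mu, md, row.names = NULL, check.names = FALSE)
}
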