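## Downsampling self-consistency harness.
##
## Protocol: cluster the full dataset; pick a focal cluster; downsample it;
## recluster the reduced dataset with the same method; score the new
## clustering against the original labels restricted to the retained cells,
## conditioning the metrics on the focal cluster. A self-consistent method
## reproduces its own full-data assignment regardless of cluster prevalence.

#' Wrap a clustering function as a benchmark backend
#'
#' A backend is any function `f(x, seed)` returning one cluster label per
#' row of `x` (named by row ids when available). The harness treats
#' backends as opaque, so external methods can be plugged in as adapters.
#' A backend may attach a `"signatures"` attribute to its labels (a
#' clusters x markers 0/1 matrix with row names the cluster labels) to
#' support focal-cluster selection by marker constraint.
#'
#' @param fn The clustering function.
#' @param name Display name.
#' @return The function with class `clustering_backend`.
#' @export
clustering_backend <- function(fn, name) {
  stopifnot(is.function(fn))
  structure(fn, name = name, class = c("clustering_backend", "function"))
}

#' @export
print.clustering_backend <- function(x, ...) {
  cat("<clustering_backend>", attr(x, "name"), "\n")
  invisible(x)
}

#' Backend: binary latent signature clustering
#'
#' Fits the [rarity()] model to the data and labels each cell by its
#' signature cluster; labels carry the cluster signature matrix so focal
#' clusters can be selected by [marker_constraint()].
#'
#' @param ... Arguments passed on to [rarity()] (epochs, hidden, ...);
#'   `seed` is supplied by the harness.
#' @return A `clustering_backend`.
#' @export
backend_rarity <- function(...) {
  args <- list(...)
  clustering_backend(function(x, seed = 1L) {
    fit <- do.call(rarity, c(list(x = x, seed = seed), args))
    cl <- predict(fit, x, type = "cluster")
    labels <- apply(cl$signatures[cl$cluster, , drop = FALSE], 1L,
                    paste0, collapse = "")
    names(labels) <- names(cl$cluster)
    sig <- cl$signatures
    rownames(sig) <- apply(sig, 1L, paste0, collapse = "")
    attr(labels, "signatures") <- sig
    labels
  }, name = "rarity")
}

#' Backend: replay stored labels (identity oracle)
#'
#' Always returns the stored labels for whichever cells are present in the
#' input. By construction it reproduces itself perfectly after any
#' downsampling, which makes it the harness self-test: every conditional
#' score must equal 1.
#'
#' @param labels Named label vector covering all cells that may appear.
#' @return A `clustering_backend`.
#' @export
backend_identity <- function(labels) {
  if (is.null(names(labels))) stop_("'labels' must be named by cell id")
  force(labels)
  clustering_backend(function(x, seed = 1L) {
    X <- as_intensity_matrix(x)
    if (!all(rownames(X) %in% names(labels)))
      stop_("stored labels do not cover all cells")
    labels[rownames(X)]
  }, name = "identity")
}

#' Backend: constant single-cluster labeler
#'
#' Assigns every cell to one cluster. Maximally complete, minimally
#' homogeneous; useful as a degenerate control.
#'
#' @return A `clustering_backend`.
#' @export
backend_constant <- function() {
  clustering_backend(function(x, seed = 1L) {
    X <- as_intensity_matrix(x)
    stats::setNames(rep("all", nrow(X)), rownames(X))
  }, name = "constant")
}

#' Backend: k-means adapter
#'
#' Demonstrates the adapter contract for conventional centroid clustering
#' via [stats::kmeans()].
#'
#' @param k Number of centres.
#' @param nstart Restarts per fit.
#' @return A `clustering_backend`.
#' @export
backend_kmeans <- function(k, nstart = 5L) {
  clustering_backend(function(x, seed = 1L) {
    X <- as_intensity_matrix(x)
    km <- local_seed(seed, stats::kmeans(X, centers = k, nstart = nstart))
    stats::setNames(as.character(km$cluster), rownames(X))
  }, name = sprintf("kmeans(k=%d)", k))
}

## Resolve the focal cluster: explicit label, or the largest cluster whose
## signature satisfies a marker constraint. Backends without signatures get
## a pseudo-signature from cluster mean intensities thresholded halfway
## between the pooled 10th and 90th intensity percentiles.
resolve_focal <- function(labels, X, focal) {
  if (!inherits(focal, "marker_constraint")) {
    focal <- as.character(focal)
    if (!focal %in% labels)
      stop_("focal cluster '", focal, "' not found in the clustering")
    return(focal)
  }
  sig <- attr(labels, "signatures")
  if (is.null(sig)) {
    mid <- mean(stats::quantile(X, c(0.10, 0.90)))
    levs <- unique(labels)
    sig <- t(vapply(levs, function(l)
      as.integer(colMeans(X[labels == l, , drop = FALSE]) > mid),
      integer(ncol(X))))
    dimnames(sig) <- list(levs, colnames(X))
  }
  hit <- rownames(sig)[constraint_matches(sig, focal)]
  hit <- hit[hit %in% labels]
  if (!length(hit)) stop_("no cluster satisfies the focal marker constraint")
  sizes <- table(labels)[hit]
  names(which.max(sizes))
}

#' One downsampling self-consistency experiment
#'
#' Runs `backend` on the full data, downsamples the focal cluster to
#' `n_keep` cells, reruns the backend on the reduced data, and scores the
#' new clustering against the original labels restricted to the retained
#' cells with [conditional_scores()], conditioning on the focal cluster.
#' By default the original full-data labels act as the reference partition
#' (self-consistency); pass `truth` to score against external ground-truth
#' labels instead.
#'
#' @param x Cells x markers matrix or `cell_dataset`.
#' @param backend A [clustering_backend()].
#' @param focal Either an explicit cluster label of the full-data
#'   clustering or a [marker_constraint()]; a constraint selects the
#'   largest matching cluster.
#' @param n_keep Number of focal-cluster cells to retain.
#' @param seed Integer seed; seeds the backend runs and the downsampling.
#' @param truth Optional named vector of reference labels; when given, the
#'   scores compare the reduced-data clustering against `truth` (restricted
#'   to retained cells) and the focal type is `truth_focal`.
#' @param truth_focal Focal label within `truth` (required with `truth`).
#' @return An object of class `self_consistency`: list with `scores`
#'   (a [conditional_scores()] object), `original_labels`,
#'   `downsampled_labels`, `retained_cells`, `focal_cluster`, `n_keep`,
#'   `backend`, `seed`.
#' @export
self_consistency <- function(x, backend, focal, n_keep, seed = 1L,
                             truth = NULL, truth_focal = NULL) {
  stopifnot(inherits(backend, "clustering_backend"))
  X <- as_intensity_matrix(x)
  n_keep <- as.integer(n_keep)
  orig <- backend(X, seed = seed)
  if (length(orig) != nrow(X))
    stop_("backend returned ", length(orig), " labels for ", nrow(X),
          " cells")
  if (is.null(names(orig))) names(orig) <- rownames(X)
  focal_cluster <- resolve_focal(orig, X, focal)
  members <- which(orig == focal_cluster)
  if (n_keep > length(members))
    stop_("'n_keep' (", n_keep, ") exceeds focal cluster size (",
          length(members), ")")
  kept <- local_seed(seed + 1L, sample(members, n_keep))
  keep <- sort(c(setdiff(seq_len(nrow(X)), members), kept))
  Xr <- X[keep, , drop = FALSE]
  new <- backend(Xr, seed = seed + 2L)
  if (is.null(names(new))) names(new) <- rownames(Xr)
  if (is.null(truth)) {
    ref <- orig[rownames(Xr)]
    focal_type <- focal_cluster
  } else {
    if (is.null(truth_focal)) stop_("'truth_focal' required with 'truth'")
    ref <- truth[rownames(Xr)]
    focal_type <- truth_focal
  }
  scores <- conditional_scores(contingency(ref, new[rownames(Xr)]),
                               focal_type)
  structure(list(scores = scores, original_labels = orig,
                 downsampled_labels = new, retained_cells = rownames(Xr),
                 focal_cluster = focal_cluster, n_keep = n_keep,
                 backend = attr(backend, "name"), seed = as.integer(seed)),
            class = "self_consistency")
}

#' @export
print.self_consistency <- function(x, ...) {
  cat(sprintf(paste0("<self_consistency> backend %s, focal '%s' ",
                     "downsampled to %d cells (seed %d)\n"),
              x$backend, x$focal_cluster, x$n_keep, x$seed))
  print(x$scores)
  invisible(x)
}

#' Factorial sweep of self-consistency experiments
#'
#' Runs [self_consistency()] over the full factorial of backends, retained
#' cell counts and seeds, collecting scores in a tidy table. Failures of
#' individual cells of the factorial are recorded per row and do not abort
#' the sweep.
#'
#' @param x Data as in [self_consistency()].
#' @param backends Named list of [clustering_backend()] objects.
#' @param n_keep Integer vector of retained cell counts.
#' @param seeds Integer vector of seeds.
#' @param focal Focal cluster specifier passed through.
#' @param truth,truth_focal Optional ground-truth reference, passed through.
#' @return A data frame with one row per (backend, n_keep, seed):
#'   `backend`, `n_keep`, `seed`, `focal`, `completeness`, `homogeneity`,
#'   `v_measure`, `error` (NA on success).
#' @export
self_consistency_sweep <- function(x, backends, n_keep, seeds, focal,
                                   truth = NULL, truth_focal = NULL) {
  if (inherits(backends, "clustering_backend")) backends <- list(backends)
  if (is.null(names(backends)))
    names(backends) <- vapply(backends, attr, character(1), "name")
  grid <- expand.grid(backend = names(backends), n_keep = n_keep,
                      seed = seeds, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    g <- grid[r, ]
    res <- tryCatch(
      self_consistency(x, backends[[g$backend]], focal, g$n_keep, g$seed,
                       truth = truth, truth_focal = truth_focal),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(g, focal = NA_character_, completeness = NA_real_,
                 homogeneity = NA_real_, v_measure = NA_real_,
                 error = conditionMessage(res))
    else
      data.frame(g, focal = res$focal_cluster,
                 completeness = res$scores$completeness,
                 homogeneity = res$scores$homogeneity,
                 v_measure = res$scores$v_measure, error = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flow table between two clusterings
#'
#' The cell flows underlying alluvial diagrams: one row per (original
#' cluster, new cluster) pair with the number of shared cells, plus the
#' number of distinct original parents of each new cluster as an attribute
#' (`"parents"`).
#'
#' @param original,new Equal-length label vectors over the same cells.
#' @return A data frame `original`, `new`, `cells`, sorted by decreasing
#'   flow; `attr(, "parents")` is a named integer vector giving, for each
#'   new cluster, how many original clusters flow into it.
#' @export
cluster_mapping_table <- function(original, new) {
  if (length(original) != length(new))
    stop_("label vectors have different lengths")
  A <- contingency(original, new)
  idx <- which(A > 0, arr.ind = TRUE)
  out <- data.frame(original = rownames(A)[idx[, 1]],
                    new = colnames(A)[idx[, 2]],
                    cells = A[idx], row.names = NULL)
  out <- out[order(-out$cells), , drop = FALSE]
  rownames(out) <- NULL
  parents <- apply(A > 0, 2L, sum)
  attr(out, "parents") <- parents
  out
}
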