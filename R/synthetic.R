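#' Cell type specification for the synthetic generator
#'
#' A cell type is defined by a binary on/off signature over the marker panel
#' and the number of cells to simulate.
#'
#' @param name Short unique label for the cell type.
#' @param signature Numeric or integer vector of 0/1 on/off indicators, one
#'   entry per marker.
#' @param count Non-negative integer number of cells to generate.
#' @return An object of class `cell_type_spec`.
#' @seealso [simulate_cells()], [reference_cell_types()]
#' @export
cell_type_spec <- function(name, signature, count) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_("'name' must be a non-empty string")
  signature <- as.numeric(signature)
  if (length(signature) < 1L || !all(signature %in% c(0, 1)))
    stop_("'signature' must be a vector of 0/1 indicators")
  count <- as.integer(count)
  if (length(count) != 1L || is.na(count) || count < 0L)
    stop_("'count' must be a non-negative integer")
  structure(list(name = name, signature = signature, count = count),
            class = "cell_type_spec")
}

#' @export
print.cell_type_spec <- function(x, ...) {
  cat(sprintf("<cell_type_spec> %s: (%s), %d cells\n",
              x$name, paste(x$signature, collapse = ","), x$count))
  invisible(x)
}

#' Parameters of the two-state Gaussian intensity model
#'
#' Marker intensities are drawn from `N(mean_on, sd_on^2)` where a marker is
#' "on" in the cell's signature and `N(mean_off, sd_off^2)` where it is
#' "off". Defaults reproduce the calibration used throughout the package's
#' simulation experiments: intensities live on a roughly \[0, 1\]
#' percentile-normalized scale, with expressed markers centred at 0.5 and
#' background at 0.05.
#'
#' @param mean_on,mean_off Component means; `mean_on > mean_off` is required
#'   so the two states are separable.
#' @param sd_on,sd_off Positive component standard deviations.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(mean_on = 0.5, mean_off = 0.05,
                              sd_on = 0.18, sd_off = 0.03) {
  if (sd_on <= 0 || sd_off <= 0) stop_("standard deviations must be positive")
  if (mean_on <= mean_off) stop_("'mean_on' must exceed 'mean_off'")
  structure(list(mean_on = mean_on, mean_off = mean_off,
                 sd_on = sd_on, sd_off = sd_off),
            class = "generative_params")
}

#' Reference five-population simulation design
#'
#' The fixed simulation design used for all calibration experiments: five
#' cell types (A-E) over a panel of seven markers, three common populations
#' and two rare ones. Types D and E differ from the common types in only one
#' or two markers, which is what makes them hard for conventional clustering.
#'
#' The signatures are
#' \preformatted{
#'   A = (1,1,1,1,0,0,0)  4000 cells
#'   B = (1,1,1,0,1,0,0)  3000 cells
#'   C = (1,1,1,1,0,1,0)  1000 cells
#'   D = (1,1,1,0,0,0,0)    60 cells
#'   E = (1,1,0,0,0,0,0)    40 cells
#' }
#'
#' @return A list of [cell_type_spec()] objects.
#' @export
reference_cell_types <- function() {
  sig <- list(A = c(1, 1, 1, 1, 0, 0, 0),
              B = c(1, 1, 1, 0, 1, 0, 0),
              C = c(1, 1, 1, 1, 0, 1, 0),
              D = c(1, 1, 1, 0, 0, 0, 0),
              E = c(1, 1, 0, 0, 0, 0, 0))
  n <- c(A = 4000L, B = 3000L, C = 1000L, D = 60L, E = 40L)
  mapply(cell_type_spec, names(sig), sig, n, SIMPLIFY = FALSE)
}

validate_specs <- function(specs) {
  if (!is.list(specs) || length(specs) == 0L)
    stop_("'specs' must be a non-empty list of cell_type_spec objects")
  if (!all(vapply(specs, inherits, logical(1), "cell_type_spec")))
    stop_("all elements of 'specs' must be cell_type_spec objects")
  P <- unique(vapply(specs, function(s) length(s$signature), integer(1)))
  if (length(P) != 1L)
    stop_("all signatures must share the same length (got lengths ",
          paste(P, collapse = ", "), ")")
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop_("cell type names must be unique")
  names(specs) <- nms
  specs
}

#' Simulate a labeled marker-intensity dataset
#'
#' Draws, for every cell type spec, `count` cells whose per-marker
#' intensities are independent Gaussians selected by the type's binary
#' signature: `N(mean_on, sd_on^2)` for "on" markers and
#' `N(mean_off, sd_off^2)` for "off" markers. Rows are generated per type
#' and then shuffled (with the same seed) so that row order carries no type
#' information. Sampled intensities are not clipped; values slightly below
#' zero are a property of the Gaussian model and downstream code tolerates
#' them.
#'
#' @param specs List of [cell_type_spec()] objects sharing one marker count.
#' @param params A [generative_params()] object.
#' @param seed Integer seed; the dataset is reproducible given the seed.
#' @param marker_names Optional marker names; defaults to `M1...MP`.
#' @return An object of class `cell_dataset`: a list with elements `X`
#'   (cells x markers numeric matrix with cell ids and marker names),
#'   `labels` (character vector of true type names), `specs`, `params`,
#'   `seed`.
#' @examples
#' d <- simulate_cells(list(cell_type_spec("T", c(1, 0), 5)), seed = 1)
#' dim(d$X)
#' @export
simulate_cells <- function(specs, params = generative_params(), seed = 1L,
                           marker_names = NULL) {
  specs <- validate_specs(specs)
  stopifnot(inherits(params, "generative_params"))
  P <- length(specs[[1]]$signature)
  marker_names <- marker_names %||% paste0("M", seq_len(P))
  if (length(marker_names) != P) stop_("'marker_names' must have length ", P)
  counts <- vapply(specs, `[[`, integer(1), "count")
  N <- sum(counts)
  labels <- rep(names(specs), counts)
  Z <- do.call(rbind, lapply(specs, function(s)
    if (s$count > 0L) matrix(s$signature, s$count, P, byrow = TRUE)
    else matrix(numeric(0), 0L, P)))
  local_seed(seed, {
    mu <- params$mean_on * Z + params$mean_off * (1 - Z)
    sd <- params$sd_on * Z + params$sd_off * (1 - Z)
    X <- if (N > 0L) matrix(stats::rnorm(N * P, mu, sd), N, P) else
      matrix(numeric(0), 0L, P)
    ord <- if (N > 0L) sample.int(N) else integer(0)
    X <- X[ord, , drop = FALSE]
    labels <- labels[ord]
  })
  dimnames(X) <- list(sprintf("cell_%05d", seq_len(N)), marker_names)
  structure(list(X = X, labels = labels, specs = specs, params = params,
                 seed = as.integer(seed)),
            class = "cell_dataset")
}

#' Simulate the reference five-population dataset
#'
#' Convenience wrapper generating the fixed reference design of
#' [reference_cell_types()] (8100 cells, 7 markers) under the default
#' [generative_params()].
#'
#' @param seed Integer seed.
#' @return A `cell_dataset`; see [simulate_cells()].
#' @export
simulate_reference <- function(seed = 1L)
  simulate_cells(reference_cell_types(), generative_params(), seed = seed)

#' @export
print.cell_dataset <- function(x, ...) {
  tab <- table(factor(x$labels, levels = names(x$specs)))
  cat(sprintf("<cell_dataset> %d cells x %d markers (seed %d)\n",
              nrow(x$X), ncol(x$X), x$seed))
  cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.cell_dataset <- function(x, ...) {
  data.frame(cell_id = rownames(x$X), x$X, label = x$labels,
             check.names = FALSE, row.names = NULL)
}

#' Rescale the prevalence of the rare cell types in a design
#'
#' Adjusts the counts of the named rare types (preserving their relative
#' proportions, rounding to whole cells with a minimum of one) so that their
#' combined share of the total is `target_fraction`; counts of all other
#' types are untouched. Used to build the 0.5%, 1% and 5% rare-prevalence
#' scenarios from one design.
#'
#' @param specs List of [cell_type_spec()] objects.
#' @param rare_names Character vector of spec names to treat as rare; may be
#'   empty, in which case `specs` is returned unchanged.
#' @param target_fraction Desired combined share of rare cells, in (0, 1).
#' @return The modified list of specs.
#' @export
rescale_rare_prevalence <- function(specs, rare_names, target_fraction) {
  specs <- validate_specs(specs)
  if (length(rare_names) == 0L) return(specs)
  unknown <- setdiff(rare_names, names(specs))
  if (length(unknown))
    stop_("unknown rare type name(s): ", paste(unknown, collapse = ", "))
  if (!is.numeric(target_fraction) || target_fraction <= 0 ||
      target_fraction >= 1)
    stop_("'target_fraction' must be in (0, 1)")
  counts <- vapply(specs, `[[`, integer(1), "count")
  common <- sum(counts[setdiff(names(specs), rare_names)])
  if (common == 0L)
    stop_("cannot rescale: no common cells to anchor the total")
  ## rare_total solves rare / (common + rare) = f
  rare_total <- target_fraction * common / (1 - target_fraction)
  old_rare <- counts[rare_names]
  if (sum(old_rare) == 0L)
    stop_("rare types have zero cells; cannot preserve proportions")
  new_rare <- pmax(1L, as.integer(round(rare_total * old_rare /
                                          sum(old_rare))))
  names(new_rare) <- names(old_rare)
  total <- common + sum(new_rare)
  if (abs(sum(new_rare) / total - target_fraction) * total > 1 + 1e-9)
    stop_("'target_fraction' infeasible: cannot reach ", target_fraction,
          " within one cell with at least one cell per rare type")
  for (nm in rare_names) specs[[nm]]$count <- new_rare[[nm]]
  specs
}

#' Downsample one labeled population of a dataset
#'
#' Retains a uniformly random subset of `n_keep` cells of the target label
#' and every cell of all other labels; intensity vectors of retained cells
#' are untouched. Used by the self-consistency experiments.
#'
#' @param dataset A `cell_dataset` (or any list with `X` and `labels`).
#' @param label The label whose population is reduced.
#' @param n_keep Number of its cells to retain; must not exceed the current
#'   count.
#' @param seed Integer seed making the retained set reproducible.
#' @return A `cell_dataset` with the reduced matrix and labels; row order of
#'   retained cells is preserved.
#' @export
downsample_label <- function(dataset, label, n_keep, seed = 1L) {
  stopifnot(is.list(dataset), !is.null(dataset$X), !is.null(dataset$labels))
  if (!label %in% dataset$labels)
    stop_("unknown label: ", label)
  idx <- which(dataset$labels == label)
  n_keep <- as.integer(n_keep)
  if (n_keep > length(idx))
    stop_("'n_keep' (", n_keep, ") exceeds available cells of label '",
          label, "' (", length(idx), ")")
  kept <- local_seed(seed, sample(idx, n_keep))
  keep <- sort(c(setdiff(seq_along(dataset$labels), idx), kept))
  out <- dataset
  out$X <- dataset$X[keep, , drop = FALSE]
  out$labels <- dataset$labels[keep]
  out
}
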