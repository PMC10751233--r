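## Readers and writers. CSV/TSV with a header row is the canonical
## interchange format: one `cell_id` column (optional; row order is used if
## absent), one numeric column per marker, and optionally a trailing
## `label` column. Writers prepend a `#`-comment provenance line; readers
## skip comment lines.

provenance_line <- function(params = character()) {
  ver <- tryCatch(as.character(utils::packageVersion("rarity")),
                  error = function(e) "dev")
  extra <- if (length(params))
    paste0(" ", paste(names(params), params, sep = "=", collapse = " "))
  else ""
  sprintf("# rarity %s%s", ver, extra)
}

#' Read a cell x marker intensity matrix
#'
#' Reads a delimited text file with a header row of marker names, an
#' optional `cell_id` column and an optional `label` column. Non-numeric
#' values in marker columns and duplicated marker names are rejected with a
#' located error. FCS input is not supported by this build; export the
#' per-cell mean intensities to CSV/TSV instead.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"fcs"`.
#' @return A numeric matrix with cell ids as row names and marker names as
#'   column names; any `label` column is attached as attribute `"labels"`.
#' @export
read_intensity_matrix <- function(path, format = c("auto", "csv", "tsv",
                                                   "fcs")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("file not found: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", tab = "tsv", txt = "tsv", fcs = "fcs",
                     "csv")
  if (format == "fcs")
    stop_("FCS input is not supported by this build; export the per-cell ",
          "mean intensities to CSV/TSV")
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop_("no columns found in ", path)
  cell_ids <- if ("cell_id" %in% names(df)) {
    ids <- as.character(df[["cell_id"]])
    df[["cell_id"]] <- NULL
    ids
  } else sprintf("cell_%05d", seq_len(nrow(df)))
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.character(df[["label"]])
    df[["label"]] <- NULL
  }
  if (ncol(df) < 1L) stop_("no marker columns found in ", path)
  if (anyDuplicated(names(df)))
    stop_("duplicated marker column(s) in ", path, ": ",
          paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop_("non-numeric value in column '", names(df)[j], "', data row ",
            bad, " of ", path, ": '", col[bad], "'")
    }
  }
  X <- as.matrix(df)
  rownames(X) <- cell_ids
  if (anyDuplicated(cell_ids)) stop_("duplicated cell ids in ", path)
  attr(X, "labels") <- labels
  X
}

#' Write a dataset or intensity matrix to CSV
#'
#' Writes `cell_id`, one column per marker, and (for labeled datasets) a
#' final `label` column, preceded by a `#` provenance comment line with the
#' package version and parameters.
#'
#' @param x A `cell_dataset`, or a numeric matrix with marker column names.
#' @param path Output file path.
#' @param params Optional named character vector recorded in the
#'   provenance line.
#' @return `path`, invisibly.
#' @export
write_cell_dataset <- function(x, path, params = character()) {
  if (inherits(x, "cell_dataset")) {
    df <- as.data.frame(x)
    params <- c(params, seed = as.character(x$seed))
  } else {
    X <- as_intensity_matrix(x)
    df <- data.frame(cell_id = rownames(X), X, check.names = FALSE,
                     row.names = NULL)
    lab <- attr(x, "labels")
    if (!is.null(lab)) df$label <- lab
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(params), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cluster assignment and its signature table
#'
#' Produces two CSVs: `<path>` with `cell_id,cluster` and
#' `<signature_path>` with `cluster,size` and one 0/1 column per marker.
#'
#' @param assignment A [assign_clusters()] object.
#' @param path Output path for the per-cell assignment.
#' @param signature_path Output path for the cluster signature table;
#'   defaults to `<path>` with a `_signatures.csv` suffix.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(assignment, path, signature_path = NULL) {
  stopifnot(inherits(assignment, "signature_clusters"))
  signature_path <- signature_path %||%
    sub("(\\.[^.]*)?$", "_signatures.csv", path)
  con <- file(path, "w")
  writeLines(provenance_line(), con)
  utils::write.table(data.frame(cell_id = names(assignment$cluster),
                                cluster = unname(assignment$cluster)),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  sig <- data.frame(cluster = rownames(assignment$signatures),
                    size = as.integer(assignment$sizes),
                    assignment$signatures, check.names = FALSE,
                    row.names = NULL)
  con <- file(signature_path, "w")
  writeLines(provenance_line(), con)
  utils::write.table(sig, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Percentile normalization of marker intensities
#'
#' Divides each marker by its q-th intensity percentile (the standard
#' preprocessing for multiplexed imaging panels, conventionally q = 99),
#' using the linear-interpolation quantile convention
#' ([stats::quantile()] type 7). Values above 1 are permitted unless
#' `clip = TRUE`. Markers whose q-th percentile is not positive are passed
#' through unscaled with a warning.
#'
#' @param x Cells x markers matrix (or `cell_dataset` / data frame).
#' @param q Percentile in (0, 100].
#' @param clip If `TRUE`, normalized values are capped at 1.
#' @return The normalized matrix.
#' @export
percentile_normalize <- function(x, q = 99, clip = FALSE) {
  X <- as_intensity_matrix(x)
  if (q <= 0 || q > 100) stop_("'q' must be in (0, 100]")
  for (j in seq_len(ncol(X))) {
    s <- stats::quantile(X[, j], q / 100, names = FALSE, type = 7)
    if (!is.finite(s) || s <= 0) {
      warning("marker '", colnames(X)[j],
              "' has non-positive ", q, "th percentile; left unscaled",
              call. = FALSE)
      next
    }
    X[, j] <- X[, j] / s
  }
  if (clip) X <- pmin(X, 1)
  X
}
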