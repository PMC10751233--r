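`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a given seed without disturbing the caller's RNG stream.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_ <- function(...) stop(..., call. = FALSE)

## Coerce the various accepted inputs (matrix, data.frame, cell_dataset) to a
## numeric cells x markers matrix with unique marker names and cell ids.
as_intensity_matrix <- function(x) {
  if (inherits(x, "cell_dataset")) x <- x$X
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    keep <- x[, num, drop = FALSE]
    m <- as.matrix(keep)
    if (!is.null(x$cell_id)) rownames(m) <- as.character(x$cell_id)
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop_("'x' must be a numeric cells x markers matrix")
  if (ncol(x) < 1L) stop_("need at least one marker column")
  if (is.null(colnames(x))) colnames(x) <- paste0("M", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop_("marker names must be unique; duplicated: ",
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("cell_%05d", seq_len(nrow(x)))
  x
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))
sigmoid <- function(x) stats::plogis(x)
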