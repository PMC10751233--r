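#' @export
print.rarity <- function(x, ...) {
  cat("Binary latent signature model (amortized variational mixture)\n")
  cat(sprintf("  %d cells, %d markers; %d epochs, final ELBO/cell %.3f\n",
              x$N, x$P, x$config$epochs, utils::tail(x$elbo_trace, 1)))
  mixlab <- if (x$config$shared_mixture) "shared across markers" else
    "per marker"
  cat(sprintf("  mixture (%s): off ~ N(%.3f, %.3f^2), on ~ N(%.3f, %.3f^2)\n",
              mixlab, x$mixture$mu_off[1], x$mixture$sigma_off[1],
              x$mixture$mu_on[1], x$mixture$sigma_on[1]))
  invisible(x)
}

#' Posterior probabilities, signatures or cluster labels for cells
#'
#' Applies the fitted encoder to `newdata` (a deterministic forward pass, no
#' sampling: identical inputs always give identical outputs, including cells
#' never seen in training).
#'
#' @param object A fitted [rarity()] model.
#' @param newdata Matrix, data frame or `cell_dataset`; marker set must
#'   match the training data.
#' @param type `"prob"` for the cells x markers matrix of posterior
#'   on-probabilities (strictly inside (0, 1)), `"signature"` for the
#'   thresholded 0/1 matrix, or `"cluster"` for a [assign_clusters()]
#'   object grouping cells with identical signatures.
#' @param threshold Binarization threshold; defaults to the one stored in
#'   the model.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.rarity <- function(object, newdata, type = c("prob", "signature",
                                                     "cluster"),
                           threshold = NULL, ...) {
  type <- match.arg(type)
  X <- check_markers(object, newdata)
  probs <- sigmoid(encoder_forward(object$encoder, X)$logits)
  dimnames(probs) <- dimnames(X)
  if (type == "prob") return(probs)
  states <- binarize(probs, threshold %||% object$threshold)
  if (type == "signature") return(states)
  assign_clusters(states)
}

#' @export
coef.rarity <- function(object, ...) {
  with(object$mixture,
       rbind(mu_off = mu_off, sigma_off = sigma_off,
             mu_on = mu_on, sigma_on = sigma_on))
}

#' @export
fitted.rarity <- function(object, newdata, ...) {
  if (missing(newdata))
    stop_("supply the training data as 'newdata'; the model stores no data")
  X <- check_markers(object, newdata)
  q <- predict(object, X, type = "prob")
  out <- q * rep(object$mixture$mu_on, each = nrow(X)) +
    (1 - q) * rep(object$mixture$mu_off, each = nrow(X))
  dimnames(out) <- dimnames(X)
  out
}

#' @export
residuals.rarity <- function(object, newdata, ...) {
  X <- check_markers(object, newdata)
  X - fitted(object, X)
}

#' Exact marginal log-likelihood under the fitted model
#'
#' The latent states are independent Bernoulli(`prior_p`) per marker, so the
#' marginal density factorizes into per-marker two-component mixtures and
#' can be evaluated exactly:
#' `p(x_g) = (1 - p) N(x_g; mu_off, sigma_off^2) + p N(x_g; mu_on, sigma_on^2)`.
#'
#' @param object A fitted [rarity()] model.
#' @param newdata Data to evaluate.
#' @param ... Unused.
#' @return An object of class `logLik` (total over cells and markers).
#' @export
logLik.rarity <- function(object, newdata, ...) {
  X <- check_markers(object, newdata)
  p <- object$config$prior_p
  B <- nrow(X)
  mix <- object$mixture
  la <- log(1 - p) + stats::dnorm(sweep(X, 2, mix$mu_off, "-") /
                                    rep(mix$sigma_off, each = B),
                                  log = TRUE) -
    rep(log(mix$sigma_off), each = B)
  lb <- log(p) + stats::dnorm(sweep(X, 2, mix$mu_on, "-") /
                                rep(mix$sigma_on, each = B), log = TRUE) -
    rep(log(mix$sigma_on), each = B)
  mx <- pmax(la, lb)
  ll <- sum(mx + log1p(exp(pmin(la, lb) - mx)))
  structure(ll, df = length(unlist(object$encoder$W)) +
              length(unlist(object$encoder$b)) + 4 * object$P,
            nobs = B, class = "logLik")
}

#' Simulate cells from the fitted generative model
#'
#' Draws latent on/off states from the `Bernoulli(prior_p)` prior and then
#' intensities from the fitted per-marker mixture components.
#'
#' @param object A fitted [rarity()] model.
#' @param nsim Number of cells to draw.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list with `X` (nsim x P intensity matrix) and `Z` (the latent
#'   0/1 states used).
#' @export
simulate.rarity <- function(object, nsim = 1L, seed = 1L, ...) {
  P <- object$P
  mix <- object$mixture
  local_seed(seed, {
    Z <- matrix(stats::rbinom(nsim * P, 1L, object$config$prior_p), nsim, P)
    mu <- rep(mix$mu_on, each = nsim) * Z + rep(mix$mu_off, each = nsim) *
      (1 - Z)
    sd <- rep(mix$sigma_on, each = nsim) * Z +
      rep(mix$sigma_off, each = nsim) * (1 - Z)
    X <- matrix(stats::rnorm(nsim * P, mu, sd), nsim, P)
  })
  colnames(X) <- colnames(Z) <- object$marker_names
  list(X = X, Z = Z)
}

#' @export
plot.rarity <- function(x, ...) {
  graphics::plot(seq_along(x$elbo_trace), x$elbo_trace, type = "l",
                 xlab = "epoch", ylab = "ELBO per cell",
                 main = "Training evidence lower bound", ...)
  invisible(x)
}

#' @export
summary.rarity <- function(object, ...) {
  structure(list(model = object, mixture = coef(object)),
            class = "summary.rarity")
}

#' @export
print.summary.rarity <- function(x, ...) {
  print(x$model)
  cat("\nMixture parameters per marker:\n")
  print(round(x$mixture, 4))
  cat(sprintf("\nTemperature schedule %.2f -> %.2f, prior p = %.2f, ",
              x$model$config$temperature[1], x$model$config$temperature[2],
              x$model$config$prior_p))
  cat(sprintf("binarization threshold %.2f\n", x$model$threshold))
  invisible(x)
}

#' Save or load a fitted model
#'
#' Serializes the fitted parameters, configuration and marker names to a
#' single archive file (RDS).
#'
#' @param object A fitted [rarity()] model.
#' @param path File path.
#' @return `read_rarity_model` returns the model; `write_rarity_model`
#'   returns `path` invisibly.
#' @export
write_rarity_model <- function(object, path) {
  stopifnot(inherits(object, "rarity"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname write_rarity_model
#' @export
read_rarity_model <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "rarity")) stop_("'", path, "' is not a saved model")
  obj
}
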