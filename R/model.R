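## Amortized variational inference for the binary latent signature model.
##
## Generative model, per cell i and marker g:
##   z_ig ~ Bernoulli(prior_p)            (relaxed to a binary Concrete during
##                                         training)
##   x_ig | z_ig ~ (1 - z_ig) N(mu_off, sigma_off^2) + z_ig N(mu_on, sigma_on^2)
##
## The approximate posterior q(z_i) is an independent (relaxed) Bernoulli per
## marker with probabilities given by an encoder MLP shared across cells.
## Training maximizes the Monte-Carlo ELBO
##   E_q[log p(x | z)] - KL(Bernoulli(q) || Bernoulli(prior_p))
## by Adam, with the reconstruction term reparameterized through relaxed
## (Concrete) samples at an annealed temperature and the KL term computed
## analytically between the unrelaxed Bernoullis.

LOGIT_CLAMP <- 10

#' Log-likelihood of one marker intensity given a (relaxed) on/off state
#'
#' Evaluates `log[(1 - z) N(x; mu_off, sigma_off^2) + z N(x; mu_on,
#' sigma_on^2)]`, the z-weighted two-component Gaussian mixture density.
#' The weight `z` may be any value in \[0, 1\], so relaxed samples from a
#' concrete distribution are valid; at `z = 0` or `z = 1` it collapses to
#' the single off/on component. Vectorized over all arguments.
#'
#' @param x Intensity value(s).
#' @param z State weight(s) in \[0, 1\].
#' @param mu_off,sigma_off Mean and sd of the "not expressed" component.
#' @param mu_on,sigma_on Mean and sd of the "expressed" component.
#' @return Log density, same length as the broadcast arguments.
#' @export
marker_loglik <- function(x, z, mu_off, sigma_off, mu_on, sigma_on) {
  if (any(sigma_off <= 0) || any(sigma_on <= 0))
    stop_("standard deviations must be positive")
  if (any(z < 0 | z > 1)) stop_("'z' must lie in [0, 1]")
  n <- max(length(x), length(z), length(mu_off), length(sigma_off),
           length(mu_on), length(sigma_on))
  x <- rep_len(x, n); z <- rep_len(z, n)
  mu_off <- rep_len(mu_off, n); sigma_off <- rep_len(sigma_off, n)
  mu_on <- rep_len(mu_on, n); sigma_on <- rep_len(sigma_on, n)
  la <- stats::dnorm(x, mu_off, sigma_off, log = TRUE)
  lb <- stats::dnorm(x, mu_on, sigma_on, log = TRUE)
  ## log[(1-z) e^la + z e^lb], stable for z exactly 0 or 1
  l1 <- ifelse(z < 1, log1p(-pmin(z, 1 - 1e-300)) + la, -Inf)
  l2 <- ifelse(z > 0, log(pmax(z, 1e-300)) + lb, -Inf)
  m <- pmax(l1, l2)
  m + log1p(exp(pmin(l1, l2) - m))
}

## Analytic KL(Bernoulli(q) || Bernoulli(p)), elementwise.
kl_bernoulli <- function(q, p) {
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  q * log(q / p) + (1 - q) * log((1 - q) / (1 - p))
}

## ---- encoder ----------------------------------------------------------

encoder_init <- function(P, hidden) {
  sizes <- c(P, hidden, P)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    fin <- sizes[l]; fout <- sizes[l + 1L]
    W[[l]] <- matrix(stats::rnorm(fin * fout, 0, sqrt(2 / (fin + fout))),
                     fin, fout)
    b[[l]] <- numeric(fout)
  }
  list(W = W, b = b, hidden = hidden)
}

## Forward pass; returns hidden activations for backprop and clamped logits.
encoder_forward <- function(enc, X) {
  L <- length(enc$W)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    A <- sweep(H[[l]] %*% enc$W[[l]], 2L, enc$b[[l]], "+")
    H[[l + 1L]] <- if (l < L) tanh(A) else A
  }
  L0 <- H[[L + 1L]]
  list(H = H, L0 = L0,
       logits = pmin(pmax(L0, -LOGIT_CLAMP), LOGIT_CLAMP),
       mask = abs(L0) < LOGIT_CLAMP)
}

## Backprop dObj/dlogits (already masked, already scaled) to weight grads.
encoder_backward <- function(enc, fwd, G) {
  L <- length(enc$W)
  gW <- vector("list", L); gb <- vector("list", L)
  D <- G
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fwd$H[[l]], D)
    gb[[l]] <- colSums(D)
    if (l > 1L) D <- (D %*% t(enc$W[[l]])) * (1 - fwd$H[[l]]^2)
  }
  list(W = gW, b = gb)
}

## ---- mixture parameterization -----------------------------------------
## Raw parameters: mu_off, delta (mu_on = mu_off + softplus(delta)),
## lsd_off, lsd_on (sd = exp(lsd)); all length-P vectors. When the mixture
## is shared across markers the entries are kept identical by summing the
## per-marker gradients.

mixture_from_raw <- function(raw) {
  list(mu_off = raw$mu_off,
       sigma_off = exp(raw$lsd_off),
       mu_on = raw$mu_off + softplus(raw$delta),
       sigma_on = exp(raw$lsd_on))
}

mixture_init <- function(X, shared) {
  P <- ncol(X)
  q10 <- apply(X, 2L, stats::quantile, 0.10, names = FALSE)
  q90 <- apply(X, 2L, stats::quantile, 0.90, names = FALSE)
  if (shared) {
    q10 <- rep(mean(q10), P)
    q90 <- rep(mean(q90), P)
  }
  list(mu_off = q10,
       delta = softplus_inv(pmax(q90 - q10, 0.05)),
       lsd_off = rep(log(0.1), P),
       lsd_on = rep(log(0.1), P))
}

## ---- training ----------------------------------------------------------

## Adam over a flat named list of numeric arrays (matrices and vectors).
make_adam <- function(theta)
  list(m = lapply(theta, function(e) e * 0),
       v = lapply(theta, function(e) e * 0), t = 0L)

adam_step <- function(theta, g, st, lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - 0.9^st$t
  bc2 <- 1 - 0.999^st$t
  for (k in seq_along(theta)) {
    st$m[[k]] <- 0.9 * st$m[[k]] + 0.1 * g[[k]]
    st$v[[k]] <- 0.999 * st$v[[k]] + 0.001 * g[[k]]^2
    theta[[k]] <- theta[[k]] +
      lr * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + 1e-8)
  }
  list(theta = theta, st = st)
}

## One minibatch: returns per-cell mean ELBO and gradients of the ELBO.
elbo_batch <- function(Xb, enc, raw, temperature, prior_p, mc_samples,
                       grad = TRUE) {
  B <- nrow(Xb); P <- ncol(Xb)
  mix <- mixture_from_raw(raw)
  fwd <- encoder_forward(enc, Xb)
  L <- fwd$logits
  q <- sigmoid(L)
  la <- stats::dnorm(sweep(Xb, 2L, mix$mu_off, "-") /
                       rep(mix$sigma_off, each = B), log = TRUE) -
    rep(log(mix$sigma_off), each = B)
  lb <- stats::dnorm(sweep(Xb, 2L, mix$mu_on, "-") /
                       rep(mix$sigma_on, each = B), log = TRUE) -
    rep(log(mix$sigma_on), each = B)
  gL <- 0; g_muo <- 0; g_mun <- 0; g_lso <- 0; g_lsn <- 0
  recon <- 0
  for (s in seq_len(mc_samples)) {
    eps <- matrix(stats::rlogis(B * P), B, P)
    Z <- sigmoid((L + eps) / temperature)
    Z <- pmin(pmax(Z, 1e-6), 1 - 1e-6)
    l1 <- log1p(-Z) + la
    l2 <- log(Z) + lb
    mx <- pmax(l1, l2)
    lm <- mx + log1p(exp(pmin(l1, l2) - mx))
    recon <- recon + sum(lm)
    if (grad) {
      w_on <- exp(l2 - lm)
      w_off <- 1 - w_on
      dz <- w_on / Z - w_off / (1 - Z)
      gL <- gL + dz * Z * (1 - Z) / temperature
      r_off <- sweep(Xb, 2L, mix$mu_off, "-")
      r_on <- sweep(Xb, 2L, mix$mu_on, "-")
      so2 <- rep(mix$sigma_off^2, each = B)
      sn2 <- rep(mix$sigma_on^2, each = B)
      g_muo <- g_muo + colSums(w_off * r_off / so2)
      g_mun <- g_mun + colSums(w_on * r_on / sn2)
      g_lso <- g_lso + colSums(w_off * (r_off^2 / so2 - 1))
      g_lsn <- g_lsn + colSums(w_on * (r_on^2 / sn2 - 1))
    }
  }
  kl <- kl_bernoulli(q, prior_p)
  value <- (recon / mc_samples - sum(kl)) / B
  if (!grad) return(list(value = value))
  ## dObj/dlogits: reconstruction (through relaxed sample) minus KL
  g_kl_L <- (L - stats::qlogis(prior_p)) * q * (1 - q)
  G <- ((gL / mc_samples) - g_kl_L) * fwd$mask / B
  genc <- encoder_backward(enc, fwd, G)
  list(value = value,
       grads = list(
         enc = genc,
         mu_off = (g_muo + g_mun) / (mc_samples * B),
         delta = (g_mun / (mc_samples * B)) * sigmoid(raw$delta),
         lsd_off = g_lso / (mc_samples * B),
         lsd_on = g_lsn / (mc_samples * B)))
}

#' Fit the binary latent signature model
#'
#' Fits, by stochastic gradient ascent on the evidence lower bound (ELBO),
#' an amortized variational mixture model in which each marker of each cell
#' has a latent on/off state: intensities follow
#' `(1 - z) N(mu_off, sigma_off^2) + z N(mu_on, sigma_on^2)` and a shared
#' encoder network maps each cell's intensity vector to its vector of
#' posterior on-probabilities. Thresholding those probabilities yields a
#' binary expression signature per cell, and cells with identical signatures
#' form a cluster (see [predict.rarity()] and [assign_clusters()]).
#'
#' Training uses the relaxed-Bernoulli (binary Concrete) reparameterization
#' for the reconstruction term, with the temperature annealed linearly from
#' `temperature[1]` to `temperature[2]` over the first half of the epochs,
#' and an analytic Bernoulli KL against the `Bernoulli(prior_p)` prior. The
#' whole procedure is deterministic given `seed`.
#'
#' @param x Numeric cells x markers matrix (typically 99th-percentile
#'   normalized to roughly \[0, 1\]), a data frame, or a `cell_dataset`.
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size (capped at the number of cells).
#' @param learning_rate Adam step size.
#' @param hidden Integer vector of encoder hidden-layer widths.
#' @param temperature Length-2 vector `c(start, end)` of the relaxation
#'   temperature schedule; `start >= end > 0`.
#' @param prior_p Prior on-probability of each latent state, in (0, 1).
#' @param mc_samples Number of relaxed samples per cell per gradient step.
#' @param shared_mixture If `TRUE` (default) the four mixture parameters are
#'   shared across markers, as appropriate after percentile normalization;
#'   if `FALSE` each marker gets its own parameters, initialized from its
#'   10th/90th intensity percentiles. Note that per-marker parameters are
#'   only identifiable for markers observed in both states.
#' @param threshold Default binarization threshold stored in the model.
#' @param seed Integer seed controlling initialization, minibatch order and
#'   relaxed sampling.
#' @param verbose Print the ELBO every 20 epochs.
#' @return An object of class `rarity` with components `mixture`
#'   (`mu_off`, `sigma_off`, `mu_on`, `sigma_on`, per marker), `encoder`,
#'   `elbo_trace` (per-epoch mean ELBO per cell), `config`, `marker_names`,
#'   and the usual method support ([coef()], [predict()], [plot()],
#'   [summary()], [simulate()], [residuals()], [logLik()]).
#' @examples
#' d <- simulate_cells(reference_cell_types()[c(1, 2)], seed = 1)
#' fit <- rarity(d, epochs = 3, seed = 1)
#' head(predict(fit, type = "signature"))
#' @export
rarity <- function(x, epochs = 200L, batch_size = 256L, learning_rate = 1e-3,
                   hidden = c(64L, 64L), temperature = c(1.0, 0.3),
                   prior_p = 0.5, mc_samples = 1L, shared_mixture = TRUE,
                   threshold = 0.5, seed = 1L, verbose = FALSE) {
  X <- as_intensity_matrix(x)
  if (anyNA(X) || any(!is.finite(X)))
    stop_("'x' contains missing or non-finite values")
  if (length(temperature) != 2L || temperature[2] <= 0 ||
      temperature[1] < temperature[2])
    stop_("'temperature' must be c(start, end) with start >= end > 0")
  if (prior_p <= 0 || prior_p >= 1) stop_("'prior_p' must be in (0, 1)")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop_("'epochs' must be >= 1")
  mc_samples <- as.integer(mc_samples)
  if (mc_samples < 1L) stop_("'mc_samples' must be >= 1")
  N <- nrow(X); P <- ncol(X)
  batch_size <- min(as.integer(batch_size), N)
  if (batch_size < 1L) stop_("no cells to fit")

  trace <- numeric(epochs)
  anneal <- max(1L, epochs %/% 2L)
  mixnames <- c("mu_off", "delta", "lsd_off", "lsd_on")
  local_seed(seed, {
    enc <- encoder_init(P, hidden)
    raw <- mixture_init(X, shared_mixture)
    nl <- length(enc$W)
    theta <- c(enc$W, enc$b, raw)
    names(theta) <- c(paste0("W", seq_len(nl)), paste0("b", seq_len(nl)),
                      mixnames)
    ad <- make_adam(theta)
    nb <- ceiling(N / batch_size)
    for (ep in seq_len(epochs)) {
      tau <- temperature[1] + (temperature[2] - temperature[1]) *
        min(1, (ep - 1) / max(1L, anneal - 1L))
      ord <- sample.int(N)
      acc <- 0
      for (ib in seq_len(nb)) {
        idx <- ord[(((ib - 1L) * batch_size) + 1L):min(ib * batch_size, N)]
        Xb <- X[idx, , drop = FALSE]
        st <- elbo_batch(Xb, enc, raw, tau, prior_p, mc_samples)
        if (!is.finite(st$value))
          stop_("training diverged: non-finite ELBO at epoch ", ep,
                " (try a lower learning rate)")
        acc <- acc + st$value * length(idx)
        g <- c(st$grads$enc$W, st$grads$enc$b,
               st$grads[mixnames])
        if (shared_mixture)
          for (k in 2L * nl + seq_len(4L)) g[[k]] <- rep(sum(g[[k]]), P)
        up <- adam_step(theta, g, ad, learning_rate)
        theta <- up$theta
        ad <- up$st
        enc$W <- theta[seq_len(nl)]
        enc$b <- theta[nl + seq_len(nl)]
        raw <- theta[mixnames]
      }
      trace[ep] <- acc / N
      if (verbose && (ep %% 20L == 0L || ep == 1L))
        message(sprintf("epoch %4d  ELBO/cell %.4f  tau %.2f", ep,
                        trace[ep], tau))
    }
  })

  mix <- mixture_from_raw(raw)
  names(mix$mu_off) <- names(mix$mu_on) <- colnames(X)
  names(mix$sigma_off) <- names(mix$sigma_on) <- colnames(X)
  structure(list(
    encoder = enc,
    mixture = mix,
    mixture_raw = raw,
    config = list(epochs = epochs, batch_size = batch_size,
                  learning_rate = learning_rate, hidden = hidden,
                  temperature = temperature, prior_p = prior_p,
                  mc_samples = mc_samples, shared_mixture = shared_mixture,
                  seed = as.integer(seed)),
    elbo_trace = trace,
    marker_names = colnames(X),
    threshold = threshold,
    N = N, P = P,
    call = match.call()),
    class = "rarity")
}

#' Monte-Carlo ELBO of a fitted model on a dataset
#'
#' Recomputes the evidence lower bound (mean per cell) of a fitted model on
#' `newdata`, sampling the relaxed latent states at the given temperature.
#' Useful for monitoring and for comparing against exact marginal
#' likelihoods (see [logLik.rarity()]); the ELBO can never exceed the
#' marginal log-likelihood.
#'
#' @param object A fitted [rarity()] model.
#' @param newdata Matrix or `cell_dataset`; defaults to none (required).
#' @param temperature Relaxation temperature; defaults to the final
#'   temperature of the training schedule.
#' @param mc_samples Number of relaxed samples.
#' @param seed Integer seed for the sampling.
#' @return The ELBO per cell (a single number).
#' @export
rarity_elbo <- function(object, newdata, temperature = NULL,
                        mc_samples = 16L, seed = 1L) {
  stopifnot(inherits(object, "rarity"))
  X <- check_markers(object, newdata)
  temperature <- temperature %||% object$config$temperature[2]
  if (temperature <= 0) stop_("'temperature' must be positive")
  local_seed(seed,
    elbo_batch(X, object$encoder, object$mixture_raw, temperature,
               object$config$prior_p, as.integer(mc_samples),
               grad = FALSE)$value)
}

check_markers <- function(object, newdata) {
  X <- as_intensity_matrix(newdata)
  if (ncol(X) != object$P)
    stop_("'newdata' has ", ncol(X), " markers; model expects ", object$P)
  if (!identical(colnames(X), object$marker_names)) {
    if (!setequal(colnames(X), object$marker_names))
      stop_("marker names of 'newdata' do not match the fitted model")
    X <- X[, object$marker_names, drop = FALSE]
  }
  X
}

#' Threshold posterior on-probabilities into binary signatures
#'
#' Maps each posterior probability to 1 ("on") where it is greater than or
#' equal to `threshold` and 0 otherwise; a probability exactly at the
#' threshold maps to "on" (documented tie rule). The threshold used is
#' recorded as an attribute.
#'
#' @param probs Numeric matrix (or vector) of posterior probabilities.
#' @param threshold Binarization threshold in (0, 1).
#' @return An integer 0/1 matrix of the same shape, with attribute
#'   `threshold`.
#' @export
binarize <- function(probs, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop_("'threshold' must be strictly inside (0, 1)")
  states <- (probs >= threshold) * 1L
  attr(states, "threshold") <- threshold
  states
}
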