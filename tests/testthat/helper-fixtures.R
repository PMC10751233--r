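## Shared fixtures and independent oracles. Oracles are written as direct,
## loop-based evaluations of the defining formulas so they share no code
## with the package implementation.

ref_signatures <- rbind(A = c(1, 1, 1, 1, 0, 0, 0),
                        B = c(1, 1, 1, 0, 1, 0, 0),
                        C = c(1, 1, 1, 1, 0, 1, 0),
                        D = c(1, 1, 1, 0, 0, 0, 0),
                        E = c(1, 1, 0, 0, 0, 0, 0))
ref_counts <- c(A = 4000L, B = 3000L, C = 1000L, D = 60L, E = 40L)

## Small two-population dataset for fast model tests.
tiny_dataset <- function(n_on = 150L, n_off = 150L, seed = 7L) {
  simulate_cells(list(cell_type_spec("hi", c(1, 1, 0), n_on),
                      cell_type_spec("lo", c(0, 0, 0), n_off)),
                 seed = seed)
}

quick_fit <- function(x, epochs = 40L, seed = 1L, ...)
  rarity(x, epochs = epochs, seed = seed, ...)

## --- entropy / conditional-score oracle ---------------------------------
## Direct evaluation of the four entropy formulas, loop by loop.

oracle_entropy <- function(counts) {
  tot <- sum(counts)
  h <- 0
  for (v in counts) if (v > 0) h <- h - (v / tot) * log(v / tot)
  h
}

oracle_conditional <- function(A, c_idx) {
  A <- as.matrix(A)
  HK <- oracle_entropy(colSums(A))
  HC <- oracle_entropy(rowSums(A))
  HKc <- oracle_entropy(A[c_idx, ])
  kstar <- which(A[c_idx, ] == max(A[c_idx, ]))[1]
  HCk <- oracle_entropy(A[, kstar])
  comp <- if (HK == 0) 1 else 1 - HKc / HK
  hom <- if (HC == 0) 1 else 1 - HCk / HC
  comp <- min(1, max(0, comp))
  hom <- min(1, max(0, hom))
  v <- if (comp == 0 || hom == 0) 0 else 2 * comp * hom / (comp + hom)
  list(completeness = comp, homogeneity = hom, v_measure = v,
       modal = kstar)
}

oracle_v_measure <- function(A) {
  A <- as.matrix(A)
  N <- sum(A)
  HC <- oracle_entropy(rowSums(A))
  HK <- oracle_entropy(colSums(A))
  HCgK <- 0
  for (k in seq_len(ncol(A)))
    HCgK <- HCgK + sum(A[, k]) / N * oracle_entropy(A[, k])
  HKgC <- 0
  for (c in seq_len(nrow(A)))
    HKgC <- HKgC + sum(A[c, ]) / N * oracle_entropy(A[c, ])
  hom <- if (HC == 0) 1 else 1 - HCgK / HC
  comp <- if (HK == 0) 1 else 1 - HKgC / HK
  v <- if (hom + comp == 0) 0 else 2 * hom * comp / (hom + comp)
  c(hom, comp, v)
}

random_table <- function(C, K, N) {
  A <- matrix(0L, C, K)
  hits <- sample.int(C * K, N, replace = TRUE)
  for (h in hits) A[h] <- A[h] + 1L
  ## ensure no empty focal rows
  for (i in seq_len(C)) if (sum(A[i, ]) == 0) A[i, sample.int(K, 1)] <- 1L
  rownames(A) <- paste0("t", seq_len(C))
  colnames(A) <- paste0("k", seq_len(K))
  A
}

## --- Hamming ball oracle ------------------------------------------------

oracle_ball <- function(signatures, reference, radius) {
  hits <- integer(0)
  for (k in seq_len(nrow(signatures))) {
    d <- 0
    for (j in seq_len(ncol(signatures)))
      if (signatures[k, j] != reference[j]) d <- d + 1
    if (d <= radius) hits <- c(hits, k)
  }
  hits
}

random_assignment <- function(P, n_clusters, seed) {
  set.seed(seed)
  sigs <- unique(matrix(rbinom(3 * n_clusters * P, 1, 0.5), ncol = P))
  sigs <- sigs[seq_len(min(n_clusters, nrow(sigs))), , drop = FALSE]
  n_per <- sample(1:30, nrow(sigs), replace = TRUE)
  S <- sigs[rep(seq_len(nrow(sigs)), n_per), , drop = FALSE]
  colnames(S) <- paste0("M", seq_len(P))
  rownames(S) <- sprintf("c%04d", seq_len(nrow(S)))
  assign_clusters(S)
}
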