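truth_clusters <- function(seed = 2) {
  d <- simulate_reference(seed = seed)
  S <- ref_signatures[d$labels, , drop = FALSE]
  dimnames(S) <- list(rownames(d$X), colnames(d$X))
  list(dataset = d, assignment = assign_clusters(S))
}

test_that("identical signatures collapse to one cluster per signature", {
  S <- matrix(1L, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  one <- assign_clusters(S)
  expect_equal(nrow(one$signatures), 1L)
  expect_equal(unname(one$sizes), 10L)

  ## P = 2 with all four signatures present: the full cluster space 2^P
  S4 <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(1, 1))
  a4 <- assign_clusters(S4)
  expect_equal(nrow(a4$signatures), 4L)
})

test_that("ground-truth signatures give the five reference clusters", {
  tc <- truth_clusters()
  a <- tc$assignment
  expect_equal(nrow(a$signatures), 5L)
  expect_equal(unname(a$sizes), c(4000L, 3000L, 1000L, 60L, 40L))
  ## cluster 1 is type A's signature (largest first)
  expect_equal(unname(a$signatures[1, ]), unname(ref_signatures["A", ]))
  ## every cell's signature equals its cluster's signature
  expect_equal(sum(a$sizes), length(a$cluster))
})

test_that("cluster ids are ordered by size then lexicographic signature", {
  S <- rbind(matrix(rep(c(0L, 1L), 3), 3, 2, byrow = TRUE),
             matrix(rep(c(1L, 0L), 3), 3, 2, byrow = TRUE),
             c(1L, 1L))
  a <- assign_clusters(S)
  ## two tied clusters of size 3: "01" sorts before "10"
  expect_equal(unname(a$signatures[1, ]), c(0L, 1L))
  expect_equal(unname(a$signatures[2, ]), c(1L, 0L))
  expect_equal(unname(a$sizes), c(3L, 3L, 1L))
})

test_that("clustering is invariant to row permutation", {
  set.seed(5)
  S <- matrix(rbinom(60 * 4, 1, 0.5), 60, 4)
  rownames(S) <- sprintf("c%03d", 1:60)
  a <- assign_clusters(S)
  p <- sample.int(60)
  b <- assign_clusters(S[p, ])
  expect_identical(a$signatures, b$signatures)
  expect_identical(a$cluster[rownames(S)], b$cluster[rownames(S)])
})

test_that("cluster count never exceeds the signature space", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- sample(2:5, 1)
    S <- matrix(rbinom(40 * P, 1, 0.5), 40, P)
    a <- assign_clusters(S)
    expect_lte(nrow(a$signatures), 2^P)
    expect_lte(nrow(a$signatures), 40L)
  }
})

test_that("a minimum cluster size marks cells unassigned, never merges", {
  S <- rbind(matrix(0L, 5, 2), matrix(1L, 2, 2))
  a <- assign_clusters(S, min_size = 3L)
  expect_equal(sum(is.na(a$cluster)), 2L)
  expect_equal(sum(a$cluster == 1L, na.rm = TRUE), 5L)
})

test_that("hamming distance counts differing positions", {
  expect_equal(hamming_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(hamming_distance(c(1, 0, 1), c(0, 1, 1)), 2)
  ## a lone-marker reference vs the same plus one extra marker
  expect_equal(hamming_distance(c(1, 0, 0), c(1, 1, 0)), 1)
  expect_error(hamming_distance(c(1, 0), c(1, 0, 1)), "length")
})

test_that("hamming ball query equals brute-force enumeration", {
  for (seed in 1:10) {
    a <- random_assignment(P = 5, n_clusters = 12, seed = seed)
    ref <- rbinom(5, 1, 0.5)
    for (r in c(0, 2, 5)) {
      res <- hamming_ball_query(a, ref, r)
      expect_setequal(res$cluster, oracle_ball(a$signatures, ref, r))
    }
    ## monotone in the radius
    sets <- lapply(0:5, function(r)
      hamming_ball_query(a, ref, r)$cluster)
    for (r in 1:5) expect_true(all(sets[[r]] %in% sets[[r + 1]]))
    ## radius P covers every observed cluster
    expect_setequal(sets[[6]], seq_len(nrow(a$signatures)))
  }
})

test_that("hamming ball query output is sorted and validated", {
  a <- random_assignment(P = 4, n_clusters = 8, seed = 1)
  res <- hamming_ball_query(a, c(0, 0, 0, 0), 4)
  expect_false(is.unsorted(res$distance))
  within <- split(res$size, res$distance)
  for (g in within) expect_false(is.unsorted(rev(g)))
  expect_error(hamming_ball_query(a, c(0, 0, 0, 0), 5), "radius")
  expect_error(hamming_ball_query(a, c(0, 0), 1), "length")
  ## named references are aligned by marker name
  ref <- c(M3 = 1, M1 = 0, M2 = 0, M4 = 0)
  r1 <- hamming_ball_query(a, ref, 1)
  r2 <- hamming_ball_query(a, c(0, 0, 1, 0), 1)
  expect_identical(r1, r2)
})

test_that("marker-constraint gating selects exactly the matching cells", {
  tc <- truth_clusters()
  a <- tc$assignment
  d <- tc$dataset
  markers <- colnames(d$X)
  ## unconstrained query returns every cell
  expect_setequal(select_cells(a, marker_constraint(markers)),
                  rownames(d$X))
  ## M4 is on only in types A and C
  got <- select_cells(a, marker_constraint(markers, on = "M4"))
  expect_setequal(got, rownames(d$X)[d$labels %in% c("A", "C")])
  ## fully specified signature isolates one cluster
  consE <- marker_constraint(markers, on = c("M1", "M2"),
                             off = c("M3", "M4", "M5", "M6", "M7"))
  expect_setequal(select_cells(a, consE), rownames(d$X)[d$labels == "E"])
  expect_error(marker_constraint(markers, on = "nope"), "unknown")
  expect_error(marker_constraint(markers, on = "M1", off = "M1"), "both")
})

test_that("refinement splits a selection into disjoint exhaustive parts", {
  tc <- truth_clusters()
  a <- tc$assignment
  d <- tc$dataset
  markers <- colnames(d$X)
  base <- marker_constraint(markers, on = c("M1", "M2", "M3"))
  parts <- refine_selection(a, base, "M4")
  ## M1-3 on selects A, B, C and D; M4 separates A+C from B+D
  expect_length(parts$on, 5000L)
  expect_length(parts$off, 3060L)
  expect_length(intersect(parts$on, parts$off), 0L)
  expect_setequal(c(parts$on, parts$off), select_cells(a, base))
  expect_error(refine_selection(a, base, "M1"), "already constrained")
  ## empty base selection gives two empty parts
  none <- marker_constraint(markers, on = "M7")
  p0 <- refine_selection(a, none, "M6")
  expect_length(p0$on, 0L)
  expect_length(p0$off, 0L)
})

test_that("cluster summaries aggregate intensities per cluster", {
  X <- matrix(2.5, 6, 2, dimnames = list(sprintf("cell_%05d", 1:6),
                                         c("a", "b")))
  a <- assign_clusters(matrix(1L, 6, 2,
                              dimnames = list(rownames(X), c("a", "b"))))
  sm <- cluster_summary(a, X)
  expect_equal(sm$mean.a, 2.5)
  expect_equal(sm$median.b, 2.5)

  tc <- truth_clusters()
  sm <- cluster_summary(tc$assignment, tc$dataset$X)
  expect_equal(sum(sm$size), nrow(tc$dataset$X))
  p <- tc$dataset$params
  for (k in seq_len(nrow(sm))) {
    sig <- tc$assignment$signatures[k, ]
    n <- sm$size[k]
    for (j in seq_along(sig)) {
      mu <- if (sig[j] == 1) p$mean_on else p$mean_off
      sd_ <- if (sig[j] == 1) p$sd_on else p$sd_off
      expect_lt(abs(sm[[paste0("mean.", names(sig)[j])]][k] - mu),
                3 * sd_ / sqrt(n) + 1e-12)
    }
  }
})
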