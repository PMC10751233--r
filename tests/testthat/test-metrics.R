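test_that("contingency tables tally cells with first-appearance ordering", {
  A <- contingency(c("x", "x", "y"), c(1, 2, 2))
  expect_equal(unclass(unname(A)), rbind(c(1L, 1L), c(0L, 1L)),
               ignore_attr = TRUE)
  expect_identical(rownames(A), c("x", "y"))
  ## identical labelings give a diagonal table
  lab <- rep(c("b", "a", "c"), c(3, 2, 1))
  D <- contingency(lab, lab)
  expect_true(all(D[upper.tri(D)] == 0) && all(D[lower.tri(D)] == 0))
  expect_identical(rownames(D), c("b", "a", "c"))
  expect_equal(sum(D), 6L)
  expect_error(contingency(1:3, 1:4), "lengths")
})

test_that("conditional entropies match direct two-outcome computations", {
  A <- rbind(t1 = c(10L, 0L), t2 = c(2L, 2L))
  colnames(A) <- c("k1", "k2")
  expect_equal(h_clusters_given_type(A, "t1"), 0)
  expect_equal(h_clusters_given_type(A, "t2"), log(2))
  expect_equal(h_clusters_given_type(rbind(c(3L, 1L)), 1),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  B <- cbind(k1 = c(5L, 5L), k2 = c(4L, 0L))
  rownames(B) <- c("t1", "t2")
  expect_equal(h_types_given_cluster(B, "k2"), 0)
  expect_equal(h_types_given_cluster(B, "k1"), log(2))
  expect_equal(h_types_given_cluster(cbind(c(2L, 1L, 1L)), 1),
               oracle_entropy(c(2, 1, 1)))
  expect_error(h_clusters_given_type(A, "zz"), "unknown")
  C <- rbind(a = c(0L, 0L), b = c(1L, 1L))
  expect_error(h_clusters_given_type(C, "a"), "no cells")
})

test_that("marginal entropies come from the table margins", {
  expect_equal(marginal_entropies(matrix(5L, 1, 1)),
               c(H_types = 0, H_clusters = 0))
  A <- rbind(c(2L, 2L), c(1L, 3L))
  expect_equal(unname(marginal_entropies(A)[1]), log(2))
  set.seed(1)
  B <- random_table(3, 3, 40)
  expect_equal(unname(marginal_entropies(B)),
               c(oracle_entropy(rowSums(B)), oracle_entropy(colSums(B))))
})

test_that("perfect reclassification scores 1.0 on every conditional metric", {
  ## permutation-matrix table: each type maps to exactly one cluster
  A <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  A["a", "z"] <- 10L; A["b", "x"] <- 5L; A["c", "y"] <- 3L
  for (ty in rownames(A)) {
    s <- conditional_scores(A, ty)
    expect_identical(s$completeness, 1)
    expect_identical(s$homogeneity, 1)
    expect_identical(s$v_measure, 1)
  }
})

test_that("conditional scores match the brute-force entropy oracle", {
  ## fixed example
  A <- rbind(c(40L, 10L, 0L), c(0L, 50L, 0L), c(0L, 0L, 100L))
  dimnames(A) <- list(c("r1", "r2", "r3"), c("c1", "c2", "c3"))
  o <- oracle_conditional(A, 1)
  s <- conditional_scores(A, "r1")
  expect_equal(s$completeness, o$completeness, tolerance = 1e-12)
  expect_equal(s$homogeneity, o$homogeneity, tolerance = 1e-12)
  expect_equal(s$v_measure, o$v_measure, tolerance = 1e-12)
  expect_identical(s$modal_cluster, colnames(A)[o$modal])
  ## random small tables
  set.seed(42)
  for (i in 1:300) {
    A <- random_table(sample(1:5, 1), sample(1:5, 1), sample(1:50, 1))
    ci <- sample(nrow(A), 1)
    o <- oracle_conditional(A, ci)
    s <- conditional_scores(A, ci)
    expect_equal(s$completeness, o$completeness, tolerance = 1e-12)
    expect_equal(s$homogeneity, o$homogeneity, tolerance = 1e-12)
    expect_equal(s$v_measure, o$v_measure, tolerance = 1e-12)
  }
})

test_that("degenerate tables follow the documented conventions", {
  ## single cluster: completeness 1 by convention, homogeneity < 1, V = 0
  ## exactly when homogeneity is 0
  A <- cbind(c(6L, 6L))
  rownames(A) <- c("a", "b")
  s <- conditional_scores(A, "a")
  expect_identical(s$completeness, 1)
  expect_identical(s$homogeneity, 0)  # H(C|k) = H(C)
  expect_identical(s$v_measure, 0)
  ## single type: homogeneity 1 by convention
  B <- rbind(c(3L, 3L))
  rownames(B) <- "only"
  s2 <- conditional_scores(B, "only")
  expect_identical(s2$homogeneity, 1)
  expect_equal(s2$completeness, 0)  # split over two equal clusters
})

test_that("scores are clipped into [0, 1] for pathological tables", {
  ## focal type split 50/50 over two tiny clusters while a third huge
  ## cluster dominates: H(K | C = a) > H(K)
  A <- rbind(a = c(50L, 50L, 0L), b = c(0L, 0L, 1000L))
  expect_gt(h_clusters_given_type(A, "a"),
            marginal_entropies(A)[["H_clusters"]])
  s <- conditional_scores(A, "a")
  expect_gte(s$completeness, 0)
  expect_lte(s$v_measure, 1)
})

test_that("scores are invariant to cluster and type relabeling", {
  set.seed(7)
  for (i in 1:20) {
    A <- random_table(4, 4, 60)
    s <- conditional_scores(A, 2)
    pc <- sample(ncol(A))
    pr <- c(2, setdiff(sample(nrow(A)), 2))  # keep focal row identity
    B <- A[pr, pc]
    s2 <- conditional_scores(B, "t2")
    expect_equal(s2$completeness, s$completeness, tolerance = 1e-12)
    ## homogeneity depends on the modal cluster, which is only
    ## permutation-invariant when the row maximum is unique
    if (sum(A[2, ] == max(A[2, ])) == 1L)
      expect_equal(s2$homogeneity, s$homogeneity, tolerance = 1e-12)
  }
})

test_that("standard V-measure matches conventions and the oracle", {
  lab <- rep(c("a", "b", "c"), c(5, 3, 2))
  expect_equal(unname(v_measure(contingency(lab, lab))), c(1, 1, 1))
  ## one predicted cluster: perfectly complete, not homogeneous
  one <- v_measure(contingency(lab, rep(1, 10)))
  expect_equal(unname(one["completeness"]), 1)
  expect_lt(one["homogeneity"], 1)
  set.seed(3)
  for (i in 1:50) {
    A <- random_table(4, 4, 80)
    expect_equal(unname(v_measure(A)), oracle_v_measure(A),
                 tolerance = 1e-12)
  }
})

test_that("standard V-measure agrees with scikit-learn", {
  set.seed(19)
  true <- sample(0:3, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.3, sample(0:3, 200, replace = TRUE), true)
  ours <- v_measure(contingency(true, pred))
  script <- paste0(
    "import json,sys\n",
    "from sklearn.metrics import homogeneity_completeness_v_measure\n",
    "t=json.loads(sys.argv[1]); p=json.loads(sys.argv[2])\n",
    "print(json.dumps(homogeneity_completeness_v_measure(t,p)))")
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- suppressWarnings(system2(
    "python", c(sf, shQuote(jsonlite::toJSON(true)),
                shQuote(jsonlite::toJSON(pred))),
    stdout = TRUE, stderr = FALSE))
  unlink(sf)
  skref <- as.numeric(jsonlite::fromJSON(out[length(out)]))
  expect_equal(unname(ours), skref, tolerance = 1e-10)
})
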