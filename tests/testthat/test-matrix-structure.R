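test_that("Patefield draws conserve margins exactly and are reproducible", {
  set.seed(3)
  M <- matrix(rpois(35, 3), 5, 7)
  M[1, 1] <- M[1, 1] + 1
  ens <- patefield_null(M, n_draws = 200, seed = 11)
  expect_true(all(vapply(ens$matrices, function(x)
    all(rowSums(x) == rowSums(M)) && all(colSums(x) == colSums(M)) &&
      all(x >= 0) && all(x == round(x)), logical(1))))
  ens2 <- patefield_null(M, n_draws = 200, seed = 11)
  expect_identical(ens$matrices, ens2$matrices)
  expect_error(patefield_null(matrix(0, 2, 2), 5), "degenerate")
  expect_error(patefield_null(matrix(c(1, -1, 1, 1), 2), 5), "validation")
})

test_that("the 2x2 unit-margin null puts equal mass on both admissible tables", {
  # margins (1,1)/(1,1): exactly two tables, identity and flip
  M <- diag(1, 2)
  ens <- patefield_null(M, n_draws = 4000, seed = 5)
  ident <- mean(vapply(ens$matrices, function(x) x[1, 1] == 1, logical(1)))
  ci <- 2.576 * sqrt(0.25 / 4000)
  expect_lt(abs(ident - 0.5), ci)
})

test_that("WIN scores packing and is invariant to row/column permutation", {
  # 1x1: a single cell is the corner
  expect_equal(win(matrix(5, 1, 1)), 1)
  # packed triangular matrix scores higher than its checkerboard
  packed <- rbind(c(8, 4, 2), c(4, 2, 0), c(2, 0, 0))
  anti <- matrix(0, 3, 3); anti[cbind(1:3, 3:1)] <- 4
  expect_gt(win(packed), win(anti))
  set.seed(13)
  M <- matrix(rpois(35, 2), 5, 7)
  M[2, 3] <- M[2, 3] + 2
  for (rep in 1:5)
    expect_equal(win(M[sample(5), sample(7)]), win(M))
  expect_error(win(matrix(0, 2, 2)), "degenerate")
})

test_that("WINE is calibrated: ~0 on self-null, high on packed, negative on anti-nested", {
  set.seed(61)
  base <- matrix(rpois(8 * 7, 3), 8, 7)
  base[rowSums(base) == 0, 1] <- 1
  # matrix drawn from its own null: WINE near 0, p roughly uniform
  wines <- vapply(1:30, function(i) {
    M <- patefield_null(base, 1, seed = i)$matrices[[1]]
    wine(M, patefield_null(M, 80, seed = i + 100))$wine
  }, numeric(1))
  expect_lt(abs(mean(wines)), 0.1)

  # the margins-maximal packing itself: WINE = 1 by construction
  M <- piosphere:::pack_matrix(base)
  ens <- patefield_null(M, 200, seed = 7)
  wmax_matrix <- local({
    r <- sort(rowSums(M), decreasing = TRUE)
    cs <- sort(colSums(M), decreasing = TRUE)
    cl <- piosphere:::corner_closeness(length(r), length(cs))
    X <- matrix(0, length(r), length(cs))
    for (k in order(-as.vector(cl))) {
      i <- (k - 1) %% length(r) + 1; j <- (k - 1) %/% length(r) + 1
      a <- min(r[i], cs[j]); X[i, j] <- a; r[i] <- r[i] - a; cs[j] <- cs[j] - a
    }
    X
  })
  res <- wine(wmax_matrix, patefield_null(wmax_matrix, 200, seed = 8))
  expect_equal(res$wine, 1, tolerance = 1e-10)
  expect_lte(res$p, 0.05)

  # anti-diagonal checkerboard: anti-nested
  A <- matrix(0, 5, 5); A[cbind(1:5, 5:1)] <- 4
  res <- wine(A, patefield_null(A, 300, seed = 9))
  expect_lt(res$wine, 0)
  expect_lt(res$z, 0)
})

test_that("bipartite modularity Q matches hand evaluation and recomputation", {
  # block diagonal with matched partition: Q = 1/2 - 2 * (5*5)/(10*10) ... = 0.5
  M <- rbind(c(5, 0), c(0, 5))
  expect_equal(bipartite_modularity_Q(M, c(1, 2), c(1, 2)), 0.5)
  # everything in one module: Q = 0
  set.seed(2)
  R <- matrix(rpois(12, 3), 3, 4)
  expect_equal(bipartite_modularity_Q(R, rep(1, 3), rep(1, 4)), 0,
               tolerance = 1e-12)
  expect_error(bipartite_modularity_Q(R, c(1, 2), rep(1, 4)), "incomplete")

  fit <- optimize_modularity(R, restarts = 4, seed = 3)
  expect_equal(bipartite_modularity_Q(R, unname(fit$row_modules),
                                      unname(fit$column_modules)),
               fit$Q, tolerance = 1e-12)
})

test_that("the annealer attains the exhaustive optimum on small matrices", {
  set.seed(17)
  for (rep in 1:15) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    if (nr + nc > 8) nc <- 8 - nr
    M <- matrix(rpois(nr * nc, 2), nr, nc)
    if (sum(M) == 0) M[1, 1] <- 1
    q_star <- exhaustive_modularity_q(M)
    q_hat <- optimize_modularity(M, restarts = 10, seed = rep)$Q
    expect_equal(q_hat, q_star, tolerance = 1e-10)
  }
})

test_that("planted two-block partitions are recovered and runs are deterministic", {
  set.seed(29)
  M <- matrix(0, 10, 10)
  M[1:5, 1:5] <- rpois(25, 4); M[6:10, 6:10] <- rpois(25, 4)
  M <- M + matrix(rbinom(100, 1, 0.05), 10, 10)
  fit <- optimize_modularity(M, restarts = 10, seed = 1)
  rm_ <- unname(fit$row_modules); cm_ <- unname(fit$column_modules)
  expect_equal(length(unique(rm_[1:5])), 1)
  expect_equal(length(unique(rm_[6:10])), 1)
  expect_false(rm_[1] == rm_[6])
  expect_equal(cm_[1:5], rep(rm_[1], 5))
  expect_equal(cm_[6:10], rep(rm_[6], 5))

  fit2 <- optimize_modularity(M, restarts = 10, seed = 1)
  expect_identical(fit$Q, fit2$Q)
  expect_identical(fit$row_modules, fit2$row_modules)

  ens <- patefield_null(M, 60, seed = 4)
  sig <- modularity_significance(M, ens, restarts = 5, seed = 6)
  expect_lte(sig$p, 0.05)
  sig2 <- modularity_significance(M, ens, restarts = 5, seed = 6)
  expect_identical(sig$Q, sig2$Q)
  expect_identical(sig$q_null, sig2$q_null)
})

test_that("seasonal D-value permutation test matches an exhaustive oracle", {
  # identical seasons: p = 1 under the inclusive convention
  res <- seasonal_comparison(0.5, c(0.4, 0.6, 0.5), 0.5, c(0.4, 0.6, 0.5),
                             n_permutations = 500, seed = 1)
  expect_equal(res$p, 1)
  expect_equal(res$D_wet, c(-0.1, 0.1, 0))
  expect_equal(res$statistic, 0)

  # strong separation: tiny p
  set.seed(44)
  nw <- rnorm(200, 0, 1); nd <- rnorm(200, 5, 1)
  res <- seasonal_comparison(0, nw, 0, nd, n_permutations = 999, seed = 2)
  expect_lte(res$p, 0.001)

  # small-sample agreement with full enumeration
  for (rep in 1:5) {
    x <- rnorm(5); y <- rnorm(5, 0.5)
    res <- seasonal_comparison(0, x, 0, y, n_permutations = 19999, seed = rep)
    expect_lt(abs(res$p - exhaustive_permutation_p(x, y)), 0.02)
  }
  expect_warning(seasonal_comparison(0, rnorm(5), 0, rnorm(5),
                                     n_permutations = 50),
                 "100 permutations")
})
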