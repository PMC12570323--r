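test_that("eigenvalue modification matches direct formula evaluation", {
  expect_equal(modify_eigenvalues(c(5, 1, 0.9, 0.1), m = 4, l = 1),
               c(5 - 2 / 4, 0, 0, 0))
  expect_equal(modify_eigenvalues(c(5, 1, 0.9, 0.1), m = 4, l = 1,
                                  denominator = "tail_mean"),
               c(5 - 2 / 3, 0, 0, 0))
  # empty tail subtracts nothing
  expect_equal(modify_eigenvalues(c(3, 0, 0), l = 1), c(3, 0, 0))
  expect_error(modify_eigenvalues(c(1, 2), l = 1), "non-increasing")
  expect_error(modify_eigenvalues(c(2, 1), l = 3), "1 <= l <= m")
  # a flat spectrum under the tail-mean denominator hits the zero floor
  expect_warning(
    lt_flat <- modify_eigenvalues(c(1, 1, 1, 1), l = 2,
                                  denominator = "tail_mean"),
    "floored")
  expect_equal(lt_flat, rep(0, 4))
})

test_that("lambda_tilde <= lambda with equality iff the tail is zero", {
  withr::with_seed(4, {
    for (rep in 1:20) {
      lam <- sort(rexp(12, 0.2), decreasing = TRUE)
      l <- sample(1:12, 1)
      lt <- suppressWarnings(modify_eigenvalues(lam, l = l))
      expect_true(all(lt[seq_len(l)] <= lam[seq_len(l)] + 1e-12))
      expect_true(all(lt[-seq_len(l)] == 0))
    }
  })
  lt <- modify_eigenvalues(c(7, 5, 0, 0), l = 2)
  expect_equal(lt[2], 5)  # zero tail beyond i = 2: untouched
  expect_lt(lt[1], 7)
})

test_that("essential dimension follows the residual-mass rule", {
  expect_identical(essential_dimension(c(5, 1, 0.9, 0.1), d = 4), 1L)
  # flat unit spectrum satisfies the rule already at k = 0: clamped
  expect_warning(l0 <- essential_dimension(rep(1, 6), d = 6), "degenerate")
  expect_identical(l0, 1L)
  # brute-force scan oracle on a spiked spectrum over a near-unit noise floor
  lam <- c(10, 9, 8, rep(0.97, 97))
  d <- 100
  brute <- min(which(sapply(0:100, function(k)
    sum(lam[seq_along(lam) > k]) <= d - k)) - 1L)
  expect_identical(essential_dimension(lam, d), as.integer(brute))
  expect_identical(brute, 3L)
})

test_that("eigenvector modification keeps the largest components", {
  U <- cbind(c(0.5, 0.5, 0.5, 0.5))
  got <- modify_eigenvectors(U, lambda = 1, lambda_mod = 0.6, l_star = 1)
  expect_equal(got[, 1], c(1 / sqrt(2), 1 / sqrt(2), 0, 0))
  # ratio 1: full retention, unchanged
  U2 <- cbind(c(0.8, 0.6, 0) / 1)
  expect_equal(modify_eigenvectors(U2, 1, 1, 1), U2)
  # k_i floored at 1
  expect_equal(modify_eigenvectors(U2, 1, 0.5, 1)[, 1], c(1, 0, 0))
  # unit norm always
  withr::with_seed(8, {
    u <- rnorm(30); u <- u / sqrt(sum(u^2))
    for (ratio in c(0.2, 0.5, 0.9)) {
      v <- modify_eigenvectors(cbind(u), 1, ratio, 1)[, 1]
      expect_equal(sum(v^2), 1, tolerance = 1e-12)
      expect_lte(sum(v != 0), sum(u != 0))
    }
  })
})

test_that("full decomposition satisfies the trace identity and orthonormality", {
  sim <- generate_spiked(80, 60, c(12, 9), seed = 2)
  sp <- eigendecompose(sim$values)
  expect_equal(sum(sp$eigenvalues), sp$total_variance, tolerance = 1e-8)
  expect_equal(crossprod(sp$eigenvectors[, 1:10]), diag(10),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(sp$eigenvalues) <= 1e-8))
  # identical columns: degenerate covariance
  flat <- matrix(rep(1:5, 4), 5, 4)
  expect_warning(sp0 <- eigendecompose(flat), "degenerate")
  expect_identical(sp0$essential_dim, 1L)
  expect_equal(sp0$modified_eigenvalues, rep(0, sp0$m))
})

test_that("truncated path reproduces the full decomposition", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      sim <- generate_spiked(sample(100:250, 1), sample(100:250, 1),
                             spikes = c(14, 11, 9), seed = rep + 30)
      full <- eigendecompose(sim$values)
      fast <- eigendecompose(sim$values, fast = TRUE, l_hint = 8)
      expect_true(fast$fast)
      expect_identical(fast$essential_dim, full$essential_dim)
      l <- full$essential_dim
      expect_equal(fast$modified_eigenvalues[1:l],
                   full$modified_eigenvalues[1:l], tolerance = 1e-8)
      expect_equal(fast$total_variance, full$total_variance,
                   tolerance = 1e-10)
      # principal angles between leading subspaces
      s <- svd(crossprod(full$eigenvectors[, 1:l, drop = FALSE],
                         fast$eigenvectors[, 1:l, drop = FALSE]))$d
      expect_true(all(acos(pmin(s, 1)) < 1e-6))
    }
  })
})

test_that("v2 modifies only the leading columns and keeps orthonormal norms", {
  sim <- generate_spiked(60, 90, c(10, 8), seed = 6)
  sp <- eigendecompose(sim$values, variant = "v2")
  l <- sp$essential_dim
  for (i in seq_len(l))
    expect_equal(sum(sp$modified_eigenvectors[, i]^2), 1, tolerance = 1e-10)
  expect_equal(sp$modified_eigenvectors[, -(seq_len(l))],
               sp$eigenvectors[, -(seq_len(l))])
})

test_that("a fitted spectral model serializes to a flat-file bundle", {
  sim <- generate_spiked(40, 50, c(9), seed = 1)
  sp <- eigendecompose(sim$values)
  dir <- withr::local_tempdir()
  write_spectral_model(sp, file.path(dir, "model"))
  ev <- read.table(file.path(dir, "model", "eigenvalues.tsv"), header = TRUE)
  expect_equal(ev$eigenvalue, sp$eigenvalues, tolerance = 1e-6)
  U <- as.matrix(read.table(file.path(dir, "model", "U.tsv"), header = TRUE))
  expect_equal(ncol(U), sp$essential_dim)
})
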