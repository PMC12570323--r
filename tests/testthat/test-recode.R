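test_that("fit is deterministic and downsampling respects the config", {
  sim <- generate_pure_noise(40, 120, seed = 2)
  cfg <- recode_config(downsample_threshold = 100, seed = 3)
  m1 <- suppressWarnings(recode_fit(sim$counts, cfg))
  m2 <- suppressWarnings(recode_fit(sim$counts, cfg))
  expect_length(m1$fit_cells, ceiling(0.2 * 120))
  expect_identical(m1$fit_cells, m2$fit_cells)
  # fraction 1 disables downsampling entirely
  mfull <- suppressWarnings(
    recode_fit(sim$counts, recode_config(downsample_fraction = 1,
                                         downsample_threshold = 100)))
  expect_length(mfull$fit_cells, 120L)
  expect_error(
    recode_fit(sim$counts, recode_config(downsample_fraction = 0.05,
                                         downsample_threshold = 100)),
    "fewer than 10")
})

test_that("the transform factorizes exactly and preserves structure", {
  sim <- generate_celltype_batches(150, 200, seed = 5)
  model <- recode_fit(sim$counts)
  out <- rc_apply(model, sim$counts)
  # factorization identity, bitwise
  expect_identical(out, rc_inv(model, rc_ess(model, sim$counts)))
  # shape and ids preserved
  expect_identical(dim(out), dim(sim$counts$values))
  expect_identical(rownames(out), sim$counts$feature_ids)
  expect_identical(colnames(out), sim$counts$cell_ids)
  # essential matrix has l* rows
  e <- rc_ess(model, sim$counts)
  expect_identical(nrow(e$values), model$spectral$essential_dim)
  # gene-wise NVSN mean preservation
  y_out <- nvsn_forward(model$nvsn, out)
  expect_equal(unname(rowMeans(y_out)), unname(model$spectral$gene_means),
               tolerance = 1e-8)
  # undetected gene rows stay zero
  v <- as_dense(sim$counts); v[3, ] <- 0
  cm0 <- count_matrix(v)
  m0 <- recode_fit(cm0)
  expect_equal(unname(rc_apply(m0, cm0)[3, ]), rep(0, ncol(v)))
})

test_that("essential-space row variances equal the modified eigenvalues", {
  sim <- generate_celltype_batches(150, 200, seed = 7)
  model <- recode_fit(sim$counts)
  e <- rc_ess(model, sim$counts)
  l <- model$spectral$essential_dim
  expect_equal(unname(apply(e$values, 1, stats::var)),
               model$spectral$modified_eigenvalues[seq_len(l)],
               tolerance = 1e-8)
  # cells at the fit mean profile map to the zero essential matrix
  y_mean <- model$spectral$gene_means
  x_mean <- nvsn_inverse(model$nvsn, matrix(y_mean, length(y_mean), 3),
                         cell_totals = rep(1000, 3))
  e0 <- rc_ess(model, x_mean, cell_totals = rep(1000, 3))
  expect_equal(max(abs(e0$values)), 0, tolerance = 1e-8)
})

test_that("reconstruction of the zero essential matrix is the mean profile", {
  sim <- generate_celltype_batches(120, 150, seed = 8)
  model <- recode_fit(sim$counts)
  e <- rc_ess(model, sim$counts)
  e$values[] <- 0
  out <- rc_inv(model, e)
  y <- nvsn_forward(model$nvsn, out)
  expect_equal(y, matrix(model$spectral$gene_means, nrow(y), ncol(y)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("identical columns are returned unchanged", {
  v <- matrix(rep(c(3, 1, 4, 1, 5), 6), 5, 6)
  cm <- count_matrix(v)
  model <- suppressWarnings(recode_fit(cm))
  expect_equal(unname(rc_apply(model, cm)), v, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("negative entries are counted and optionally clipped", {
  sim <- generate_celltype_batches(150, 200, seed = 9)
  model <- recode_fit(sim$counts)
  out <- rc_apply(model, sim$counts)
  expect_identical(attr(out, "n_negative"), sum(out < 0))
  model_c <- recode_fit(sim$counts, recode_config(clip_negative = TRUE))
  out_c <- rc_apply(model_c, sim$counts)
  expect_gte(min(out_c), 0)
})

test_that("denoising beats raw data against the simulation truth", {
  wins <- vapply(1:5, function(seed) {
    sim <- generate_celltype_batches(200, 250, seed = seed)
    model <- recode_fit(sim$counts)
    out <- rc_apply(model, sim$counts)
    raw <- as_dense(sim$counts)
    tj <- colSums(raw)
    mse <- function(m) mean((sweep(m, 2, tj, "/") - sim$truth$true_rates)^2)
    mse(out) < mse(raw)
  }, logical(1))
  expect_true(all(wins))
})

test_that("a downsample-learned model applied to full data tracks the full fit", {
  sim <- generate_celltype_batches(150, 1500, seed = 10)
  m_ds <- recode_fit(sim$counts, recode_config(downsample_threshold = 1000,
                                               seed = 4))
  m_full <- recode_fit(sim$counts)
  expect_length(m_ds$fit_cells, 300L)
  r <- cor(rowMeans(rc_apply(m_ds, sim$counts)),
           rowMeans(rc_apply(m_full, sim$counts)))
  expect_gt(r, 0.99)
})

test_that("v2 sparsifies eigenvectors while tracking the original output", {
  sim <- generate_celltype_batches(150, 200, seed = 11)
  m_v2 <- recode_fit(sim$counts, recode_config(variant = "v2"))
  expect_identical(m_v2$variant, "v2")
  sp <- m_v2$spectral
  l <- sp$essential_dim
  nz_mod <- colSums(sp$modified_eigenvectors[, 1:l, drop = FALSE] != 0)
  nz_orig <- colSums(sp$eigenvectors[, 1:l, drop = FALSE] != 0)
  expect_true(all(nz_mod <= nz_orig))
  out <- rc_apply(m_v2, sim$counts)
  expect_identical(dim(out), dim(sim$counts$values))
})
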