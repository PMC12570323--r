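test_that("feature counts follow the closed form and enumeration", {
  sc <- build_scheme(c(chr1 = 5e6), resolution = 1e6, max_distance = 2e6)
  expect_identical(sc$n_features, 12L)  # 5 + 4 + 3
  # diagonal-only scheme
  sc0 <- build_scheme(c(chr1 = 5e6), resolution = 1e6, max_distance = 0)
  expect_identical(sc0$n_features, 5L)
  # closed form L*(D+1) - D*(D+1)/2 vs brute-force enumeration
  for (L in c(3, 7, 20, 50)) for (D in c(0, 1, 4, 10)) {
    if (L <= D) next
    sc_ld <- build_scheme(stats::setNames(L * 1e6, "c"), 1e6, D * 1e6)
    expect_identical(sc_ld$n_features,
                     as.integer(L * (D + 1) - D * (D + 1) / 2))
    expect_identical(sc_ld$n_features, ref_feature_count(L, D))
  }
  # diagonal excluded
  sc_nd <- build_scheme(c(chr1 = 5e6), 1e6, 2e6, include_diagonal = FALSE)
  expect_identical(sc_nd$n_features, 7L)  # 4 + 3
  expect_identical(ref_feature_count(5, 2, FALSE), 7L)
  expect_error(build_scheme(c(chr1 = 0), 1e6, 1e7), "zero-length")
})

test_that("the index map is a bijection with deterministic ordering", {
  sc <- build_scheme(c(chrA = 4e6, chrB = 3e6), 1e6, 2e6)
  f <- sc$features
  # round trip index -> pair -> index
  idx <- pair_to_index(sc, f$chrom, f$bin_i, f$bin_j)
  expect_identical(idx, seq_len(sc$n_features))
  expect_identical(anyDuplicated(f), 0L)
  # ordering: chromosome blocks, bin ascending, distance ascending
  expect_identical(unique(f$chrom), c("chrA", "chrB"))
  expect_true(all(diff(order(match(f$chrom, c("chrA", "chrB")),
                             f$bin_i, f$bin_j - f$bin_i)) == 1))
  # unordered pair normalized
  expect_identical(pair_to_index(sc, "chrA", 3, 1),
                   pair_to_index(sc, "chrA", 1, 3))
  # out of band -> NA
  expect_true(is.na(pair_to_index(sc, "chrA", 0, 3)))
})

test_that("vectorization places, sums, symmetrizes and drops correctly", {
  sc <- build_scheme(c(chr1 = 5e6), 1e6, 2e6)
  one <- list(cellA = data.frame(chrom = "chr1", bin_i = 0, bin_j = 1,
                                 count = 3))
  cm <- vectorize_contacts(one, sc)
  v <- as_dense(cm)[, 1]
  expect_identical(sum(v != 0), 1L)
  expect_equal(v[[pair_to_index(sc, "chr1", 0, 1)]], 3)
  # unordered pair (4,2) -> (2,4); duplicates summed
  two <- list(c1 = data.frame(chrom = "chr1", bin_i = c(4, 2), bin_j = c(2, 4),
                              count = c(1, 2)))
  v2 <- as_dense(vectorize_contacts(two, sc))[, 1]
  expect_equal(v2[[pair_to_index(sc, "chr1", 2, 4)]], 3)
  # beyond-cutoff and inter-chromosomal records dropped with a counter
  drop <- list(c1 = data.frame(chrom = c("chr1", "chr9"), bin_i = c(0, 0),
                               bin_j = c(4, 1), count = c(5, 5)),
               c2 = data.frame(chrom = "chr1", bin_i = 1, bin_j = 2,
                               count = 1))
  cm3 <- vectorize_contacts(drop, sc)
  expect_identical(attr(cm3, "n_dropped"), 2L)
  # out-of-range bin is an error
  expect_error(vectorize_contacts(
    list(x = data.frame(chrom = "chr1", bin_i = 0, bin_j = 9, count = 1)), sc),
    "outside")
})

test_that("devectorize mirrors in-band entries and round-trips exactly", {
  sc <- build_scheme(c(chrA = 6e6, chrB = 4e6), 1e6, 3e6)
  withr::with_seed(3, v <- rpois(sc$n_features, 2))
  maps <- devectorize(v, sc)
  expect_named(maps, c("chrA", "chrB"))
  for (m in maps) expect_equal(m, t(m))
  # a specific entry appears at both (i, j) and (j, i)
  k <- pair_to_index(sc, "chrA", 1, 3)
  expect_equal(maps$chrA[2, 4], v[[k]])
  expect_equal(maps$chrA[4, 2], v[[k]])
  # rebuild contact records from the maps and re-vectorize
  f <- sc$features
  rec <- data.frame(chrom = f$chrom, bin_i = f$bin_i, bin_j = f$bin_j,
                    count = v)
  back <- as_dense(vectorize_contacts(list(c1 = rec[rec$count > 0, ]), sc))[, 1]
  expect_equal(unname(back), v)
  expect_equal(unname(devectorize(numeric(sc$n_features), sc)$chrA),
               matrix(0, 6, 6))
  expect_error(devectorize(v[-1], sc), "length")
})

test_that("manifest-driven reading converts bp positions when asked", {
  dir <- withr::local_tempdir()
  write.table(data.frame(chrom = "chr1", p1 = c(0, 2500000),
                         p2 = c(1500000, 2700000), n = c(2, 4)),
              file.path(dir, "cell1.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines("cellX\tcell1.tsv", file.path(dir, "manifest.tsv"))
  cells <- read_contacts(file.path(dir, "manifest.tsv"), resolution = 1e6,
                         positions = TRUE)
  expect_identical(names(cells), "cellX")
  expect_equal(cells$cellX$bin_i, c(0, 2))
  expect_equal(cells$cellX$bin_j, c(1, 2))
})

test_that("log-normalization matches the closed form", {
  expect_equal(unname(log_normalize(matrix(1, 2, 2), scale = 1)),
               matrix(log(1.5), 2, 2))
  # zeros stay zero; monotone in the entry for fixed totals
  x <- rbind(c(0, 4), c(2, 1))
  ln <- log_normalize(x, scale = 10)
  expect_equal(ln[1, 1], 0)
  expect_true(ln[1, 2] > ln[2, 2])
  expect_error(log_normalize(matrix(c(-1, 2, 2, 2), 2)), "negative")
})
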