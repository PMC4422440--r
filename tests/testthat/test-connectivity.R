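# Cross-correlation profile construction: downsampling, Pearson profiles,
# Fisher-Z, group averaging.

make_grid_matrix <- function(counts, dim3, cell_mm = 2) {
  connectivity_matrix(counts,
                      target_grid = list(dim = dim3,
                                         affine = diag(c(cell_mm, cell_mm, cell_mm, 1)),
                                         cell_mm = cell_mm),
                      participant_id = "t")
}

test_that("target downsampling sums non-overlapping blocks and conserves rows", {
  m <- make_grid_matrix(matrix(1, nrow = 3, ncol = 64), c(4, 4, 4))
  d <- downsample_targets(m, 4)
  expect_identical(d$target_grid$dim, c(2L, 2L, 2L))
  expect_equal(dim(d$counts), c(3, 8))
  expect_true(all(d$counts == 8))  # 2x2x2 source blocks of ones

  set.seed(1)
  m2 <- make_grid_matrix(matrix(rpois(5 * 64, 3), nrow = 5), c(4, 4, 4))
  d2 <- downsample_targets(m2, 4)
  expect_equal(rowSums(d2$counts), rowSums(m2$counts))
  # identity block: same cell size returns the input unchanged
  expect_identical(downsample_targets(m2, 2)$counts, m2$counts)
  expect_error(downsample_targets(m2, 3), "not a positive multiple")
})

test_that("cross-correlation matches hand-computed Pearson values", {
  counts <- rbind(c(1, 2, 4), c(2, 2, 5), c(3, 2, 1), c(1, 2, 3))
  p <- cross_correlate(connectivity_matrix(counts))
  expect_equal(p$values[1, 2], 5 / sqrt(28), tolerance = 1e-12)  # 0.9449
  expect_equal(p$values[3, 4], -1, tolerance = 1e-12)            # anti-linear rows
  expect_equal(p$values[1, 1], 1)
  expect_true(isSymmetric(p$values))
  # identical rows correlate perfectly
  p2 <- cross_correlate(connectivity_matrix(rbind(c(1, 5, 2), c(1, 5, 2))))
  expect_equal(p2$values[1, 2], 1, tolerance = 1e-12)
})

test_that("zero-variance seed rows raise a policy error naming the voxels, and drop mode removes them", {
  counts <- rbind(c(1, 2, 3), c(4, 4, 4), c(2, 1, 5))
  m <- connectivity_matrix(counts)
  expect_error(cross_correlate(m), "voxels 2")
  p <- cross_correlate(m, zero_variance = "drop")
  expect_identical(p$dropped, 2L)
  expect_equal(nrow(p$values), 2)
})

test_that("Pearson profiles are invariant to per-row affine rescaling", {
  set.seed(42)
  counts <- matrix(rpois(6 * 30, 10), nrow = 6)
  base <- cross_correlate(connectivity_matrix(counts))$values
  scaled <- counts * 3 + 7
  resc <- cross_correlate(connectivity_matrix(scaled))$values
  expect_equal(resc, base, tolerance = 1e-12)
  # and to permuting target cells
  perm <- counts[, sample(ncol(counts))]
  expect_equal(cross_correlate(connectivity_matrix(perm))$values, base,
               tolerance = 1e-12)
})

test_that("Fisher-Z is the clipped arctanh: fixed point, closed form, finiteness", {
  r <- matrix(c(1, 0.5, 0, 0.5, 1, -0.25, 0, -0.25, 1), 3)
  p <- structure(list(values = r, transform = "raw_r", n_averaged = 1L,
                      seed_index = NULL, dropped = integer(0)),
                 class = "correlation_profile")
  z <- fisher_z(p, clip_epsilon = 1e-6)
  expect_equal(z$values[1, 2], atanh(0.5), tolerance = 1e-12)  # 0.5493
  expect_equal(z$values[1, 3], 0)
  expect_equal(z$values[1, 1], atanh(1 - 1e-6))
  expect_true(all(is.finite(z$values)))
  expect_error(fisher_z(z), "already transformed")
  # strictly increasing and odd on a grid
  grid <- seq(-0.95, 0.95, by = 0.05)
  zg <- atanh(pmin(pmax(grid, -1 + 1e-7), 1 - 1e-7))
  expect_true(all(diff(zg) > 0))
  expect_equal(zg, -rev(zg), tolerance = 1e-12)
})

test_that("group averaging is the entrywise mean of Fisher-Z profiles", {
  mk <- function(v) {
    vals <- matrix(c(0, v, v, 0), 2)
    structure(list(values = vals, transform = "fisher_z", n_averaged = 1L,
                   seed_index = NULL, dropped = integer(0)),
              class = "correlation_profile")
  }
  one <- average_group(list(mk(0.4)))
  expect_equal(one$values[1, 2], 0.4)
  expect_identical(one$n_averaged, 1L)
  expect_equal(average_group(list(mk(0.3), mk(-0.3)))$values[1, 2], 0)
  avg <- average_group(list(mk(0.1), mk(0.2), mk(0.6)))
  expect_equal(avg$values[1, 2], 0.3, tolerance = 1e-12)
  expect_identical(avg$n_averaged, 3L)
  raw <- structure(list(values = matrix(0, 2, 2), transform = "raw_r",
                        n_averaged = 1L, seed_index = NULL, dropped = integer(0)),
                   class = "correlation_profile")
  expect_error(average_group(list(mk(0.1), raw)), "Fisher-Z")
})

test_that("downsampling then correlating is invariant to target-cell order", {
  set.seed(7)
  m <- make_grid_matrix(matrix(rpois(5 * 64, 4), nrow = 5), c(4, 4, 4))
  r1 <- cross_correlate(downsample_targets(m, 4))$values
  # permute source cells within the matrix: correlation over targets is
  # order-free, and block sums only reorder
  r2 <- cross_correlate(connectivity_matrix(
    downsample_targets(m, 4)$counts[, sample(8)]))$values
  expect_equal(r2, r1, tolerance = 1e-12)
})
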