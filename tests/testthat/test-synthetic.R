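# Synthetic generator: planted labels, group simulation, hemisphere
# mirroring, determinism and noise monotonicity.

test_that("planted labels satisfy their contract", {
  # pigeonhole: as many parcels as voxels forces a bijection
  cfg4 <- synthetic_config(n_seed_voxels = 4, k_true = 4, n_targets = 10)
  expect_setequal(make_planted_labels(cfg4)$labels, 1:4)

  cfg <- synthetic_config(n_seed_voxels = 100, k_true = 4, rng_seed = 7)
  l1 <- make_planted_labels(cfg)$labels
  l2 <- make_planted_labels(cfg)$labels
  expect_identical(l1, l2)              # deterministic given the seed
  expect_setequal(unique(l1), 1:4)      # all parcels populated
  expect_true(max(table(l1)) - min(table(l1)) <= 1)  # balanced sizes

  expect_error(synthetic_config(n_seed_voxels = 3, k_true = 4), "exceeds")
})

test_that("hierarchy split plants a child layer with a parent map", {
  cfg <- synthetic_config(n_seed_voxels = 60, k_true = 4,
                          hierarchy_split = c(2, 3), rng_seed = 3)
  truth <- make_planted_labels(cfg)
  expect_length(truth$parent_map, 6)  # 4 parcels, parcel 2 -> 3 children
  expect_setequal(unique(truth$child_labels), 1:6)
  # each child maps to exactly one parent, and the split children map to 2
  expect_identical(truth$parent_map[c(2, 5, 6)], rep(2L, 3))
  # children partition exactly the parent's voxels
  expect_identical(which(truth$labels == 2),
                   which(truth$child_labels %in% c(2, 5, 6)))
})

test_that("zero-noise rows are identical within a parcel, and signal-free rows everywhere", {
  cfg <- synthetic_config(n_participants = 2, n_seed_voxels = 12, n_targets = 30,
                          k_true = 3, noise_scale = 0, rng_seed = 9)
  truth <- make_planted_labels(cfg)
  mats <- simulate_group(cfg, truth)
  m <- mats[[1]]$counts
  for (p in 1:3) {
    rows <- m[truth$labels == p, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  cfg0 <- synthetic_config(n_participants = 2, n_seed_voxels = 12, n_targets = 30,
                           k_true = 3, fingerprint_scale = 0, noise_scale = 0,
                           baseline = 10, rng_seed = 9)
  m0 <- simulate_group(cfg0, make_planted_labels(cfg0))[[1]]$counts
  expect_true(all(m0 == m0[1, 1]))
})

test_that("within-parcel correlation exceeds between-parcel correlation at high signal", {
  cfg <- synthetic_config(n_participants = 4, n_seed_voxels = 40, n_targets = 100,
                          k_true = 4, fingerprint_scale = 5, noise_scale = 1,
                          rng_seed = 21)
  truth <- make_planted_labels(cfg)
  mats <- simulate_group(cfg, truth)
  same <- outer(truth$labels, truth$labels, "==")
  diag(same) <- NA
  for (m in mats) {
    r <- cor(t(m$counts))
    expect_gt(mean(r[which(same)]), mean(r[which(!same)]))
  }
})

test_that("generated matrices are nonnegative, finite, and bit-reproducible", {
  cfg <- synthetic_config(n_participants = 3, n_seed_voxels = 20, n_targets = 40,
                          rng_seed = 13)
  a <- simulate_group(cfg)
  b <- simulate_group(cfg)
  for (s in seq_along(a)) {
    expect_true(all(is.finite(a[[s]]$counts)))
    expect_true(all(a[[s]]$counts >= 0))
    expect_identical(a[[s]]$counts, b[[s]]$counts)
  }
})

test_that("hemisphere pair relabels exactly the stated fraction, always to a different parcel", {
  cfg <- synthetic_config(n_seed_voxels = 100, k_true = 4, symmetry_level = 0.8,
                          rng_seed = 31)
  pair <- simulate_hemisphere_pair(cfg)
  changed <- sum(pair$left$labels != pair$right$labels)
  expect_identical(changed, 20L)
  expect_identical(pair$left$mirrored_labels, pair$right$labels)

  cfg1 <- synthetic_config(n_seed_voxels = 100, k_true = 4, symmetry_level = 1,
                           rng_seed = 31)
  p1 <- simulate_hemisphere_pair(cfg1)
  expect_identical(p1$left$labels, p1$right$labels)

  cfg0 <- synthetic_config(n_seed_voxels = 100, k_true = 4, symmetry_level = 0,
                           rng_seed = 31)
  p0 <- simulate_hemisphere_pair(cfg0)
  expect_true(all(p0$left$labels != p0$right$labels))
})

test_that("recovered parcellation agreement does not improve as noise grows", {
  noise_levels <- c(0.5, 1, 2, 4, 8)
  agree <- sapply(noise_levels, function(ns) {
    mean(sapply(1:20, function(rep_i) {
      cfg <- synthetic_config(n_participants = 4, n_seed_voxels = 24,
                              n_targets = 60, k_true = 4, fingerprint_scale = 2,
                              noise_scale = ns, rng_seed = 700 + rep_i)
      truth <- make_planted_labels(cfg)
      g <- average_group(lapply(simulate_group(cfg, truth),
                                function(m) fisher_z(cross_correlate(m))))
      p <- kmeans_replicates(g, 4, n_replicates = 20, rng_seed = rep_i)
      attr(match_labels(truth$labels, p$labels), "overlap") / 24
    }))
  })
  # means over 20 replicates; small tolerance for Monte-Carlo jitter
  expect_true(all(diff(agree) <= 0.03))
  expect_gt(agree[1], agree[length(agree)])
})

test_that("synthetic geometry mirrors onto itself across the midline", {
  left <- synthetic_seed_geometry(30, "left")
  right <- synthetic_seed_geometry(30, "right")
  expect_identical(left$voxels, right$voxels)
  wl <- voxel_world_coords(left)
  wr <- voxel_world_coords(right)
  expect_equal(wl[, 1], -wr[, 1])
  expect_equal(wl[, 2:3], wr[, 2:3])
  expect_true(all(wl[, 1] < 0))
})
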