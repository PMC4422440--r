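# Information-theoretic metrics, split-half resampling, the optimal-K rule,
# hierarchy and symmetry indices.

test_that("entropy matches hand-evaluated cluster-size distributions", {
  expect_equal(cluster_entropy(rep(1, 6)), 0)
  expect_equal(cluster_entropy(c(1, 1, 2, 2)), log10(2), tolerance = 1e-12)
  expect_equal(cluster_entropy(c(1, 2, 3, 3)),
               2 * 0.25 * log10(4) + 0.5 * log10(2), tolerance = 1e-12)  # 0.4515
  expect_equal(cluster_entropy(c(1, 1, 2, 2), log_base = 2), 1, tolerance = 1e-12)
})

test_that("mutual information matches hand-evaluated joint tables", {
  c1 <- c(1, 1, 2, 2)
  expect_equal(mutual_information(c1, c1), cluster_entropy(c1), tolerance = 1e-12)
  expect_equal(mutual_information(c1, c(1, 2, 1, 2)), 0, tolerance = 1e-12)
  expect_equal(mutual_information(c1, c(1, 2, 3, 3)), log10(2), tolerance = 1e-12)
  expect_error(mutual_information(c1, c(1, 2)), "different numbers")
})

test_that("variation of information matches hand-derived values", {
  c1 <- c(1, 1, 2, 2)
  expect_equal(variation_of_information(c1, c1), 0)
  expect_equal(variation_of_information(c1, c(2, 2, 1, 1)), 0)  # relabeled
  expect_equal(variation_of_information(c1, c(1, 2, 1, 2)), 2 * log10(2),
               tolerance = 1e-12)  # 0.6021
  # refinement: VI equals the entropy difference
  c2 <- c(1, 2, 3, 3)
  expect_equal(variation_of_information(c1, c2),
               cluster_entropy(c2) - cluster_entropy(c1), tolerance = 1e-12)
})

test_that("VI is a metric on all partitions of a 5-element set", {
  parts <- all_set_partitions(5)
  expect_length(parts, 52)  # Bell(5)
  np <- length(parts)
  vi <- matrix(0, np, np)
  for (i in 1:np) for (j in 1:np)
    vi[i, j] <- variation_of_information(parts[[i]], parts[[j]])
  expect_true(all(vi >= 0))
  expect_equal(vi, t(vi), tolerance = 1e-12)
  # identity of indiscernibles: canonical partitions are pairwise distinct
  expect_true(all((vi < 1e-12) == diag(np)))
  # triangle inequality over all ordered triples
  ok <- TRUE
  for (i in 1:np) for (j in 1:np)
    if (any(vi[i, j] > vi[i, ] + vi[, j] + 1e-9)) ok <- FALSE
  expect_true(ok)
})

test_that("VI and MI respect their entropy bounds on random partitions", {
  set.seed(19)
  n <- 93
  for (i in 1:30) {
    a <- rand_partition(n, 8)
    b <- rand_partition(n, 8)
    h1 <- cluster_entropy(a); h2 <- cluster_entropy(b)
    mi <- mutual_information(a, b)
    vi <- variation_of_information(a, b)
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(h1, h2) + 1e-12)
    expect_lte(vi, h1 + h2 + 1e-12)
    expect_lte(vi, vi_upper_bound(n) + 1e-12)
  }
})

test_that("metrics are invariant under label permutation", {
  set.seed(23)
  a <- rand_partition(50, 6)
  b <- rand_partition(50, 6)
  perm <- sample(max(b))
  b2 <- perm[b]
  expect_equal(variation_of_information(a, b2), variation_of_information(a, b),
               tolerance = 1e-12)
  expect_equal(mutual_information(a, b2), mutual_information(a, b),
               tolerance = 1e-12)
})

test_that("split-half VI is zero for duplicated participants and reproducible", {
  # all participants identical: any half-split averages to the same profile
  one <- small_profiles(n_participants = 1, n_voxels = 16, n_targets = 40,
                        seed = 2)$profiles[[1]]
  clones <- rep(list(one), 6)
  cv <- split_half_vi(clones, 2:4, n_repetitions = 5, n_replicates = 20,
                      rng_seed = 3)
  expect_true(all(cv$rep_vi == 0))
  sp <- small_profiles(n_participants = 8, n_voxels = 24, seed = 4)
  cv1 <- split_half_vi(sp$profiles, 2:4, n_repetitions = 6, n_replicates = 15,
                       rng_seed = 11)
  cv2 <- split_half_vi(sp$profiles, 2:4, n_repetitions = 6, n_replicates = 15,
                       rng_seed = 11)
  expect_identical(cv1$rep_vi, cv2$rep_vi)
  expect_identical(cv1$p, cv2$p)
  expect_error(split_half_vi(sp$profiles, 3:5, 5, 5), "start at 2")
  expect_error(split_half_vi(sp$profiles[1], 2:3, 5, 5), "at least 2")
})

test_that("the optimal-K rule reads the paired tests as specified", {
  mk_curve <- function(p) {
    structure(list(k = as.integer(seq(2, length.out = length(p) + 1)), p = c(NA, p),
                   mean_vi = rep(0.1, length(p) + 1),
                   rep_vi = matrix(0, 2, length(p) + 1)), class = "vi_curve")
  }
  # significant increase at every step: largest K, flagged
  r <- select_optimal_k(mk_curve(c(0.001, 0.002, 0.0005)))
  expect_identical(r$k, 5L)
  expect_true(r$no_selection)
  # significant at 3,4,5; decrease (p ~ 1) at 6
  r2 <- select_optimal_k(mk_curve(c(0.001, 0.01, 0.001, 0.999)))
  expect_identical(r2$k, 6L)
  expect_false(r2$no_selection)
  # first eligible K wins
  expect_identical(select_optimal_k(mk_curve(c(0.2, 0.001)))$k, 3L)
  # alpha is respected
  expect_identical(select_optimal_k(mk_curve(c(0.03, 0.9)), alpha = 0.01)$k, 3L)
})

test_that("hierarchy index is 1 for nesting, errors on bad K, matches the hand tally", {
  expect_equal(hierarchy_index(c(1, 1, 2, 2, 2), c(1, 1, 2, 2, 3)), 1)
  expect_error(hierarchy_index(c(1, 1, 2, 2, 2), c(1, 2, 1, 2, 2)),
               "one more cluster")
  expect_equal(hierarchy_index(c(1, 1, 2, 2, 2, 2), c(1, 3, 1, 2, 2, 3)), 2 / 3,
               tolerance = 1e-12)
  # relabeling either side changes nothing
  expect_equal(hierarchy_index(c(2, 2, 1, 1, 1, 1), c(3, 1, 3, 2, 2, 1)), 2 / 3,
               tolerance = 1e-12)
})

test_that("hierarchy index is 1 on generated nested splits and bounded below", {
  set.seed(29)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    kp <- sample(2:5, 1)
    parent <- sample(c(1:kp, sample.int(kp, n - kp, replace = TRUE)))
    # split a parent cluster with >= 2 members into two children
    sizes <- table(parent)
    target <- as.integer(names(sizes)[sizes >= 2][1])
    child <- parent
    members <- which(parent == target)
    half <- members[seq_len(floor(length(members) / 2))]
    child[half] <- kp + 1L
    expect_equal(hierarchy_index(parent, child), 1)
    hp <- hierarchy_profile(list(parent, child))
    expect_equal(hp$hierarchy_index, 1)
    expect_gte(hierarchy_index(parent, child), 1 / kp)
  }
})

test_that("symmetry index is 1 for mirrored parcellations and 0.5 on the balanced toy", {
  maskL <- synthetic_seed_geometry(12, "left")
  maskR <- synthetic_seed_geometry(12, "right")
  ll <- rep(c(1L, 2L), each = 6)
  s1 <- symmetry_index(ll, ll, maskL, maskR)
  expect_equal(s1$symmetry, 1)
  expect_equal(s1$overlap_n, 12)
  # contingency [[3,3],[3,3]]: either assignment agrees on 6 of 12
  lr <- c(1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(symmetry_index(ll, lr, maskL, maskR)$symmetry, 0.5)
})

test_that("split-half VI at planted k_true drops below its neighbors", {
  sp <- small_profiles(n_participants = 12, n_voxels = 32, n_targets = 80,
                       k_true = 4, seed = 6)
  cv <- split_half_vi(sp$profiles, 2:5, n_repetitions = 12, n_replicates = 30,
                      rng_seed = 8)
  expect_lt(cv$mean_vi[3], cv$mean_vi[2])  # K=4 below K=3
  expect_lt(cv$mean_vi[3], cv$mean_vi[4])  # K=4 below K=5
})
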