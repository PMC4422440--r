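# Independent oracles and small fixture builders used across the suite.

# exhaustive minimum inertia over all 2-cluster partitions of the rows of x
brute_min_inertia_k2 <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.integer(intToBits(code))[1:n]
    ss <- 0
    for (g in 0:1) {
      rows <- x[grp == g, , drop = FALSE]
      ctr <- colMeans(rows)
      ss <- ss + sum(sweep(rows, 2, ctr)^2)
    }
    if (ss < best) best <- ss
  }
  best
}

# all set partitions of 1..n as label vectors (canonical first-occurrence ids)
all_set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_set_partitions(n - 1)) {
    k <- max(p)
    for (j in 1:(k + 1)) out[[length(out) + 1]] <- c(p, j)
  }
  out
}

# random label vector of n elements with up to kmax clusters, every label
# from 1..k present
rand_partition <- function(n, kmax) {
  k <- sample(2:kmax, 1)
  as.integer(sample(c(1:k, sample.int(k, n - k, replace = TRUE))))
}

# small group of Fisher-Z profiles with planted structure, for split-half
# and pipeline tests
small_profiles <- function(n_participants = 8, n_voxels = 24, n_targets = 60,
                           k_true = 4, noise = 1, seed = 5) {
  cfg <- synthetic_config(n_participants = n_participants,
                          n_seed_voxels = n_voxels, n_targets = n_targets,
                          k_true = k_true, noise_scale = noise, rng_seed = seed)
  truth <- make_planted_labels(cfg)
  mats <- simulate_group(cfg, truth)
  list(cfg = cfg, truth = truth, mats = mats,
       profiles = lapply(mats, function(m) fisher_z(cross_correlate(m))))
}

# tract map set wrapping a participants x voxels matrix as 1-voxel-thick
# volumes over a given number of clusters
flat_tract_set <- function(per_cluster_list, normalization = "proportion",
                           binarized = FALSE, threshold = 0.01) {
  np <- nrow(per_cluster_list[[1]])
  nv <- ncol(per_cluster_list[[1]])
  vols <- array(0, dim = c(nv, 1, 1, np, length(per_cluster_list)))
  for (cl in seq_along(per_cluster_list))
    for (s in seq_len(np)) vols[, 1, 1, s, cl] <- per_cluster_list[[cl]][s, ]
  tract_map_set(vols, normalization = normalization,
                threshold_applied = threshold, binarized = binarized)
}
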