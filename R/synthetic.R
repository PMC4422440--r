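# Synthetic group-level connectivity data with planted parcel structure.
# The generator emulates the statistical structure the pipeline assumes in
# real tractography data: seed voxels of the same parcel share a
# connectivity fingerprint over targets, perturbed by participant-level and
# voxel-level noise; optionally a mirrored second hemisphere with
# controllable left-right agreement and a nested parcel split for
# hierarchy testing.

#' Configuration for the synthetic connectivity generator
#'
#' @param n_participants number of simulated participants.
#' @param n_seed_voxels number of seed voxels per hemisphere.
#' @param n_targets number of target cells (>= 2).
#' @param k_true number of planted parcels (<= n_seed_voxels).
#' @param fingerprint_scale between-parcel signal magnitude: s.d. of the
#'   parcel fingerprint around the baseline count level.
#' @param noise_scale s.d. of both the participant-level fingerprint
#'   perturbation and the voxel-level count noise.
#' @param symmetry_level fraction in \[0,1\] of mirrored voxels keeping the
#'   homologous parcel label (1 = perfectly symmetric hemispheres).
#' @param hierarchy_split optional pair `c(parent, children)`: planted
#'   parcel `parent` is subdivided into `children` nested subparcels.
#' @param baseline mean count level of every fingerprint; the default
#'   (three signal-plus-noise s.d.s) keeps simulated counts essentially
#'   always positive so the count transform rarely folds.
#' @param rng_seed integer seed; identical configurations produce
#'   bit-identical data.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 20, n_seed_voxels = 60,
                             n_targets = 150, k_true = 4,
                             fingerprint_scale = 5, noise_scale = 1,
                             symmetry_level = 1, hierarchy_split = NULL,
                             baseline = NULL, rng_seed = 1L) {
  stopifnot(n_participants >= 1, n_seed_voxels >= 1, n_targets >= 2,
            k_true >= 1, fingerprint_scale >= 0, noise_scale >= 0,
            symmetry_level >= 0, symmetry_level <= 1)
  if (k_true > n_seed_voxels)
    stop("k_true exceeds the number of seed voxels")
  if (!is.null(hierarchy_split)) {
    stopifnot(length(hierarchy_split) == 2, hierarchy_split[1] >= 1,
              hierarchy_split[1] <= k_true, hierarchy_split[2] >= 2)
    hierarchy_split <- as.integer(hierarchy_split)
  }
  if (is.null(baseline)) baseline <- 3 * (fingerprint_scale + noise_scale)
  structure(list(n_participants = as.integer(n_participants),
                 n_seed_voxels = as.integer(n_seed_voxels),
                 n_targets = as.integer(n_targets),
                 k_true = as.integer(k_true),
                 fingerprint_scale = fingerprint_scale,
                 noise_scale = noise_scale,
                 symmetry_level = symmetry_level,
                 hierarchy_split = hierarchy_split,
                 baseline = baseline,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' Plant parcel labels on synthetic seed voxels
#'
#' Assigns each of the `n_seed_voxels` voxels to one of `k_true` parcels
#' uniformly at random, guaranteeing every parcel at least one voxel. When
#' `hierarchy_split = c(p, m)` is set, parcel p is additionally subdivided
#' into m nested children, producing a finer child labeling and a
#' child-to-parent map.
#'
#' @param cfg a `synthetic_config`.
#' @return An object of class `planted_truth`: `labels` (parcel id per
#'   voxel, 1..k_true), and when a hierarchy is requested `child_labels`
#'   (ids 1..k_true+m-1) with `parent_map` (child id -> parent id).
#' @export
make_planted_labels <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.child_seed(cfg$rng_seed, 101))
  n <- cfg$n_seed_voxels; k <- cfg$k_true
  # balanced assignment in random order: parcel sizes differ by at most one
  # voxel, so no parcel pair is structurally preferred when solutions with
  # K below k_true must merge parcels (sizes would otherwise act as a
  # hidden tie-break shared by both split halves)
  labels <- sample(rep(seq_len(k), length.out = n))
  out <- list(labels = labels)
  if (!is.null(cfg$hierarchy_split)) {
    p <- cfg$hierarchy_split[1]; m <- cfg$hierarchy_split[2]
    members <- which(labels == p)
    if (length(members) < m)
      stop("parcel to split has fewer voxels than requested children")
    child <- labels
    # children reuse id p and extend beyond k_true, keeping ids contiguous
    sub <- integer(length(members))
    sub[sample.int(length(members), m)] <- 1:m
    rest_m <- sub == 0
    if (any(rest_m)) sub[rest_m] <- sample.int(m, sum(rest_m), replace = TRUE)
    new_ids <- as.integer(c(p, k + seq_len(m - 1)))
    child[members] <- new_ids[sub]
    parent_map <- seq_len(k)
    parent_map[new_ids] <- as.integer(p)
    out$child_labels <- child
    out$parent_map <- parent_map
  }
  structure(out, class = "planted_truth")
}

#' Parcel fingerprints for a synthetic configuration
#'
#' Builds one connectivity fingerprint per parcel as a two-level block
#' pattern. The targets are split (after a seeded random permutation) into
#' `k_true` near-equal blocks, one per parcel, and parcels are grouped in
#' pairs into superclusters (parcel p belongs to supercluster
#' `ceiling(p/2)`). Parcel p's fingerprint elevates the blocks of its
#' whole supercluster by `fingerprint_scale` above the common `baseline`
#' and its own block by a further `fingerprint_scale` — the anatomically
#' natural picture of a hierarchically organized region whose parcels feed
#' related but distinct tract systems. Consequences the pipeline exploits:
#' sibling parcels are more similar than cross-supercluster parcels, so
#' coarse solutions (e.g. K = 2 for four parcels) recover the superclusters
#' stably; intermediate K must choose which supercluster to split first, a
#' structural tie decided by participant noise, so split-half solutions
#' there are unstable; and K = `k_true` recovers the parcels stably. When a
#' `hierarchy_split` is planted, the children of the split parcel share its
#' fingerprint and additionally elevate their own sub-block of it at half
#' scale, so the nested structure is recoverable at the finer K.
#'
#' @param cfg a `synthetic_config`.
#' @param truth the `planted_truth` (needed for hierarchy bookkeeping).
#' @return Matrix, one row per (child-level) parcel id.
#' @export
make_fingerprints <- function(cfg, truth) {
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.child_seed(cfg$rng_seed, 202))
  k <- cfg$k_true
  nt <- cfg$n_targets
  # exactly equal block sizes (remainder targets stay at baseline for every
  # parcel): unequal blocks would act as a structural tie-break shared by
  # both split halves
  b <- nt %/% k
  if (b < 1) stop("n_targets must be at least k_true for block fingerprints")
  block <- sample(c(rep(seq_len(k), each = b), rep(0L, nt - b * k)))
  super <- pmin(seq_len(k), 2L)  # parcel 1 vs the rest: asymmetric hierarchy
  fp <- matrix(cfg$baseline, k, nt)
  for (p in seq_len(k)) {
    sib_blocks <- block %in% which(super == super[p])
    fp[p, sib_blocks] <- fp[p, sib_blocks] + cfg$fingerprint_scale
    fp[p, block == p] <- fp[p, block == p] + cfg$fingerprint_scale
  }
  if (!is.null(truth$parent_map)) {
    k_child <- length(truth$parent_map)
    out <- matrix(NA_real_, k_child, nt)
    split_parent <- cfg$hierarchy_split[1]
    kids <- which(truth$parent_map == split_parent)
    par_targets <- which(block == split_parent)
    sub <- rep(seq_along(kids), length.out = length(par_targets))
    for (ci in seq_len(k_child)) out[ci, ] <- fp[truth$parent_map[ci], ]
    for (si in seq_along(kids)) {
      out[kids[si], par_targets[sub == si]] <-
        out[kids[si], par_targets[sub == si]] + cfg$fingerprint_scale / 2
    }
    out
  } else {
    fp
  }
}

#' Simulate a group of connectivity matrices
#'
#' For each participant, each seed voxel's count row is its parcel
#' fingerprint plus a participant-by-parcel fingerprint perturbation and
#' independent voxel-level noise (both s.d. `noise_scale`), mapped to valid
#' streamline counts by rounding the absolute value. Rows sharing a planted
#' label therefore correlate strongly over targets, with participant-level
#' variation that survives group averaging — the structure split-half
#' resampling exploits.
#'
#' @param cfg a `synthetic_config`.
#' @param truth a `planted_truth` for `cfg` (defaults to
#'   `make_planted_labels(cfg)`); when it carries a hierarchy, the
#'   child-level labels drive generation.
#' @param fingerprints optional fingerprint matrix from
#'   [make_fingerprints()] (shared across hemispheres for mirrored data).
#' @param stream_offset internal offset decorrelating the noise streams of
#'   different hemispheres.
#' @return List of `cfg$n_participants` [connectivity_matrix()] objects.
#' @export
simulate_group <- function(cfg, truth = make_planted_labels(cfg),
                           fingerprints = NULL, stream_offset = 0L) {
  stopifnot(inherits(cfg, "synthetic_config"), inherits(truth, "planted_truth"))
  labels <- if (!is.null(truth$child_labels)) truth$child_labels else truth$labels
  if (length(labels) != cfg$n_seed_voxels)
    stop("planted truth does not match the configuration's seed voxel count")
  if (is.null(fingerprints)) fingerprints <- make_fingerprints(cfg, truth)
  if (max(labels) > nrow(fingerprints))
    stop("fingerprint matrix has fewer rows than planted parcel ids")
  old <- .save_rng()
  on.exit(.restore_rng(old))
  n_par <- max(labels)
  geom <- synthetic_seed_geometry(cfg$n_seed_voxels)
  target_grid <- list(dim = c(cfg$n_targets, 1L, 1L),
                      affine = diag(c(5, 5, 5, 1)), cell_mm = 5)
  lapply(seq_len(cfg$n_participants), function(s) {
    set.seed(.child_seed(cfg$rng_seed, 303 + stream_offset, s))
    # participant-level perturbation of each parcel fingerprint
    pert <- cfg$noise_scale * matrix(stats::rnorm(n_par * cfg$n_targets), n_par)
    signal <- (fingerprints + pert)[labels, , drop = FALSE]
    noise <- cfg$noise_scale *
      matrix(stats::rnorm(cfg$n_seed_voxels * cfg$n_targets), cfg$n_seed_voxels)
    counts <- round(abs(signal + noise))
    connectivity_matrix(counts, seed_index = geom$voxels,
                        target_grid = target_grid,
                        participant_id = sprintf("sub-%03d", s))
  })
}

#' Simulate a mirrored hemisphere pair of planted truths
#'
#' Builds the left-hemisphere planted labels and a mirrored right
#' counterpart in which a fraction `1 - symmetry_level` of voxels
#' (rounded to the nearest voxel count) is relabeled uniformly at random to
#' a *different* parcel, so the expected homologous agreement equals
#' `symmetry_level` plus nothing.
#'
#' @param cfg a `synthetic_config` with `symmetry_level` set.
#' @return List with `left` and `right` `planted_truth`s; `left` also
#'   carries the right labels as `mirrored_labels`.
#' @export
simulate_hemisphere_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  left <- make_planted_labels(cfg)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(.child_seed(cfg$rng_seed, 404))
  n <- cfg$n_seed_voxels
  n_flip <- round((1 - cfg$symmetry_level) * n)
  right_labels <- left$labels
  if (n_flip > 0) {
    flip <- sample.int(n, n_flip)
    for (v in flip) {
      others <- setdiff(seq_len(cfg$k_true), right_labels[v])
      right_labels[v] <- if (length(others) == 1) others else sample(others, 1)
    }
  }
  right <- structure(list(labels = right_labels), class = "planted_truth")
  left$mirrored_labels <- right_labels
  list(left = left, right = right)
}

#' Synthetic seed-mask geometry
#'
#' Lays the requested number of seed voxels out as a compact blob (voxels
#' nearest the grid center, ties broken by index order) on a 2 mm grid.
#' The left-hemisphere affine maps grid x to negative world x and the right
#' affine to its exact reflection, so mirroring across x = 0 sends right
#' voxels onto the left grid exactly — the geometry the symmetry machinery
#' assumes of a standard space.
#'
#' @param n_voxels number of seed voxels.
#' @param hemisphere `"left"` (default) or `"right"`.
#' @return A `seed_mask`.
#' @export
synthetic_seed_geometry <- function(n_voxels, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  side <- max(3L, as.integer(ceiling((2 * n_voxels)^(1 / 3))) + 1L)
  dim <- rep(side, 3)
  ctr <- (dim - 1) / 2
  ijk <- arrayInd(seq_len(prod(dim)), dim) - 1L
  d2 <- rowSums(sweep(ijk, 2, ctr)^2)
  ord <- order(d2, seq_along(d2))
  if (n_voxels > prod(dim)) stop("blob does not fit the grid")
  vox <- ijk[ord[seq_len(n_voxels)], , drop = FALSE]
  sgn <- if (hemisphere == "left") -1 else 1
  affine <- rbind(c(2 * sgn, 0, 0, 4 * sgn),
                  c(0, 2, 0, -10),
                  c(0, 0, 2, -10),
                  c(0, 0, 0, 1))
  seed_mask(vox, dim, affine, hemisphere)
}

#' Write a complete synthetic dataset to disk
#'
#' Materializes a synthetic group as the file formats the pipeline reads:
#' NIfTI seed-mask label volumes and per-participant connectivity matrices
#' in dense or sparse-triplet text form, plus the planted labels as a TSV.
#'
#' @param cfg a `synthetic_config`.
#' @param dir output directory (created if needed).
#' @param format `"dense"` or `"sparse"` matrix format.
#' @return Invisibly, a list of the written paths plus the truth object.
#' @export
write_synthetic_dataset <- function(cfg, dir, format = c("dense", "sparse")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- make_planted_labels(cfg)
  mats <- simulate_group(cfg, truth)
  mask <- synthetic_seed_geometry(cfg$n_seed_voxels)
  mask_path <- file.path(dir, "seed_mask.nii.gz")
  write_seed_mask(mask, mask_path)
  mat_paths <- character(cfg$n_participants)
  for (s in seq_along(mats)) {
    mat_paths[s] <- file.path(dir, sprintf("%s_matrix.txt", mats[[s]]$participant_id))
    write_connectivity(mats[[s]], mat_paths[s], format = format)
  }
  truth_path <- file.path(dir, "planted_labels.tsv")
  utils::write.table(data.frame(voxel = seq_along(truth$labels),
                                label = truth$labels),
                     truth_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(mask = mask_path, matrices = mat_paths, truth_file = truth_path,
                 truth = truth, config = cfg))
}
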