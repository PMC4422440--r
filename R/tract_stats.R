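# Cluster-wise tract-map aggregation across participants and the
# sign-flipping max-statistic permutation contrast of one cluster's
# connectivity against the average of the others.

#' Construct a tract map set
#'
#' Per-participant, per-cluster 3D streamline-visitation maps on a common
#' grid, with bookkeeping of the processing state (raw counts vs
#' normalized proportions, threshold, binarization).
#'
#' @param volumes 5D numeric array `[x, y, z, participant, cluster]` of
#'   nonnegative values.
#' @param affine optional 4 x 4 grid-to-world affine for the tract grid.
#' @param normalization `"raw_counts"` or `"proportion"`.
#' @param threshold_applied proportion cutoff already applied, or `NULL`.
#' @param binarized logical.
#' @return An object of class `tract_map_set`.
#' @export
tract_map_set <- function(volumes, affine = diag(4),
                          normalization = c("raw_counts", "proportion"),
                          threshold_applied = NULL, binarized = FALSE) {
  normalization <- match.arg(normalization)
  stopifnot(length(dim(volumes)) == 5)
  if (any(!is.finite(volumes))) stop("non-finite tract map values")
  if (any(volumes < 0)) stop("negative tract map values")
  if (normalization == "proportion" && max(volumes) > 1)
    stop("proportion maps must lie in [0, 1]")
  if (binarized && !all(volumes %in% c(0, 1)))
    stop("binarized maps must contain only 0 and 1")
  structure(list(volumes = volumes, affine = affine,
                 normalization = normalization,
                 threshold_applied = threshold_applied,
                 binarized = binarized,
                 n_participants = dim(volumes)[4],
                 n_clusters = dim(volumes)[5]),
            class = "tract_map_set")
}

#' @export
print.tract_map_set <- function(x, ...) {
  cat(sprintf("Tract map set: %d participants x %d clusters on a %s grid (%s%s%s)\n",
              x$n_participants, x$n_clusters,
              paste(dim(x$volumes)[1:3], collapse = " x "), x$normalization,
              if (!is.null(x$threshold_applied))
                sprintf(", thresholded at %g", x$threshold_applied) else "",
              if (x$binarized) ", binarized" else ""))
  invisible(x)
}

#' Normalize tract counts to streamline proportions
#'
#' Divides every voxel of each participant-cluster map by that map's total
#' possible streamline count (number of seed voxels in the cluster times
#' the samples drawn per seed voxel), converting visitation counts to the
#' proportion of streamlines passing through the voxel.
#'
#' @param raw a `tract_map_set` with `normalization = "raw_counts"`.
#' @param total_possible positive scalar, or participant x cluster matrix,
#'   of total possible streamline counts.
#' @return The set with `normalization = "proportion"`.
#' @export
normalize_tracts <- function(raw, total_possible) {
  stopifnot(inherits(raw, "tract_map_set"))
  if (raw$normalization != "raw_counts")
    stop("tract maps are already normalized")
  d <- dim(raw$volumes)
  if (length(total_possible) == 1) {
    total_possible <- matrix(total_possible, d[4], d[5])
  }
  total_possible <- as.matrix(total_possible)
  stopifnot(all(dim(total_possible) == d[4:5]))
  if (any(total_possible <= 0)) stop("total possible streamline count must be positive")
  vols <- raw$volumes
  for (s in seq_len(d[4])) for (cl in seq_len(d[5]))
    vols[, , , s, cl] <- vols[, , , s, cl] / total_possible[s, cl]
  if (max(vols) > 1) stop("counts exceed the stated total possible streamlines")
  tract_map_set(vols, raw$affine, "proportion")
}

#' Threshold (and optionally binarize) proportion tract maps
#'
#' Zeroes voxels whose proportion falls below `cutoff` (a voxel exactly at
#' the cutoff survives). With `binarize = TRUE` surviving voxels become 1 —
#' the form averaged into overlap maps; with `binarize = FALSE` they keep
#' their continuous proportions — the form entering the permutation
#' contrast.
#'
#' @param t a `tract_map_set` with `normalization = "proportion"`.
#' @param cutoff proportion in (0, 1); the study-scale default is 0.01.
#' @param binarize logical, default `TRUE`.
#' @return The thresholded set, with `threshold_applied` recorded.
#' @export
threshold_binarize <- function(t, cutoff = 0.01, binarize = TRUE) {
  stopifnot(inherits(t, "tract_map_set"))
  if (t$normalization != "proportion")
    stop("threshold applies to proportion-normalized maps")
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie strictly inside (0, 1)")
  vols <- t$volumes
  keep <- vols >= cutoff
  vols[!keep] <- 0
  if (binarize) vols[keep] <- 1
  tract_map_set(vols, t$affine, "proportion", threshold_applied = cutoff,
                binarized = binarize)
}

#' Cross-participant tract overlap map
#'
#' For each cluster and voxel, the fraction of participants whose
#' binarized tract map is suprathreshold there; fractions below
#' `consistency_cutoff` are zeroed in the displayed map (a tract is only
#' considered if enough participants carry it, 50% at study scale).
#'
#' @param t a binarized `tract_map_set`.
#' @param consistency_cutoff proportion in (0, 1\].
#' @return List with `fraction` (4D array `[x, y, z, cluster]` of raw
#'   fractions) and `display` (same, zeroed below the cutoff), plus the
#'   cutoff.
#' @export
overlap_map <- function(t, consistency_cutoff = 0.5) {
  stopifnot(inherits(t, "tract_map_set"))
  if (!t$binarized) stop("overlap maps require binarized tract maps")
  stopifnot(consistency_cutoff > 0, consistency_cutoff <= 1)
  d <- dim(t$volumes)
  frac <- apply(t$volumes, c(1, 2, 3, 5), mean)
  disp <- frac
  disp[disp < consistency_cutoff] <- 0
  list(fraction = frac, display = disp, consistency_cutoff = consistency_cutoff)
}

#' Sign-flipping max-statistic permutation test on difference maps
#'
#' One-sample test of whether the per-participant difference maps have
#' zero mean at every voxel. The observed statistic is the voxelwise
#' one-sample t; the null distribution is generated by randomly flipping
#' the sign of whole participants (valid under exchangeability of the
#' paired design), and family-wise error is controlled by referring each
#' voxel's |t| to the permutation distribution of the maximum |t| over
#' voxels.
#'
#' @param diffs participants x voxels matrix of difference values.
#' @param alpha FWE level for the significance mask.
#' @param n_permutations number of random sign flips.
#' @param rng_seed integer seed.
#' @return List: `stat` (observed t per voxel), `p_corrected`,
#'   `p_uncorrected`, `significant` (logical, `p_corrected < alpha`),
#'   `n_permutations`.
#' @export
sign_flip_max_t <- function(diffs, alpha = 0.01, n_permutations = 1000,
                            rng_seed = 1L) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs); v <- ncol(diffs)
  if (n < 2) stop("at least 2 participants are required")
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 1)
  t_of <- function(m, ss) {
    varv <- pmax((ss - n * m^2) / (n - 1), 0)
    se <- sqrt(varv / n)
    out <- ifelse(se > 0, m / se, ifelse(m == 0, 0, sign(m) * Inf))
    out
  }
  ss <- colSums(diffs^2)
  obs <- t_of(colMeans(diffs), ss)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  perm_means <- (signs %*% diffs) / n
  # sum of squares is sign-invariant, so the permuted t needs only the mean
  perm_t <- abs(t_of(perm_means, matrix(ss, n_permutations, v, byrow = TRUE)))
  max_t <- apply(perm_t, 1, max)
  a_obs <- abs(obs)
  p_corr <- vapply(a_obs, function(t0) (1 + sum(max_t >= t0)) / (n_permutations + 1),
                   numeric(1))
  p_unc <- vapply(seq_len(v), function(j)
    (1 + sum(perm_t[, j] >= a_obs[j])) / (n_permutations + 1), numeric(1))
  list(stat = obs, p_corrected = p_corr, p_uncorrected = p_unc,
       significant = p_corr < alpha, n_permutations = as.integer(n_permutations))
}

#' Contrast one cluster's tracts against the rest
#'
#' For each participant, forms the difference map between the chosen
#' cluster's normalized, thresholded (but not binarized) tract map and the
#' mean of the other clusters' maps, then tests the mean difference with
#' [sign_flip_max_t()] under max-statistic FWE correction.
#'
#' @param t a `tract_map_set` with `normalization = "proportion"`,
#'   thresholded, `binarized = FALSE`, at least 2 clusters and 2
#'   participants.
#' @param cluster cluster id to contrast.
#' @param alpha FWE level (study-scale 0.01).
#' @param n_permutations permutation count (study-scale 1000).
#' @param rng_seed integer seed.
#' @return An object of class `contrast_result`: `stat_map`,
#'   `p_corrected_map`, `p_uncorrected_map`, `significance_mask` (3D
#'   arrays), `cluster`, `alpha`, `n_permutations`.
#' @export
contrast_cluster_vs_rest <- function(t, cluster, alpha = 0.01,
                                     n_permutations = 1000, rng_seed = 1L) {
  stopifnot(inherits(t, "tract_map_set"))
  if (t$normalization != "proportion")
    stop("contrast requires proportion-normalized maps")
  if (t$binarized) stop("contrast requires non-binarized maps")
  d <- dim(t$volumes)
  if (d[5] < 2) stop("contrast requires at least 2 clusters")
  if (d[4] < 2) stop("contrast requires at least 2 participants")
  stopifnot(cluster >= 1, cluster <= d[5])
  nv <- prod(d[1:3])
  flat <- matrix(t$volumes, nrow = nv)  # voxels x (participant*cluster)
  dim(flat) <- c(nv, d[4], d[5])
  cl_maps <- flat[, , cluster, drop = FALSE][, , 1]
  rest <- apply(flat[, , -cluster, drop = FALSE], c(1, 2), mean)
  diffs <- t(cl_maps - rest)  # participants x voxels
  res <- sign_flip_max_t(diffs, alpha, n_permutations, rng_seed)
  shape3 <- d[1:3]
  structure(list(stat_map = array(res$stat, shape3),
                 p_corrected_map = array(res$p_corrected, shape3),
                 p_uncorrected_map = array(res$p_uncorrected, shape3),
                 significance_mask = array(res$significant, shape3),
                 cluster = cluster, alpha = alpha,
                 n_permutations = res$n_permutations),
            class = "contrast_result")
}

#' Aggregate per-cluster synthetic tract volumes from a parcellation
#'
#' Utility producing a `tract_map_set` from per-participant streamline
#' visitation volumes already split by cluster, as written by tractography
#' run per cluster. Provided mainly to assemble NIfTI inputs.
#'
#' @param volume_list list (participants) of lists (clusters) of 3D arrays
#'   on a common grid.
#' @param affine grid-to-world affine.
#' @return A `tract_map_set` of raw counts.
#' @export
assemble_tract_maps <- function(volume_list, affine = diag(4)) {
  np <- length(volume_list)
  stopifnot(np >= 1)
  nc <- length(volume_list[[1]])
  g <- dim(volume_list[[1]][[1]])
  vols <- array(0, dim = c(g, np, nc))
  for (s in seq_len(np)) {
    stopifnot(length(volume_list[[s]]) == nc)
    for (cl in seq_len(nc)) {
      stopifnot(all(dim(volume_list[[s]][[cl]]) == g))
      vols[, , , s, cl] <- volume_list[[s]][[cl]]
    }
  }
  tract_map_set(vols, affine, "raw_counts")
}
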