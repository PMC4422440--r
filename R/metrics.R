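# Information-theoretic comparison of parcellations (entropy, mutual
# information, variation of information), the split-half resampling
# procedure that scores cluster-number candidates, the optimal-K decision
# rule, and the hierarchy and symmetry indices.

#' Entropy of a clustering
#'
#' Shannon entropy of the cluster-size distribution,
#' \eqn{H(C) = -\sum_k P(k) \log P(k)} with \eqn{P(k)} the fraction of
#' elements in cluster k and \eqn{0 \log 0 = 0}.
#'
#' @param c a `parcellation` or integer label vector.
#' @param log_base logarithm base; base 10 is the package default
#'   throughout the VI machinery (see [variation_of_information()]).
#' @return Nonnegative entropy.
#' @export
cluster_entropy <- function(c, log_base = 10) {
  labels <- .as_labels(c)
  n <- length(labels)
  stopifnot(n >= 1, log_base > 0, log_base != 1)
  p <- as.numeric(table(labels)) / n
  -sum(p * log(p, base = log_base))
}

#' Mutual information between two clusterings
#'
#' \eqn{I(C, C') = \sum_{k,k'} P(k,k') \log\frac{P(k,k')}{P(k)P(k')}},
#' where \eqn{P(k,k')} is the fraction of elements jointly in cluster k of
#' `c` and cluster k' of `c2`; empty joint cells contribute 0.
#'
#' @param c,c2 `parcellation`s or label vectors over the same elements, in
#'   the same element order.
#' @inheritParams cluster_entropy
#' @return Nonnegative mutual information.
#' @export
mutual_information <- function(c, c2, log_base = 10) {
  l1 <- .as_labels(c); l2 <- .as_labels(c2)
  if (length(l1) != length(l2))
    stop("clusterings are over different numbers of elements")
  n <- length(l1)
  joint <- table(l1, l2) / n
  p1 <- rowSums(joint); p2 <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(p1, p2)[nz], base = log_base))
}

#' Variation of information between two clusterings
#'
#' The information-theoretic distance
#' \eqn{VI(C, C') = H(C) + H(C') - 2 I(C, C')}: 0 iff the clusterings are
#' identical up to relabeling, bounded above by \eqn{\log n}, and a true
#' metric on the space of partitions. It needs no correspondence between
#' cluster ids, which is what makes it suitable for comparing independent
#' split-half solutions.
#'
#' @inheritParams mutual_information
#' @return Nonnegative VI (floating-point round-off is clipped at 0).
#' @export
variation_of_information <- function(c, c2, log_base = 10) {
  vi <- cluster_entropy(c, log_base) + cluster_entropy(c2, log_base) -
    2 * mutual_information(c, c2, log_base)
  max(vi, 0)
}

#' Upper bound of the variation of information
#'
#' VI between partitions of n elements cannot exceed \eqn{\log n} in the
#' chosen base.
#'
#' @param n number of elements.
#' @inheritParams cluster_entropy
#' @return \eqn{\log_{base} n}.
#' @export
vi_upper_bound <- function(n, log_base = 10) {
  stopifnot(n >= 1)
  log(n, base = log_base)
}

#' Split-half VI curve over candidate cluster numbers
#'
#' The resampling procedure that scores each candidate K by the stability
#' of its solution: participants are repeatedly split at random into two
#' disjoint halves (sizes floor(N/2) and ceiling(N/2)); each half's
#' Fisher-Z correlation profiles are averaged and parcellated at every K by
#' [kmeans_replicates()]; and the VI between the two half solutions is
#' recorded. The same splits are reused across all K within a run so the
#' per-K VI samples are paired, and VI(K) is compared to VI(K-1) with a
#' paired one-sided t-test of the hypothesis that VI increased.
#'
#' @param group_profiles list of per-participant `correlation_profile`s
#'   with `transform = "fisher_z"` (length >= 2).
#' @param k_range contiguous increasing integer vector of candidate K,
#'   starting at 2 (study-scale default 2..8).
#' @param n_repetitions number of random splits (study-scale default 100).
#' @param n_replicates k-means restarts per clustering.
#' @param rng_seed integer seed controlling splits and clustering.
#' @param log_base VI logarithm base.
#' @param conf_level level of the t-based confidence interval on mean VI.
#' @return An object of class `vi_curve`: `k`, `mean_vi`, `ci_low`,
#'   `ci_high`, `rep_vi` (repetitions x K matrix), `t` and `p` (paired
#'   test of K vs K-1; `NA` for the first K; a zero-variance difference,
#'   being the same in every repetition, yields `t = +-Inf` and `p` 0 or
#'   1 by its sign), `n_repetitions`, `log_base`.
#' @export
split_half_vi <- function(group_profiles, k_range = 2:8, n_repetitions = 100,
                          n_replicates = 100, rng_seed = 1L, log_base = 10,
                          conf_level = 0.95) {
  stopifnot(is.list(group_profiles))
  n_part <- length(group_profiles)
  if (n_part < 2) stop("split-half resampling needs at least 2 participants")
  k_range <- as.integer(k_range)
  if (k_range[1] != 2 || any(diff(k_range) != 1))
    stop("k_range must be contiguous and start at 2 (K-1 baseline needed)")
  n_k <- length(k_range)
  rep_vi <- matrix(NA_real_, n_repetitions, n_k,
                   dimnames = list(NULL, paste0("K", k_range)))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  half_n <- floor(n_part / 2)
  for (r in seq_len(n_repetitions)) {
    perm <- sample.int(n_part)
    h1 <- perm[seq_len(half_n)]
    h2 <- perm[(half_n + 1):n_part]
    avg1 <- average_group(group_profiles[h1])
    avg2 <- average_group(group_profiles[h2])
    for (ki in seq_len(n_k)) {
      k <- k_range[ki]
      p1 <- kmeans_replicates(avg1, k, n_replicates,
                              rng_seed = .child_seed(rng_seed, r, k, 1))
      p2 <- kmeans_replicates(avg2, k, n_replicates,
                              rng_seed = .child_seed(rng_seed, r, k, 2))
      rep_vi[r, ki] <- variation_of_information(p1, p2, log_base)
    }
  }
  # identical half-solutions leave round-off dust of order 1e-16 in VI;
  # snap it to zero so the paired tests cannot pick it up as an effect
  rep_vi[rep_vi < 1e-10] <- 0
  mean_vi <- colMeans(rep_vi)
  se <- apply(rep_vi, 2, stats::sd) / sqrt(n_repetitions)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n_repetitions - 1)
  t_stat <- rep(NA_real_, n_k)
  p_val <- rep(NA_real_, n_k)
  for (ki in 2:n_k) {
    d <- rep_vi[, ki] - rep_vi[, ki - 1]
    if (stats::sd(d) == 0) {
      # degenerate paired test: the difference is the same in every
      # repetition, which is conclusive in itself
      t_stat[ki] <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p_val[ki] <- if (mean(d) > 0) 0 else 1
      next
    }
    tt <- stats::t.test(rep_vi[, ki], rep_vi[, ki - 1], paired = TRUE,
                        alternative = "greater")
    t_stat[ki] <- unname(tt$statistic)
    p_val[ki] <- tt$p.value
  }
  structure(list(k = k_range, mean_vi = mean_vi,
                 ci_low = mean_vi - tq * se, ci_high = mean_vi + tq * se,
                 rep_vi = rep_vi, t = t_stat, p = p_val,
                 n_repetitions = as.integer(n_repetitions),
                 log_base = log_base),
            class = "vi_curve")
}

#' @export
print.vi_curve <- function(x, ...) {
  cat(sprintf("Split-half VI curve (%d repetitions, log base %g)\n",
              x$n_repetitions, x$log_base))
  print(data.frame(K = x$k, mean_VI = round(x$mean_vi, 4),
                   ci_low = round(x$ci_low, 4), ci_high = round(x$ci_high, 4),
                   t = round(x$t, 2), p = signif(x$p, 3)), row.names = FALSE)
  invisible(x)
}

#' Select the optimal number of clusters from a VI curve
#'
#' Applies the decision rule: the optimal K is the smallest K greater than
#' 2 for which VI did not significantly increase relative to K-1 (paired
#' one-sided test at level `alpha`). If every step up to the largest K
#' shows a significant increase, the largest K is returned with a
#' no-selection flag.
#'
#' @param curve a `vi_curve` covering contiguous K from 2.
#' @param alpha one-sided significance level (default 0.05).
#' @return List with `k` (selected K), `no_selection` (TRUE when no K
#'   satisfied the rule), and `p` (the p-value at the selected step, `NA`
#'   when degenerate).
#' @export
select_optimal_k <- function(curve, alpha = 0.05) {
  stopifnot(inherits(curve, "vi_curve"), alpha > 0, alpha < 1)
  for (ki in 2:length(curve$k)) {
    p <- curve$p[ki]
    if (is.na(p) || p >= alpha)
      return(list(k = curve$k[ki], no_selection = FALSE, p = p))
  }
  list(k = curve$k[length(curve$k)], no_selection = TRUE,
       p = curve$p[length(curve$k)])
}

#' Hierarchy index between consecutive parcellations
#'
#' Measures how nested a (K+1)-cluster solution is within a K-cluster
#' solution: for each child cluster i, \eqn{x_{ij}} counts its voxels
#' inherited from parent cluster j, and the index is the mean over child
#' clusters of \eqn{\max_j x_{ij} / \sum_j x_{ij}}. It equals 1 iff every
#' child cluster lies entirely within one parent cluster, and is at least
#' 1/K (a child cannot inherit less than an equal share from its largest
#' parent).
#'
#' @param parent clustering with K clusters.
#' @param child clustering with K + 1 clusters over the same elements.
#' @return Hierarchy index in (0, 1].
#' @export
hierarchy_index <- function(parent, child) {
  lp <- .as_labels(parent); lc <- .as_labels(child)
  if (length(lp) != length(lc))
    stop("parent and child clusterings are over different element sets")
  kp <- max(lp); kc <- max(lc)
  if (kc != kp + 1)
    stop(sprintf("child must have exactly one more cluster than parent (got %d vs %d)",
                 kc, kp))
  tab <- table(factor(lc, levels = 1:kc), factor(lp, levels = 1:kp))
  frac <- apply(tab, 1, max) / rowSums(tab)
  mean(frac)
}

#' Hierarchy index profile across a set of parcellations
#'
#' Convenience wrapper computing [hierarchy_index()] for every consecutive
#' pair of solutions (K vs K+1) in a list indexed by K.
#'
#' @param parcellations list of `parcellation`s with strictly increasing,
#'   consecutive K.
#' @return Data frame with columns `k_child` and `hierarchy_index`.
#' @export
hierarchy_profile <- function(parcellations) {
  ks <- vapply(parcellations, function(p) max(.as_labels(p)), integer(1))
  stopifnot(all(diff(ks) == 1))
  out <- data.frame(k_child = ks[-1], hierarchy_index = NA_real_)
  for (i in seq_len(length(parcellations) - 1))
    out$hierarchy_index[i] <- hierarchy_index(parcellations[[i]],
                                              parcellations[[i + 1]])
  out
}

#' Hemispheric symmetry of two parcellations
#'
#' Mirrors the right-hemisphere mask across the midsagittal plane (world
#' x to -x), restricts to the voxels present in both hemispheres after
#' mirroring, pairs right clusters to left clusters by [match_labels()] on
#' that overlap domain, and reports the fraction of overlap-domain voxels
#' whose left label agrees with the matched mirrored-right label.
#'
#' @param left,right `parcellation`s aligned with their masks.
#' @param left_mask,right_mask `seed_mask`s sharing grid shape and an
#'   x-symmetric standard space.
#' @return List with `symmetry` (proportion in \[0,1\]), `overlap_n`
#'   (overlap-domain voxel count), and `mapping` (right-to-left cluster id
#'   map).
#' @export
symmetry_index <- function(left, right, left_mask, right_mask) {
  ll <- .as_labels(left); lr <- .as_labels(right)
  stopifnot(length(ll) == left_mask$n_voxels,
            length(lr) == right_mask$n_voxels)
  mir <- .mirror_voxels_x(right_mask, left_mask)
  # linear grid index of each left voxel, and of each mirrored right voxel
  lin_left <- .voxel_lin(left_mask$voxels, left_mask$dim)
  keep <- mir$inside
  lin_right <- .voxel_lin(mir$voxels[keep, , drop = FALSE], left_mask$dim)
  lr_in <- lr[keep]
  common <- intersect(lin_left, lin_right)
  if (length(common) == 0) stop("hemisphere masks share no voxels after mirroring")
  left_on <- ll[match(common, lin_left)]
  right_on <- lr_in[match(common, lin_right)]
  mapping <- match_labels(left_on, right_on)
  mapped <- mapping[right_on]
  agree <- !is.na(mapped) & left_on == mapped  # unmatched ids never agree
  list(symmetry = mean(agree), overlap_n = length(common), mapping = mapping)
}
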