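# Replicated k-means parcellation of correlation-profile rows, label
# matching between solutions, and spatial cluster summaries.

#' Parcellation by best-of-replicates k-means
#'
#' Clusters the rows of a correlation profile (each seed voxel's similarity
#' fingerprint) with Lloyd's k-means, repeated `n_replicates` times from
#' random initial centroids; the replicate with the smallest total
#' within-cluster squared point-to-centroid distance (inertia) wins.
#' Initial centroids are drawn as k distinct data rows (Forgy
#' initialization); `init = "plusplus"` switches to k-means++ seeding.
#' A replicate that ends with an empty cluster is restarted with fresh
#' centroids (up to 20 attempts) and discarded if it never succeeds.
#'
#' @param p a `correlation_profile` (or a plain numeric matrix whose rows
#'   are features).
#' @param k number of clusters, `2 <= k <=` number of rows.
#' @param n_replicates number of random restarts (the study-scale default
#'   is 1000).
#' @param rng_seed integer seed; results are deterministic given it.
#' @param init `"forgy"` (default) or `"plusplus"`.
#' @param iter_max Lloyd iteration cap per replicate.
#' @return An object of class `parcellation`: `labels` (1..k per row), `k`,
#'   `inertia`, `n_replicates`, `rng_seed`.
#' @export
kmeans_replicates <- function(p, k, n_replicates = 1000, rng_seed = 1L,
                              init = c("forgy", "plusplus"), iter_max = 300L) {
  x <- if (inherits(p, "correlation_profile")) p$values else as.matrix(p)
  init <- match.arg(init)
  n <- nrow(x)
  if (k < 2 || k > n) stop(sprintf("k = %d outside the feasible range 2..%d", k, n))
  stopifnot(n_replicates >= 1)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  best <- NULL
  for (rep_i in seq_len(n_replicates)) {
    fit <- NULL
    for (attempt in 1:20) {
      centers <- if (init == "forgy") {
        x[sample.int(n, k), , drop = FALSE]
      } else {
        .plusplus_centers(x, k)
      }
      if (anyDuplicated(centers)) next  # degenerate draw: duplicated rows
      fit <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = iter_max,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
      fit <- NULL
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("no k-means replicate produced k non-empty clusters")
  structure(list(labels = as.integer(best$cluster), k = as.integer(k),
                 inertia = best$tot.withinss,
                 n_replicates = as.integer(n_replicates),
                 rng_seed = as.integer(rng_seed)),
            class = "parcellation")
}

# k-means++ seeding: successive centers drawn with probability proportional
# to squared distance from the nearest chosen center
.plusplus_centers <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in 2:k) {
    d2 <- .min_sq_dist(x, x[idx, , drop = FALSE])
    d2[idx] <- 0
    if (sum(d2) == 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = d2))
    }
  }
  x[idx, , drop = FALSE]
}

.min_sq_dist <- function(x, centers) {
  d2 <- matrix(Inf, nrow(x), nrow(centers))
  for (j in seq_len(nrow(centers)))
    d2[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
  apply(d2, 1, min)
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation: K = %d over %d voxels, inertia %.4f (%d replicates)\n",
              x$k, length(x$labels), x$inertia, x$n_replicates))
  invisible(x)
}

#' Match cluster labels between two parcellations
#'
#' Finds the one-to-one assignment of `b`'s cluster ids to `a`'s that
#' maximizes the total number of co-labelled voxels, by exhaustive
#' optimization over injective assignments on the contingency table
#' (cluster counts here are small, at most 10, so enumeration is exact and
#' cheap). Used to pair homologous clusters for the symmetry index and for
#' reporting; the variation of information needs no matching.
#'
#' @param a,b `parcellation`s (or integer label vectors) over the same
#'   voxels, or over `overlap_domain`.
#' @param overlap_domain optional logical or integer index vector selecting
#'   the voxels on which to match; defaults to all.
#' @return Named integer vector: position `j` gives the `a`-id matched to
#'   `b`-id `j` (`NA` for unmatched ids when the cluster counts differ),
#'   with attribute `overlap` = total co-labelled voxels under the
#'   assignment.
#' @export
match_labels <- function(a, b, overlap_domain = NULL) {
  la <- if (inherits(a, "parcellation")) a$labels else as.integer(a)
  lb <- if (inherits(b, "parcellation")) b$labels else as.integer(b)
  if (!is.null(overlap_domain)) {
    la <- la[overlap_domain]
    lb <- lb[overlap_domain]
  }
  if (length(la) == 0 || length(lb) == 0) stop("empty overlap domain")
  if (length(la) != length(lb)) stop("label vectors have different lengths")
  ka <- max(la); kb <- max(lb)
  tab <- matrix(0, ka, kb)
  t0 <- table(factor(la, levels = 1:ka), factor(lb, levels = 1:kb))
  tab[] <- t0
  small <- min(ka, kb)
  if (max(ka, kb) > 10) stop("label matching supports at most 10 clusters")
  # enumerate injections of the smaller id set into the larger
  perms <- .permutations(max(ka, kb), small)
  tab <- matrix(as.integer(tab), ka, kb)
  best <- -1L; best_map <- NULL
  for (r in seq_len(nrow(perms))) {
    if (ka <= kb) {
      # assign each a-id i to b-id perms[r, i]
      ov <- sum(tab[cbind(1:ka, perms[r, ])])
      map <- rep(NA_integer_, kb)
      map[perms[r, ]] <- 1:ka
    } else {
      ov <- sum(tab[cbind(perms[r, ], 1:kb)])
      map <- perms[r, ]
    }
    if (ov > best) { best <- ov; best_map <- map }
  }
  names(best_map) <- as.character(seq_along(best_map))
  attr(best_map, "overlap") <- best
  best_map
}

# all ordered selections of r elements from 1..n (n^r bounded by 10!/2!)
.permutations <- function(n, r) {
  if (r == 1) return(matrix(1:n, ncol = 1))
  sub <- .permutations(n, r - 1)
  out <- vector("list", n)
  for (i in 1:n) {
    keep <- rowSums(sub == i) == 0
    block <- sub[keep, , drop = FALSE]
    out[[i]] <- cbind(i, block)
  }
  do.call(rbind, out)
}

#' Spatial summary of a parcellation
#'
#' Computes, per cluster, the center of gravity (mean world-space mm
#' coordinate of member voxels under the seed-mask affine) and the voxel
#' count. This is the machinery behind the standard cluster-coordinate
#' table of a parcellation study.
#'
#' @param p a `parcellation` aligned with `mask`'s voxel ordering.
#' @param mask the `seed_mask` the parcellation lives on.
#' @return A data frame with columns `cluster`, `size`, `x`, `y`, `z`.
#' @export
summarize_clusters <- function(p, mask) {
  stopifnot(inherits(p, "parcellation"), inherits(mask, "seed_mask"))
  if (length(p$labels) != mask$n_voxels)
    stop("parcellation and mask have different voxel counts")
  w <- voxel_world_coords(mask)
  out <- data.frame(cluster = 1:p$k,
                    size = as.integer(tabulate(p$labels, p$k)))
  cog <- t(vapply(1:p$k, function(cl) colMeans(w[p$labels == cl, , drop = FALSE]),
                  numeric(3)))
  out$x <- cog[, 1]; out$y <- cog[, 2]; out$z <- cog[, 3]
  out
}

#' Dilate a label map by a spherical kernel
#'
#' Propagates each labeled voxel's label to all grid voxels within
#' `radius_mm` (world-space Euclidean distance). Where dilated regions
#' collide, the nearest labeled voxel wins; exact ties go to the lower
#' label id. Dilation by a small spherical kernel (e.g. 2 mm) is how
#' per-participant cluster maps are thickened before averaging into overlap
#' maps.
#'
#' @param p a `parcellation` (or integer label vector) on `mask`'s voxels.
#' @param mask the `seed_mask` supplying grid and affine.
#' @param radius_mm dilation radius, >= 0; 0 returns the undilated volume.
#' @return 3D integer array of labels on the mask grid (0 = background).
#' @export
dilate_labels <- function(p, mask, radius_mm) {
  labels <- if (inherits(p, "parcellation")) p$labels else as.integer(p)
  stopifnot(radius_mm >= 0, length(labels) == mask$n_voxels)
  spacing <- sqrt(colSums(mask$affine[1:3, 1:3]^2))
  vol <- array(0L, dim = mask$dim)
  dist_best <- array(Inf, dim = mask$dim)
  # candidate integer offsets within the world-space radius
  rng <- lapply(1:3, function(ax) -floor(radius_mm / spacing[ax]):floor(radius_mm / spacing[ax]))
  offs <- as.matrix(expand.grid(di = rng[[1]], dj = rng[[2]], dk = rng[[3]]))
  d_off <- sqrt((offs[, 1] * spacing[1])^2 + (offs[, 2] * spacing[2])^2 +
                  (offs[, 3] * spacing[3])^2)
  keep <- d_off <= radius_mm + 1e-9
  offs <- offs[keep, , drop = FALSE]
  d_off <- d_off[keep]
  vox <- mask$voxels
  # process offsets in shells of equal distance: nearer shells claim voxels
  # first, and within a shell the lowest label id wins an exact tie
  for (d in sort(unique(d_off))) {
    shell <- which(abs(d_off - d) < 1e-12)
    lin_all <- integer(0); lab_all <- integer(0)
    for (o in shell) {
      tgt <- sweep(vox, 2, offs[o, ], `+`)
      inside <- tgt[, 1] >= 0 & tgt[, 2] >= 0 & tgt[, 3] >= 0 &
        tgt[, 1] < mask$dim[1] & tgt[, 2] < mask$dim[2] & tgt[, 3] < mask$dim[3]
      if (!any(inside)) next
      lin_all <- c(lin_all, .voxel_lin(tgt[inside, , drop = FALSE], mask$dim))
      lab_all <- c(lab_all, labels[inside])
    }
    if (length(lin_all) == 0) next
    ord <- order(lab_all)
    lin_all <- lin_all[ord]; lab_all <- lab_all[ord]
    first <- !duplicated(lin_all)
    lin_f <- lin_all[first]; lab_f <- lab_all[first]
    claim <- d < dist_best[lin_f]
    dist_best[lin_f[claim]] <- d
    vol[lin_f[claim]] <- lab_f[claim]
  }
  vol
}
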