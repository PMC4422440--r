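# From per-participant seed-by-target streamline-count matrices to the
# group-averaged seed-by-seed cross-correlation profile that k-means
# clusters.

#' Construct a connectivity matrix
#'
#' One participant's seed-voxel by target-cell streamline counts, as
#' produced by probabilistic tractography. Rows follow the seed-mask voxel
#' ordering; columns follow the target grid in x-fastest order.
#'
#' @param counts nonnegative numeric matrix, seed voxels x target cells.
#' @param seed_index n x 3 integer matrix of 0-based seed voxel grid indices
#'   (the seed-mask ordering), or `NULL`.
#' @param target_grid list with elements `dim` (length-3 integer), `affine`
#'   (4 x 4) and `cell_mm` (isotropic cell size); or `NULL` for an abstract
#'   target space.
#' @param participant_id identifier.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(counts, seed_index = NULL, target_grid = NULL,
                                participant_id = NA_character_) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts))) stop("non-finite streamline counts")
  if (any(counts < 0)) stop("negative streamline counts")
  if (!is.null(seed_index) && nrow(seed_index) != nrow(counts))
    stop("seed_index length does not match the number of count rows")
  if (!is.null(target_grid) && prod(target_grid$dim) != ncol(counts))
    stop("target grid size does not match the number of count columns")
  structure(list(counts = counts, seed_index = seed_index,
                 target_grid = target_grid, participant_id = participant_id),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("Connectivity matrix [%s]: %d seed voxels x %d target cells, %s streamlines\n",
              x$participant_id, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Downsample the target space of a connectivity matrix
#'
#' Aggregates target cells into non-overlapping cubic blocks of
#' `cell_mm`-sized cells anchored at the target-grid origin voxel, summing
#' the streamline counts in each block. This is the usual storage-saving
#' reduction of whole-brain tractography targets (e.g. 2 mm voxels to 5 mm
#' cells). Row totals are conserved exactly.
#'
#' @param m a `connectivity_matrix` with a `target_grid`.
#' @param cell_mm output cell size; must be a positive integer multiple of
#'   the current cell size.
#' @return A `connectivity_matrix` on the coarser target grid.
#' @export
downsample_targets <- function(m, cell_mm) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (is.null(m$target_grid)) stop("connectivity matrix has no target grid")
  src <- m$target_grid$cell_mm
  ratio <- cell_mm / src
  if (cell_mm <= 0 || abs(ratio - round(ratio)) > 1e-8)
    stop(sprintf("cell_mm = %g is not a positive multiple of the source cell size %g",
                 cell_mm, src))
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(m)
  d <- m$target_grid$dim
  nd <- as.integer(ceiling(d / ratio))
  # block id of every source cell, x-fastest order on the coarse grid
  ijk <- arrayInd(seq_len(prod(d)), d) - 1L
  blk <- ijk %/% ratio
  blk_lin <- 1L + blk[, 1] + nd[1] * (blk[, 2] + nd[2] * blk[, 3])
  agg <- t(rowsum(t(m$counts), group = blk_lin, reorder = TRUE))
  # rowsum drops absent groups; coarse grids built by ceiling always have
  # every block populated, so column count must equal the coarse grid size
  stopifnot(ncol(agg) == prod(nd))
  affine <- m$target_grid$affine
  scale <- diag(c(ratio, ratio, ratio, 1))
  # coarse voxel (0,0,0) spans source voxels 0..ratio-1; its index scales
  new_affine <- affine %*% scale
  connectivity_matrix(agg, m$seed_index,
                      list(dim = nd, affine = new_affine, cell_mm = src * ratio),
                      m$participant_id)
}

#' Cross-correlate seed connectivity fingerprints
#'
#' Computes the Pearson correlation between every pair of seed rows of the
#' count matrix, yielding the seed-by-seed cross-correlation matrix whose
#' rows are the clustering features. A seed row with zero variance (a voxel
#' reaching no target) has undefined correlations: by default this is an
#' error naming the offending voxels; `zero_variance = "drop"` removes them
#' and records which.
#'
#' @param m a `connectivity_matrix` with at least 2 target cells.
#' @param zero_variance `"error"` (default) or `"drop"`.
#' @return An object of class `correlation_profile` with fields `values`
#'   (symmetric, unit diagonal), `transform = "raw_r"`, `n_averaged = 1`,
#'   and `dropped` (indices of dropped seed rows, if any).
#' @export
cross_correlate <- function(m, zero_variance = c("error", "drop")) {
  stopifnot(inherits(m, "connectivity_matrix"), ncol(m$counts) >= 2)
  zero_variance <- match.arg(zero_variance)
  v <- apply(m$counts, 1, stats::var)
  bad <- which(v == 0)
  counts <- m$counts
  seed_index <- m$seed_index
  if (length(bad) > 0) {
    if (zero_variance == "error")
      stop("zero-variance seed rows (no streamline contrast): voxels ",
           paste(bad, collapse = ", "),
           "; rerun with zero_variance = \"drop\" to exclude them")
    counts <- counts[-bad, , drop = FALSE]
    if (!is.null(seed_index)) seed_index <- seed_index[-bad, , drop = FALSE]
    if (nrow(counts) < 2) stop("fewer than 2 seed rows remain after dropping")
  }
  vals <- stats::cor(t(counts))
  diag(vals) <- 1
  structure(list(values = vals, transform = "raw_r", n_averaged = 1L,
                 seed_index = seed_index,
                 dropped = if (length(bad)) bad else integer(0)),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("Correlation profile: %d seed voxels, transform = %s, averaged over %d\n",
              nrow(x$values), x$transform, x$n_averaged))
  invisible(x)
}

#' Fisher-Z transform a correlation profile
#'
#' Applies arctanh to every entry after clipping to
#' `[-1 + clip_epsilon, 1 - clip_epsilon]`, so that perfect correlations
#' (including the diagonal) map to a large finite value rather than
#' infinity. Fisher-Z is the variance-stabilizing transform applied before
#' averaging correlation matrices across participants.
#'
#' @param p a `correlation_profile` with `transform = "raw_r"`.
#' @param clip_epsilon small positive clip margin; the default leaves every
#'   |r| <= 1 - 1e-6 numerically unchanged.
#' @return The profile with `transform = "fisher_z"`.
#' @export
fisher_z <- function(p, clip_epsilon = 1e-7) {
  stopifnot(inherits(p, "correlation_profile"), clip_epsilon > 0)
  if (p$transform != "raw_r") stop("profile is already transformed: ", p$transform)
  z <- atanh(pmin(pmax(p$values, -1 + clip_epsilon), 1 - clip_epsilon))
  p$values <- z
  p$transform <- "fisher_z"
  p
}

#' Average Fisher-Z correlation profiles across participants
#'
#' Entrywise arithmetic mean of the participants' Fisher-Z matrices; the
#' result is the group clustering substrate. All inputs must already be
#' Fisher-Z transformed and share the seed ordering.
#'
#' @param profiles list of `correlation_profile`s with
#'   `transform = "fisher_z"`.
#' @return A `correlation_profile` with `n_averaged = length(profiles)`.
#' @export
average_group <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  if (!all(vapply(profiles, inherits, logical(1), "correlation_profile")))
    stop("inputs must be correlation profiles")
  tr <- vapply(profiles, `[[`, character(1), "transform")
  if (!all(tr == "fisher_z"))
    stop("all profiles must be Fisher-Z transformed before averaging")
  dims <- vapply(profiles, function(p) nrow(p$values), integer(1))
  if (length(unique(dims)) != 1) stop("profiles have mismatched seed counts")
  idx <- lapply(profiles, `[[`, "seed_index")
  if (!all(vapply(idx, identical, logical(1), idx[[1]])))
    stop("profiles have mismatched seed voxel orderings")
  acc <- Reduce(`+`, lapply(profiles, `[[`, "values")) / length(profiles)
  out <- profiles[[1]]
  out$values <- acc
  out$n_averaged <- length(profiles)
  out
}
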