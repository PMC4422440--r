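# Seed masks: the set of voxels defining the region to parcellate, with the
# grid geometry needed to map voxel indices to world (mm) coordinates.

#' Construct a seed mask
#'
#' A seed mask is the list of voxels (0-based grid indices) belonging to the
#' region to be parcellated, together with the grid shape and the
#' grid-to-world affine. Voxels are kept in canonical order: sorted by grid
#' index with the x index varying fastest. This ordering is the alignment
#' contract for all seed-by-target matrices and parcellations.
#'
#' @param voxels integer matrix, n x 3, 0-based grid indices (i, j, k).
#' @param dim integer vector of length 3, grid shape.
#' @param affine 4 x 4 matrix mapping homogeneous voxel indices to world mm
#'   (RAS+ convention: world x increases to the right).
#' @param hemisphere `"left"`, `"right"`, or `NA`.
#' @return An object of class `seed_mask`.
#' @export
seed_mask <- function(voxels, dim, affine, hemisphere = NA_character_) {
  voxels <- matrix(as.integer(voxels), ncol = 3,
                   dimnames = list(NULL, c("i", "j", "k")))
  stopifnot(length(dim) == 3, all(dim >= 1),
            is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (nrow(voxels) == 0L) stop("seed mask contains no voxels")
  if (any(voxels < 0L) || any(voxels >= rep(as.integer(dim), each = nrow(voxels))))
    stop("seed mask voxel indices fall outside the grid")
  ord <- order(voxels[, 3], voxels[, 2], voxels[, 1])
  voxels <- voxels[ord, , drop = FALSE]
  if (anyDuplicated(voxels)) stop("duplicate voxels in seed mask")
  structure(list(voxels = voxels, dim = as.integer(dim), affine = affine,
                 hemisphere = hemisphere, n_voxels = nrow(voxels)),
            class = "seed_mask")
}

#' @export
print.seed_mask <- function(x, ...) {
  cat(sprintf("Seed mask (%s): %d voxels on a %s grid\n",
              ifelse(is.na(x$hemisphere), "unspecified hemisphere", x$hemisphere),
              x$n_voxels, paste(x$dim, collapse = " x ")))
  invisible(x)
}

#' World-space (mm) coordinates of seed-mask voxels
#'
#' @param mask a `seed_mask`.
#' @return n x 3 matrix of world coordinates under the mask affine.
#' @export
voxel_world_coords <- function(mask) {
  h <- cbind(mask$voxels, 1)
  w <- h %*% t(mask$affine)
  w[, 1:3, drop = FALSE]
}

#' Build a seed mask from probability maps
#'
#' Thresholds each probabilistic map and takes the union of suprathreshold
#' voxels across maps, the standard way a cytoarchitectonic region is turned
#' into a binary seed (e.g. combining the two frontal-pole probability maps
#' per hemisphere at a 50% threshold). Map values may be on a 0-1 or a 0-100
#' scale; the scale is auto-detected (any value > 1 implies percent) and the
#' threshold is interpreted on the detected scale. A voxel exactly at
#' threshold is included.
#'
#' @param prob_maps list of 3D numeric arrays (or `RNifti` images) on a
#'   shared grid.
#' @param threshold proportion in (0, 1]; compared after rescaling percent
#'   maps to proportions.
#' @param affine 4 x 4 grid-to-world affine; taken from the first map's
#'   NIfTI header when available.
#' @param hemisphere optional hemisphere tag.
#' @return A `seed_mask` of the union of suprathreshold voxels.
#' @export
build_seed_mask <- function(prob_maps, threshold = 0.5, affine = NULL,
                            hemisphere = NA_character_) {
  if (!is.list(prob_maps)) prob_maps <- list(prob_maps)
  stopifnot(length(prob_maps) >= 1, threshold > 0, threshold <= 1)
  dims <- lapply(prob_maps, function(m) dim(m)[1:3])
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("probability maps do not share a grid")
  if (is.null(affine)) {
    affine <- tryCatch(matrix(RNifti::xform(prob_maps[[1]]), 4, 4),
                       error = function(e) NULL)
    if (is.null(affine)) affine <- diag(4)
  }
  keep <- array(FALSE, dim = dims[[1]])
  for (m in prob_maps) {
    a <- as.array(m)
    if (any(!is.finite(a))) stop("non-finite values in probability map")
    if (max(a) > 1) a <- a / 100  # percent-scale map
    keep <- keep | (a >= threshold)
  }
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no voxel reaches the threshold in any map")
  seed_mask(idx - 1L, dims[[1]], affine, hemisphere)
}

#' Render labels (or mask membership) as a 3D volume
#'
#' @param mask a `seed_mask`.
#' @param values per-voxel values in mask order; default 1 (binary mask).
#' @return 3D array of `mask$dim` with `values` at mask voxels, 0 elsewhere.
#' @export
mask_to_volume <- function(mask, values = 1) {
  vol <- array(0, dim = mask$dim)
  lin <- 1L + mask$voxels[, 1] +
    mask$dim[1] * (mask$voxels[, 2] + mask$dim[2] * mask$voxels[, 3])
  vol[lin] <- values
  vol
}

#' Read / write a seed mask as a NIfTI label volume
#'
#' Nonzero voxels of the volume become mask voxels; the affine is taken from
#' the NIfTI sform/qform.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param hemisphere optional hemisphere tag on read.
#' @return `read_seed_mask`: a `seed_mask`. `write_seed_mask`: the path,
#'   invisibly.
#' @export
read_seed_mask <- function(path, hemisphere = NA_character_) {
  img <- RNifti::readNifti(path)
  affine <- matrix(RNifti::xform(img), 4, 4)
  a <- as.array(img)
  idx <- which(a != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask volume is empty: ", path)
  seed_mask(idx - 1L, dim(a)[1:3], affine, hemisphere)
}

#' @rdname read_seed_mask
#' @param mask a `seed_mask`.
#' @param values optional per-voxel values (e.g. cluster labels).
#' @export
write_seed_mask <- function(mask, path, values = 1) {
  vol <- mask_to_volume(mask, values)
  img <- RNifti::asNifti(vol)
  spacing <- sqrt(colSums(mask$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- spacing
  img <- RNifti::`sform<-`(img, structure(mask$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Mirror a seed mask across the midsagittal plane
#'
#' Reflects voxel world coordinates about world x = 0 and re-expresses them
#' as grid indices on the grid of `target_geom` (by default the mask's own
#' grid). Used to bring a right-hemisphere mask into register with the left
#' for the symmetry computation. Mirrored coordinates must land on grid
#' points (true in a symmetric standard space).
#'
#' @param mask a `seed_mask`.
#' @param target_geom a `seed_mask` supplying the destination grid and
#'   affine; defaults to `mask`.
#' @return A `seed_mask` on the destination grid containing the voxels whose
#'   mirrored position falls inside that grid.
#' @export
mirror_mask_x <- function(mask, target_geom = mask) {
  w <- voxel_world_coords(mask)
  w[, 1] <- -w[, 1]
  inv <- solve(target_geom$affine)
  g <- cbind(w, 1) %*% t(inv)
  g <- g[, 1:3, drop = FALSE]
  gi <- round(g)
  if (max(abs(g - gi)) > 1e-6)
    stop("mirrored voxels do not land on grid points; grids are not x-symmetric")
  inside <- gi[, 1] >= 0 & gi[, 2] >= 0 & gi[, 3] >= 0 &
    gi[, 1] < target_geom$dim[1] & gi[, 2] < target_geom$dim[2] &
    gi[, 3] < target_geom$dim[3]
  if (!any(inside)) stop("no mirrored voxel falls inside the destination grid")
  seed_mask(gi[inside, , drop = FALSE], target_geom$dim, target_geom$affine,
            hemisphere = setdiff(c("left", "right"), mask$hemisphere)[1])
}

# linear (1-based) index into a volume for 0-based voxel triplets
.voxel_lin <- function(voxels, dim) {
  1L + voxels[, 1] + dim[1] * (voxels[, 2] + dim[2] * voxels[, 3])
}

# mirrored (x -> -x) grid indices of mask voxels on target_geom's grid, in
# the mask's own voxel order; returns list(voxels, inside)
.mirror_voxels_x <- function(mask, target_geom) {
  w <- voxel_world_coords(mask)
  w[, 1] <- -w[, 1]
  g <- cbind(w, 1) %*% t(solve(target_geom$affine))
  g <- g[, 1:3, drop = FALSE]
  gi <- round(g)
  if (max(abs(g - gi)) > 1e-6)
    stop("mirrored voxels do not land on grid points; grids are not x-symmetric")
  inside <- gi[, 1] >= 0 & gi[, 2] >= 0 & gi[, 3] >= 0 &
    gi[, 1] < target_geom$dim[1] & gi[, 2] < target_geom$dim[2] &
    gi[, 3] < target_geom$dim[3]
  list(voxels = gi, inside = inside)
}
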