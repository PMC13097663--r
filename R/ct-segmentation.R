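#' Gray-value CT volume
#'
#' @param voxels 3D numeric array of intensities (arbitrary units).
#' @param spacing voxel spacing, 3 positive reals (mm/voxel).
#' @return An object of class `grey_volume`.
#' @export
grey_volume <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive reals")
  structure(list(voxels = voxels, spacing = spacing), class = "grey_volume")
}

#' Binary segmentation volume
#'
#' @param voxels 3D logical array (`TRUE` = bone).
#' @param spacing voxel spacing as in [grey_volume()].
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  storage.mode(voxels) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive reals")
  structure(list(voxels = voxels, spacing = spacing), class = "binary_volume")
}

#' @export
print.grey_volume <- function(x, ...) {
  cat(sprintf("<grey_volume> %s voxels, range [%.4g, %.4g]\n",
              paste(dim(x$voxels), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s voxels, %d foreground (%.2f%%)\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              100 * mean(x$voxels)))
  invisible(x)
}

# Squared Euclidean distance (voxel units) to the nearest TRUE voxel.
edt_squared <- function(mask) {
  d <- dim(mask)
  array(.edt_sq_cpp(as.logical(mask), as.integer(d)), dim = d)
}

#' Morphological erosion with a ball structuring element
#'
#' Erodes a binary mask by a Euclidean ball of the given radius (voxel
#' units), implemented through the exact distance transform: a voxel survives
#' iff its distance to the nearest background voxel exceeds the radius.
#' Voxels outside the volume count as background. May return an empty mask.
#'
#' @param mask a [binary_volume] or 3D logical array.
#' @param radius non-negative integer radius in voxels.
#' @return object of the same kind as `mask`.
#' @export
erode_binary <- function(mask, radius) {
  if (radius < 0) stop("radius must be >= 0")
  vox <- if (inherits(mask, "binary_volume")) mask$voxels else mask
  if (radius == 0) return(mask)
  padded <- array(FALSE, dim(vox) + 2L)
  padded[2:(dim(vox)[1] + 1L), 2:(dim(vox)[2] + 1L), 2:(dim(vox)[3] + 1L)] <- vox
  dist_bg <- edt_squared(!padded)
  eroded <- (dist_bg > radius^2)[2:(dim(vox)[1] + 1L), 2:(dim(vox)[2] + 1L),
                                 2:(dim(vox)[3] + 1L), drop = FALSE]
  dim(eroded) <- dim(vox)
  if (inherits(mask, "binary_volume")) binary_volume(eroded, mask$spacing) else eroded
}

#' Half-maximum-height threshold specification
#'
#' The global threshold midway between the mean bone and mean background
#' intensities: (a - b)/2 + b, with a = mean bone gray value and b = mean
#' background gray value.
#'
#' @param mean_bone mean intensity of the bone seed region (a).
#' @param mean_background mean intensity of the background seed region (b).
#' @return An object of class `threshold_spec` with field `threshold`.
#' @export
threshold_spec <- function(mean_bone, mean_background) {
  if (!(mean_bone > mean_background))
    stop("mean bone intensity (", format(mean_bone),
         ") must exceed mean background intensity (", format(mean_background), ")")
  structure(list(mean_bone = mean_bone, mean_background = mean_background,
                 threshold = (mean_bone - mean_background) / 2 + mean_background),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> bone %.4g / background %.4g -> threshold %.4g\n",
              x$mean_bone, x$mean_background, x$threshold))
  invisible(x)
}

#' Global half-maximum-height threshold segmentation
#'
#' The global-threshold protocol: (i) rough bone and background seed regions
#' are shrunk by morphological erosion (defaults: bone by 10 voxels,
#' background by 30); (ii) mean gray values are computed within the eroded
#' seeds; (iii) the optimal global threshold is (a - b)/2 + b, and voxels with
#' intensity >= threshold are classified as bone.
#'
#' @param volume a [grey_volume].
#' @param bone_seed,background_seed [binary_volume] rough seed masks.
#' @param shrink_bone,shrink_background erosion radii in voxels (defaults
#'   10 and 30).
#' @return list with `threshold_spec` and `segmentation` (a [binary_volume]).
#' @export
global_halfmax_threshold <- function(volume, bone_seed, background_seed,
                                     shrink_bone = 10L, shrink_background = 30L) {
  stopifnot(inherits(volume, "grey_volume"))
  bs <- erode_binary(bone_seed, shrink_bone)
  gs <- erode_binary(background_seed, shrink_background)
  if (!sum(bs$voxels))
    stop("bone seed empty after erosion by ", shrink_bone,
         " voxels; use a smaller shrink radius or a larger seed")
  if (!sum(gs$voxels))
    stop("background seed empty after erosion by ", shrink_background,
         " voxels; use a smaller shrink radius or a larger seed")
  spec <- threshold_spec(mean(volume$voxels[bs$voxels]),
                         mean(volume$voxels[gs$voxels]))
  list(threshold_spec = spec,
       segmentation = binary_volume(volume$voxels >= spec$threshold,
                                    volume$spacing))
}

#' Slice-wise local Otsu segmentation
#'
#' Each pixel of each 2D slice (slices along the third axis) is thresholded
#' by the Otsu criterion — maximal between-class variance on a 256-bin
#' histogram over the slice's intensity range — computed over its square
#' neighborhood of half-width `radius`, clipped at the slice border. Pixels
#' whose neighborhood holds a single gray level are classified background.
#'
#' Flat (unimodal) regions are resolved by a bimodality cascade on Otsu's
#' effectiveness metric eta = between-class variance / total variance of the
#' optimal split: a neighborhood with eta below `eta_min` is not genuinely
#' two-material (pure noise reaches eta of about 0.64-0.71), so its pixel is
#' classified by the slice-global Otsu threshold instead, and a slice that is
#' itself unimodal is entirely background. This keeps noise-only interior
#' regions from being split in half while leaving boundary neighborhoods
#' (eta typically > 0.87) under genuine local thresholding.
#'
#' @param volume a [grey_volume].
#' @param radius local domain radius in pixels (default 5).
#' @param eta_min bimodality criterion on Otsu's effectiveness metric
#'   (default 0.78, between the unimodal-noise and two-material regimes).
#' @return a [binary_volume].
#' @export
local_otsu <- function(volume, radius = 5L, eta_min = 0.78) {
  stopifnot(inherits(volume, "grey_volume"))
  if (radius < 1L) stop("radius must be >= 1")
  d <- dim(volume$voxels)
  res <- .local_otsu_cpp(as.numeric(volume$voxels), as.integer(d),
                         as.integer(radius), eta_min)
  binary_volume(array(res, d), volume$spacing)
}

.reslice_perms <- list(original = 1:3, top_bottom = c(1L, 3L, 2L),
                       left_right = c(3L, 2L, 1L))

#' Reslice a volume for a different slicing direction
#'
#' Permutes the volume axes so that 2D slices are taken along a different
#' anatomical direction: `"original"` is the identity, `"top_bottom"` swaps
#' the second and third axes, `"left_right"` swaps the first and third. Both
#' permutations are involutions, so applying the same reslice twice restores
#' the original volume. Spacing is permuted consistently.
#'
#' @param volume a [grey_volume] or [binary_volume].
#' @param orientation one of `"original"`, `"top_bottom"`, `"left_right"`.
#' @return volume of the same class with permuted axes.
#' @export
reslice <- function(volume, orientation = c("original", "top_bottom", "left_right")) {
  orientation <- match.arg(orientation)
  perm <- .reslice_perms[[orientation]]
  vox <- aperm(volume$voxels, perm)
  sp <- volume$spacing[perm]
  if (inherits(volume, "binary_volume")) binary_volume(vox, sp)
  else grey_volume(vox, sp)
}

#' Combine three segmentations by 2-of-3 voting
#'
#' A voxel is classified as bone iff at least two of the three input
#' segmentations classify it as bone. Symmetric in its arguments.
#'
#' @param m1,m2,m3 [binary_volume]s of identical shape.
#' @return a [binary_volume].
#' @export
vote_combine <- function(m1, m2, m3) {
  if (!identical(dim(m1$voxels), dim(m2$voxels)) ||
      !identical(dim(m1$voxels), dim(m3$voxels)))
    stop("segmentations have mismatched shapes")
  binary_volume((m1$voxels + m2$voxels + m3$voxels) >= 2L, m1$spacing)
}

#' Local-Otsu + reslicing + 2-of-3 vote segmentation
#'
#' Runs slice-wise local Otsu thresholding on the original volume and on the
#' two resliced versions (top-to-bottom and left-to-right slicing), maps the
#' resliced results back, and combines the three by the 2-of-3 voting rule.
#'
#' @inheritParams local_otsu
#' @return a [binary_volume].
#' @export
otsu_vote_segment <- function(volume, radius = 5L, eta_min = 0.78) {
  m1 <- local_otsu(volume, radius, eta_min)
  m2 <- reslice(local_otsu(reslice(volume, "top_bottom"), radius, eta_min), "top_bottom")
  m3 <- reslice(local_otsu(reslice(volume, "left_right"), radius, eta_min), "left_right")
  vote_combine(m1, m2, m3)
}

boundary_voxels <- function(vox) {
  d <- dim(vox)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- vox
  inner <- padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
  nb_all <- padded[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE] &
    padded[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE] &
    padded[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L), drop = FALSE] &
    padded[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L), drop = FALSE] &
    padded[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3], drop = FALSE] &
    padded[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L), drop = FALSE]
  out <- inner & !nb_all
  dim(out) <- d
  out
}

#' Compare two binary segmentations
#'
#' Voxel-wise disagreement count, Dice coefficient, and the maximum boundary
#' distance in voxels (directed both ways between the voxelized surfaces,
#' i.e. a discrete symmetric Hausdorff distance).
#'
#' @param a,b [binary_volume]s of identical shape and spacing.
#' @return list with `n_disagree`, `dice`, `max_boundary_distance`,
#'   and the directed distances `dist_a_to_b`, `dist_b_to_a`.
#' @export
segmentation_compare <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("segmentations have mismatched shapes")
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    stop("segmentations have mismatched spacing")
  va <- a$voxels; vb <- b$voxels
  n_disagree <- sum(va != vb)
  denom <- sum(va) + sum(vb)
  dice <- if (denom == 0) 1 else 2 * sum(va & vb) / denom
  ba <- boundary_voxels(va); bb <- boundary_voxels(vb)
  directed <- function(from, to) {
    if (!any(from)) return(0)
    if (!any(to)) return(Inf)
    sqrt(max(edt_squared(to)[from]))
  }
  dab <- directed(ba, bb)
  dba <- directed(bb, ba)
  list(n_disagree = n_disagree, dice = dice,
       max_boundary_distance = max(dab, dba),
       dist_a_to_b = dab, dist_b_to_a = dba)
}
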