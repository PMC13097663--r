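tps_kernel <- function(r, D) {
  if (D == 3L) return(r)
  # 2D biharmonic kernel r^2 log r, with U(0) = 0
  out <- r^2 * log(ifelse(r > 0, r, 1))
  out
}

#' Fit a thin-plate-spline mapping
#'
#' Exact (non-smoothed) thin-plate-spline interpolation from `source` control
#' points to `target` control points, solving the standard bordered linear
#' system \[\[K, P\], \[t(P), 0\]\] (w; a) = (target; 0) with the biharmonic
#' kernel U(r) = r in 3D and U(r) = r^2 log r in 2D. The resulting mapping
#' reproduces the control points exactly and reproduces any affine map
#' exactly (zero non-affine warp).
#'
#' @param source m x D matrix of control points (m >= D + 2, not all
#'   collinear/coplanar).
#' @param target m x D matrix of corresponding targets.
#' @return An object of class `tps_mapping`: `source_points`, `weights`
#'   (m x D), `affine` ((D+1) x D, first row the translation), `kernel` tag.
#' @export
tps_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target)))
    stop("source and target must have identical dimensions")
  m <- nrow(source); D <- ncol(source)
  if (m < D + 2L) stop("need at least D + 2 = ", D + 2L, " control points, got ", m)
  K <- tps_kernel(as.matrix(stats::dist(source)), D)
  P <- cbind(1, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, D + 1L, D + 1L)))
  rhs <- rbind(target, matrix(0, D + 1L, D))
  coefs <- tryCatch(solve(L, rhs),
                    error = function(e) stop("degenerate source configuration ",
                                             "(collinear/coplanar control points): ",
                                             conditionMessage(e)))
  structure(
    list(source_points = source,
         weights = coefs[seq_len(m), , drop = FALSE],
         affine = coefs[m + seq_len(D + 1L), , drop = FALSE],
         kernel = if (D == 3L) "r" else "r2logr"),
    class = "tps_mapping"
  )
}

#' Apply a thin-plate-spline mapping
#'
#' Evaluates f(x) = a (1, x) + sum_j w_j U(||x - s_j||) at arbitrary points.
#'
#' @param mapping a [tps_mapping] from [tps_fit()].
#' @param points q x D matrix (or a single point as a vector).
#' @return q x D matrix of mapped points.
#' @export
tps_apply <- function(mapping, points) {
  D <- ncol(mapping$source_points)
  if (is.null(dim(points))) points <- matrix(points, ncol = D)
  points <- as.matrix(points)
  if (ncol(points) != D) stop("points have wrong dimensionality")
  # q x m distance matrix to control points
  sq <- outer(rowSums(points^2), rep(1, nrow(mapping$source_points))) +
    outer(rep(1, nrow(points)), rowSums(mapping$source_points^2)) -
    2 * points %*% t(mapping$source_points)
  r <- sqrt(pmax(sq, 0))
  U <- tps_kernel(r, D)
  cbind(1, points) %*% mapping$affine + U %*% mapping$weights
}

# Ordinary Procrustes fit of the rows `idx` of coords onto ref[idx, ]:
# returns the similarity transform (and its inverse) mapping specimen space
# into the reference frame.
opa_transform <- function(coords, ref, idx) {
  x <- coords[idx, , drop = FALSE]
  y <- ref[idx, , drop = FALSE]
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  csx <- sqrt(sum(xc^2)); csy <- sqrt(sum(yc^2))
  if (csx <= 0 || csy <= 0) stop("degenerate landmark subset in superimposition")
  R <- optimal_rotation(xc / csx, yc / csy)
  s <- csy / csx
  list(
    fwd = function(p) sweep(sweep(p, 2, mx) %*% R * s, 2, my, `+`),
    inv = function(p) sweep(sweep(p, 2, my) %*% t(R) / s, 2, mx, `+`)
  )
}

#' Estimate missing landmarks by within-group thin-plate spline
#'
#' For each group (typically species), the reference is the Procrustes mean
#' shape of the group's complete specimens. Each incomplete specimen is first
#' superimposed on the reference using its present landmarks (translation,
#' scale, rotation); a TPS mapping is fitted from the reference's
#' present-landmark subset to the specimen's present landmarks, applied to the
#' reference coordinates of the missing landmarks, and the estimates are
#' back-transformed to the specimen's original frame. A single pass is made;
#' the output dataset has an empty missing mask.
#'
#' @param dataset a [landmark_dataset].
#' @param group_by metadata column defining the estimation groups
#'   (default "species").
#' @return The completed [landmark_dataset]; attribute `estimation_log` is a
#'   data.frame of per-specimen estimated-landmark counts.
#' @export
estimate_missing <- function(dataset, group_by = "species") {
  stopifnot(inherits(dataset, "landmark_dataset"))
  miss_tot <- sum(dataset$missing_report$n_missing)
  log_df <- dataset$missing_report[dataset$missing_report$n_missing > 0, , drop = FALSE]
  if (miss_tot == 0L) {
    attr(dataset, "estimation_log") <- data.frame(specimen_id = character(),
                                                  n_estimated = integer())
    return(dataset)
  }
  if (!group_by %in% names(dataset$metadata))
    stop("grouping column '", group_by, "' not in metadata")
  groups <- as.character(dataset$metadata[[group_by]])
  ids <- names(dataset$configurations)
  D <- ncol(dataset$configurations[[1]]$coords)
  configs <- dataset$configurations
  for (g in unique(groups)) {
    gi <- which(groups == g)
    complete_i <- gi[vapply(configs[gi], function(cf) !any(cf$missing), logical(1))]
    incomplete_i <- setdiff(gi, complete_i)
    if (!length(incomplete_i)) next
    if (!length(complete_i))
      stop("group '", g, "' has no complete specimens to build a reference")
    ref <- if (length(complete_i) == 1L) {
      cc <- configs[[complete_i]]$coords
      center_config(cc) / centroid_size(cc)
    } else {
      arr <- array(NA_real_, c(length(dataset$labels), D, length(complete_i)))
      for (j in seq_along(complete_i)) arr[, , j] <- configs[[complete_i[j]]]$coords
      dimnames(arr)[[1]] <- dataset$labels
      gpa(arr)$consensus
    }
    rownames(ref) <- dataset$labels
    for (i in incomplete_i) {
      cf <- configs[[i]]
      present <- which(!cf$missing)
      if (length(present) < D + 2L)
        stop("specimen '", cf$specimen_id, "' has only ", length(present),
             " present landmarks; at least ", D + 2L, " required")
      tr <- opa_transform(cf$coords, ref, present)
      spec_in_ref <- tr$fwd(cf$coords[present, , drop = FALSE])
      mapping <- tps_fit(ref[present, , drop = FALSE], spec_in_ref)
      est_ref_frame <- tps_apply(mapping, ref[cf$missing, , drop = FALSE])
      est <- tr$inv(est_ref_frame)
      new_coords <- cf$coords
      new_coords[cf$missing, ] <- est
      configs[[i]] <- landmark_config(new_coords, labels = cf$labels,
                                      specimen_id = cf$specimen_id,
                                      missing = rep(FALSE, length(cf$labels)))
    }
  }
  out <- assemble_dataset(configs, dataset$metadata, dataset$pairing,
                          template = dataset$labels)
  attr(out, "estimation_log") <- data.frame(specimen_id = log_df$specimen_id,
                                            n_estimated = log_df$n_missing)
  out
}
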