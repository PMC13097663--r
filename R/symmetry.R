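#' Reflect and relabel a configuration
#'
#' The relabelled reflection used in object-symmetry analysis of bilaterally
#' symmetric structures (skulls bisected by the mid-sagittal plane): the first
#' coordinate axis is negated, then the coordinates of each (left, right)
#' landmark pair are swapped; midline landmarks are only reflected. Applying
#' the operation twice returns the input (involution), and a configuration
#' that is perfectly mirror-symmetric about the x = 0 plane is a fixed point.
#'
#' The reflection axis defaults to the first coordinate axis; because the
#' doubled set is re-superimposed by GPA downstream, the choice is
#' immaterial to the symmetric component (tested as a property).
#'
#' @param coords k x D coordinate matrix with rownames equal to the landmark
#'   labels (or in the order of `labels`).
#' @param pairing a [pairing_map] covering every label.
#' @param labels landmark labels, defaulting to `rownames(coords)`.
#' @param axis coordinate axis to negate (default 1).
#' @return k x D matrix in the same label order as the input.
#' @export
reflect_relabel <- function(coords, pairing, labels = rownames(coords), axis = 1L) {
  coords <- as.matrix(coords)
  if (is.null(labels)) stop("landmark labels required (rownames or 'labels')")
  if (axis < 1L || axis > ncol(coords)) stop("invalid reflection axis")
  absent <- setdiff(labels, pairing_labels(pairing))
  if (length(absent))
    stop("labels absent from pairing map: ", paste(absent, collapse = ", "))
  refl <- coords
  refl[, axis] <- -refl[, axis]
  out <- refl
  li <- match(pairing$pairs[, 1], labels)
  ri <- match(pairing$pairs[, 2], labels)
  out[li, ] <- refl[ri, , drop = FALSE]
  out[ri, ] <- refl[li, , drop = FALSE]
  dimnames(out) <- dimnames(coords)
  out
}

#' Bilateral (object) symmetry decomposition
#'
#' Extracts the symmetric component of each specimen's shape for a structure
#' bisected by the midline plane. The original configurations and their
#' relabelled reflections are superimposed jointly by GPA; the symmetric
#' component of a specimen is the mean of its two aligned copies, and the
#' asymmetric component is the aligned original minus the symmetric component,
#' so the decomposition reconstructs the aligned original exactly. Downstream
#' shape statistics consume the symmetric component.
#'
#' @param dataset a [landmark_dataset] with a pairing map and no missing
#'   landmarks, or a k x D x n array plus `pairing`.
#' @param pairing a [pairing_map]; taken from the dataset when omitted.
#' @param axis reflection axis passed to [reflect_relabel()] (default 1;
#'   the joint GPA makes the choice immaterial).
#' @param ... passed to [gpa()].
#' @return An object of class `symmetry_decomposition`: `symmetric` and
#'   `asymmetric` (k x D x n), `consensus` (of the doubled set), and
#'   `centroid_sizes` / `log_cs` carried from the original configurations.
#' @export
symmetry_decomposition <- function(dataset, pairing = NULL, axis = 1L, ...) {
  if (inherits(dataset, "landmark_dataset")) {
    if (is.null(pairing)) pairing <- dataset$pairing
    arr <- dataset_array(dataset)
  } else {
    arr <- dataset
  }
  if (is.null(pairing)) stop("a pairing_map is required for symmetry decomposition")
  k <- dim(arr)[1]; D <- dim(arr)[2]; n <- dim(arr)[3]
  labels <- dimnames(arr)[[1]]
  if (is.null(labels)) stop("coordinate array must carry landmark labels as dimnames")
  doubled <- array(NA_real_, dim = c(k, D, 2L * n))
  doubled[, , seq_len(n)] <- arr
  for (i in seq_len(n))
    doubled[, , n + i] <- reflect_relabel(arr[, , i], pairing, labels = labels,
                                          axis = axis)
  dimnames(doubled) <- list(labels, dimnames(arr)[[2]], NULL)
  fit <- gpa(doubled, ...)
  sym <- array(NA_real_, dim = dim(arr), dimnames = dimnames(arr))
  asym <- sym
  for (i in seq_len(n)) {
    sym[, , i] <- (fit$aligned[, , i] + fit$aligned[, , n + i]) / 2
    asym[, , i] <- fit$aligned[, , i] - sym[, , i]
  }
  cs <- fit$centroid_sizes[seq_len(n)]
  names(cs) <- dimnames(arr)[[3]]
  structure(
    list(symmetric = sym, asymmetric = asym, consensus = fit$consensus,
         centroid_sizes = cs, log_cs = log(cs), gpa_fit = fit),
    class = "symmetry_decomposition"
  )
}

#' @export
print.symmetry_decomposition <- function(x, ...) {
  d <- dim(x$symmetric)
  cat(sprintf("<symmetry_decomposition> %d specimens x %d landmarks (%dD); mean |asymmetry| = %.3g\n",
              d[3], d[1], d[2], mean(sqrt(apply(x$asymmetric^2, 3, sum)))))
  invisible(x)
}
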