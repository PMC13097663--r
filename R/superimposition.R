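#' Centroid size
#'
#' The square root of the summed squared distances of all landmarks to their
#' centroid — the size measure removed by Procrustes superimposition and used,
#' log-transformed, as the allometry covariate.
#'
#' @param coords numeric k x D coordinate matrix with no missing values.
#' @return positive scalar, in the units of the coordinates (mm).
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  if (any(is.na(coords))) stop("centroid_size: coordinates contain missing values")
  ctr <- colMeans(coords)
  cs <- sqrt(sum(sweep(coords, 2, ctr)^2))
  if (cs <= .Machine$double.eps * nrow(coords))
    stop("degenerate configuration: all landmarks coincide (centroid size 0)")
  cs
}

center_config <- function(coords) sweep(coords, 2, colMeans(coords))

#' Optimal rotation between two centred configurations
#'
#' Solves the orthogonal Procrustes problem: the proper rotation R
#' (det R = +1) minimising ||A R - B||^2, by singular value decomposition of
#' the cross-covariance t(A) B with the conventional sign correction on the
#' last singular vector so reflections are never returned.
#'
#' @param A,B centred k x D matrices, D in {2, 3}.
#' @return D x D rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(dim(A), dim(B))) stop("A and B must have identical dimensions")
  D <- ncol(A)
  if (!D %in% c(2L, 3L)) stop("optimal_rotation supports D = 2 or 3")
  M <- crossprod(A, B)
  sv <- svd(M)
  s <- sign(det(sv$u %*% t(sv$v)))
  if (s == 0) s <- 1
  if (min(sv$d) < 1e-12 * max(sv$d, 1e-300)) {
    if (s < 0)
      warning("rank-deficient cross-covariance: rotation optimum ambiguous; ",
              "using deterministic SVD sign convention")
  }
  d <- c(rep(1, D - 1), s)
  sv$u %*% (d * t(sv$v))
}

#' Procrustes distance between aligned shapes
#'
#' Euclidean norm of the coordinate difference between two configurations in
#' a common alignment frame (the partial Procrustes distance).
#'
#' @param a,b k x D shape matrices, centred, unit centroid size, aligned.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("shape dimension mismatch")
  sqrt(sum((a - b)^2))
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition removing location, scale and orientation:
#' every configuration is centred and scaled to unit centroid size, then
#' repeatedly rotated to the current consensus; the consensus is the mean of
#' the aligned configurations, rescaled to unit centroid size. Iteration stops
#' when the summed squared change in the consensus falls below `tol`.
#' Reflections are never used. Centroid sizes are recorded from the original
#' (pre-scaling) configurations.
#'
#' @param x a [landmark_dataset] with no missing landmarks, or a k x D x n
#'   array.
#' @param tol convergence tolerance on the consensus change (default 1e-10).
#' @param max_iter iteration cap (default 500; real shape data converges in
#'   a handful of iterations, while unstructured random configurations can
#'   approach the tight tolerance slowly); non-convergence leaves
#'   `converged = FALSE` with a warning.
#' @return An object of class `procrustes_result`: `aligned` (k x D x n),
#'   `consensus` (k x D, unit centroid size), `centroid_sizes`, `log_cs`,
#'   `n_iterations`, `converged`.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 500L) {
  arr <- if (inherits(x, "landmark_dataset")) dataset_array(x) else x
  if (length(dim(arr)) != 3L) stop("expected a k x D x n coordinate array")
  k <- dim(arr)[1]; D <- dim(arr)[2]; n <- dim(arr)[3]
  cs <- numeric(n)
  aligned <- arr
  for (i in seq_len(n)) {
    ci <- center_config(arr[, , i])
    cs[i] <- centroid_size(arr[, , i])
    aligned[, , i] <- ci / cs[i]
  }
  consensus <- aligned[, , 1]
  iter <- 0L
  converged <- FALSE
  if (n == 1L) {
    iter <- 1L
    converged <- TRUE
  } else {
    repeat {
      iter <- iter + 1L
      for (i in seq_len(n))
        aligned[, , i] <- aligned[, , i] %*% optimal_rotation(aligned[, , i], consensus)
      new_cons <- apply(aligned, c(1, 2), mean)
      new_cons <- center_config(new_cons)
      new_cons <- new_cons / centroid_size(new_cons)
      delta <- sum((new_cons - consensus)^2)
      consensus <- new_cons
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    if (!converged)
      warning("GPA did not converge in ", max_iter, " iterations (last change ",
              format(delta), ")")
  }
  dimnames(aligned) <- dimnames(arr)
  ids <- dimnames(arr)[[3]]
  names(cs) <- ids
  structure(
    list(aligned = aligned, consensus = consensus, centroid_sizes = cs,
         log_cs = log(cs), n_iterations = iter, converged = converged),
    class = "procrustes_result"
  )
}

#' @export
print.procrustes_result <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("<procrustes_result> %d specimens x %d landmarks (%dD); %d iterations, converged: %s\n",
              d[3], d[1], d[2], x$n_iterations, x$converged))
  invisible(x)
}

#' Flatten a shape array to an n x (k*D) matrix
#'
#' Rows are specimens; columns are landmark-major (all D coordinates of
#' landmark 1, then landmark 2, ...). The inverse of [unflatten_shape()].
#'
#' @param arr k x D x n array of aligned coordinates.
#' @return n x (k*D) matrix.
#' @export
flatten_shapes <- function(arr) {
  k <- dim(arr)[1]; D <- dim(arr)[2]; n <- dim(arr)[3]
  out <- matrix(NA_real_, n, k * D)
  for (i in seq_len(n)) out[i, ] <- as.vector(t(arr[, , i]))
  rownames(out) <- dimnames(arr)[[3]]
  axis <- c("x", "y", "z")[seq_len(D)]
  lab <- dimnames(arr)[[1]]
  if (is.null(lab)) lab <- paste0("LM", seq_len(k))
  colnames(out) <- paste(rep(lab, each = D), rep(axis, k), sep = ".")
  out
}

#' Reshape a flattened shape vector back to k x D
#'
#' @param v numeric vector of length k*D in landmark-major order.
#' @param D dimensionality (2 or 3).
#' @return k x D matrix.
#' @export
unflatten_shape <- function(v, D) {
  if (length(v) %% D != 0) stop("vector length not a multiple of D")
  matrix(v, ncol = D, byrow = TRUE)
}
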