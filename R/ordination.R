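#' Principal component analysis
#'
#' PCA by singular value decomposition of the column-centred data matrix.
#' Eigenvalues are singular values squared over (n - 1). Each eigenvector's
#' sign is fixed so its largest-magnitude element is positive, making output
#' deterministic. Two loading conventions are returned: unit eigenvectors
#' and eigenvalue-scaled loadings (eigenvector times sqrt(eigenvalue)), the
#' latter being the convention under which loading magnitudes can exceed 1.
#'
#' @param X n x p numeric matrix (n >= 2): flattened shape coordinates or a
#'   standardized trait matrix.
#' @return An object of class `pca_result`: `scores` (n x r), `eigenvectors`
#'   (p x r), `eigenvalues`, `variance_fraction`, `loadings`
#'   (eigenvalue-scaled), `center`, with r = min(n - 1, p).
#' @export
pca <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 rows for PCA")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  if (all(abs(Xc) < 1e-14)) stop("constant matrix: no variance to decompose")
  r <- min(n - 1L, ncol(X))
  sv <- svd(Xc, nu = r, nv = r)
  eig <- (sv$d^2) / (n - 1L)
  total_var <- sum(eig)
  eig <- eig[seq_len(r)]
  flip <- vapply(seq_len(r), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  V <- sweep(sv$v, 2L, flip, `*`)
  scores <- Xc %*% V
  pcn <- paste0("PC", seq_len(r))
  dimnames(V) <- list(colnames(X), pcn)
  dimnames(scores) <- list(rownames(X), pcn)
  structure(
    list(scores = scores, eigenvectors = V, eigenvalues = eig,
         variance_fraction = eig / total_var,
         loadings = sweep(V, 2L, sqrt(eig), `*`),
         center = ctr, n = n),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("<pca_result> %d observations, %d components; variance explained: %s\n",
              x$n, length(x$eigenvalues),
              paste(sprintf("PC%d %.1f%%", seq_len(k),
                            100 * x$variance_fraction[seq_len(k)]), collapse = ", ")))
  invisible(x)
}

#' Shape at an extreme of a principal component
#'
#' Reconstructs landmark coordinates at a chosen score along a PC axis of a
#' shape-space PCA: mean shape + score * eigenvector, with the eigenvector
#' reshaped from its flattened landmark-major layout. Typical scores are the
#' minimum and maximum observed scores on the axis.
#'
#' @param pca_fit a `pca_result` computed on flattened shape coordinates.
#' @param mean_shape k x D mean (consensus) shape.
#' @param axis PC index.
#' @param score position along the axis.
#' @return k x D coordinate matrix.
#' @export
pc_extreme_shape <- function(pca_fit, mean_shape, axis, score) {
  stopifnot(inherits(pca_fit, "pca_result"))
  if (axis < 1L || axis > ncol(pca_fit$eigenvectors))
    stop("axis ", axis, " out of range (rank ", ncol(pca_fit$eigenvectors), ")")
  D <- ncol(mean_shape)
  v <- pca_fit$eigenvectors[, axis]
  if (length(v) != length(mean_shape))
    stop("eigenvector length does not match the mean shape")
  mean_shape + score * unflatten_shape(v, D)
}

#' Landmarking-replicate error check
#'
#' Compares digitisation error to biological signal: the mean pairwise
#' Procrustes distance among replicate digitisations of the same specimen
#' divided by the mean pairwise distance among distinct conspecific
#' specimens. Ratios well below 1 indicate that replicates cluster more
#' closely than conspecifics, i.e. negligible landmarking error.
#'
#' @param aligned k x D x n array of aligned shapes (specimen ids as third
#'   dimnames).
#' @param metadata data.frame with `specimen_id`, `species` and
#'   `replicate_of` (`NA` for original digitisations; otherwise the id of the
#'   replicated specimen).
#' @return list with `ratio`, `mean_replicate_distance`,
#'   `mean_conspecific_distance`, and a per-specimen breakdown.
#' @export
replicate_error_check <- function(aligned, metadata) {
  ids <- dimnames(aligned)[[3]]
  md <- metadata[match(ids, metadata$specimen_id), , drop = FALSE]
  rep_of <- as.character(md$replicate_of)
  base_id <- ifelse(is.na(rep_of) | rep_of == "", ids, rep_of)
  groups <- split(seq_along(ids), base_id)
  rep_groups <- groups[lengths(groups) >= 2L]
  if (!length(rep_groups)) stop("no replicated specimens in the dataset")
  pdist <- function(i, j) procrustes_distance(aligned[, , i], aligned[, , j])
  per_spec <- vapply(rep_groups, function(ix) {
    prs <- utils::combn(ix, 2L)
    mean(apply(prs, 2L, function(pr) pdist(pr[1L], pr[2L])))
  }, numeric(1))
  # conspecific distances among distinct specimens (originals only)
  orig <- which(is.na(rep_of) | rep_of == "")
  sp <- as.character(md$species)[orig]
  consp <- unlist(lapply(unique(sp), function(s) {
    ix <- orig[sp == s]
    if (length(ix) < 2L) return(numeric())
    prs <- utils::combn(ix, 2L)
    apply(prs, 2L, function(pr) pdist(pr[1L], pr[2L]))
  }))
  if (!length(consp)) stop("no conspecific specimen pairs to compare against")
  list(ratio = mean(per_spec) / mean(consp),
       mean_replicate_distance = mean(per_spec),
       mean_conspecific_distance = mean(consp),
       per_specimen = data.frame(specimen_id = names(rep_groups),
                                 mean_replicate_distance = unname(per_spec)))
}
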