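#' Permutation effect size
#'
#' Expresses an observed statistic as a standard deviate within its
#' permutation distribution: Z = (g(obs) - mean(g(perm))) / sd(g(perm)),
#' where g is the natural log for F-type statistics (values floored at a
#' small positive epsilon before the log) and the identity for distances.
#' The sd uses the n - 1 denominator.
#'
#' @param observed observed statistic.
#' @param permuted numeric vector of permuted statistics (conventionally
#'   including the observed value as one permutation).
#' @param transform `"log"` for F-type statistics, `"identity"` for distances.
#' @return scalar Z; 0 with a warning when the permutation distribution is
#'   degenerate (sd = 0).
#' @export
effect_size <- function(observed, permuted, transform = c("log", "identity")) {
  transform <- match.arg(transform)
  if (!length(permuted)) stop("empty permutation distribution")
  g <- if (transform == "log") function(x) log(pmax(x, 1e-12)) else identity
  gp <- g(permuted)
  s <- stats::sd(gp)
  if (!is.finite(s) || s == 0) {
    warning("degenerate permutation distribution (sd = 0); Z set to 0")
    return(0)
  }
  (g(observed) - mean(gp)) / s
}

# Build the nested sequence of design matrices for an ordered term list.
# Aliased columns arising from factor redundancy (e.g. nested region:island
# dummies) are dropped; a term contributing no independent columns is an
# error naming the aliased columns.
rrpp_designs <- function(terms, data) {
  n <- nrow(data)
  X_prev <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  designs <- list(X_prev)
  dfs <- integer(length(terms))
  for (i in seq_along(terms)) {
    f <- stats::reformulate(terms[seq_len(i)])
    Xi <- stats::model.matrix(f, data = data)
    qri <- qr(Xi)
    keep <- sort(qri$pivot[seq_len(qri$rank)])
    Xi <- Xi[, keep, drop = FALSE]
    dfs[i] <- ncol(Xi) - ncol(X_prev)
    if (dfs[i] <= 0L) {
      f_alone <- stats::reformulate(terms[i])
      aliased <- setdiff(colnames(stats::model.matrix(f_alone, data = data)),
                         c(colnames(Xi), "(Intercept)"))
      stop("term '", terms[i], "' is rank-deficient given preceding terms; ",
           "aliased columns: ", paste(aliased, collapse = ", "))
    }
    X_prev <- Xi
    designs[[i + 1L]] <- Xi
  }
  list(designs = designs, dfs = dfs)
}

hat_matrix <- function(X) {
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Fit a permutational linear model (randomized residual permutation)
#'
#' Multivariate linear model with sequential (type I) sums of squares over an
#' ordered term list, tested by the randomized residual permutation procedure:
#' for each term, residuals of the reduced model (all preceding terms) are
#' permuted and added to the reduced-model fitted values, and the term's F
#' statistic is recomputed. The observed arrangement counts as one
#' permutation, so the attainable minimum p is 1/(iter + 1). One permutation
#' index matrix is drawn from the seed and shared across terms.
#'
#' @param Y n x p response matrix (a vector is treated as n x 1).
#' @param terms character vector of ordered model terms, e.g.
#'   `c("log_cs", "sex", "species", "sex:species")`.
#' @param data data.frame holding the predictors (n rows, order matching Y).
#' @param iter number of random permutations (default 999; the study-scale
#'   presets use 9999).
#' @param seed integer seed for the permutation schedule.
#' @param perms optional n x m integer matrix of permutation indices
#'   replacing the random schedule (e.g. the full enumeration on tiny n);
#'   the identity permutation is prepended if absent from column 1.
#' @return An object of class `rrpp_fit` with the ANOVA quantities per term
#'   (SS, df, MS, R2, F, Z, p), permutation distributions, and the fitted
#'   design internals reused by [pairwise_groups()].
#' @export
fit_rrpp <- function(Y, terms, data, iter = 999L, seed = NULL, perms = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  if (n != nrow(data)) stop("nrow(Y) != nrow(data)")
  if (iter < 1L) stop("iter must be >= 1")
  des <- rrpp_designs(terms, data)
  Tn <- length(terms)
  H <- lapply(des$designs, hat_matrix)
  df_model <- ncol(des$designs[[Tn + 1L]]) - 1L
  df_res <- n - ncol(des$designs[[Tn + 1L]])
  if (df_res <= 0L) stop("no residual degrees of freedom (n too small for model)")
  if (is.null(perms)) {
    if (!is.null(seed)) set.seed(seed)
    perms <- matrix(0L, n, iter + 1L)
    perms[, 1L] <- seq_len(n)
    for (j in seq_len(iter) + 1L) perms[, j] <- sample.int(n)
  } else {
    perms <- unname(as.matrix(perms))
    storage.mode(perms) <- "integer"
    if (nrow(perms) != n) stop("perms must have n rows")
    if (!all(perms[, 1L] == seq_len(n))) perms <- cbind(seq_len(n), perms)
    iter <- ncol(perms) - 1L
  }
  Rfull <- diag(n) - H[[Tn + 1L]]
  SST <- sum((Y - rep(colMeans(Y), each = n))^2)
  Fdist <- matrix(NA_real_, iter + 1L, Tn, dimnames = list(NULL, terms))
  SSdist <- Fdist
  for (i in seq_len(Tn)) {
    Di <- H[[i + 1L]] - H[[i]]
    Eprev <- Y - H[[i]] %*% Y
    for (j in seq_len(iter + 1L)) {
      Ej <- Eprev[perms[, j], , drop = FALSE]
      ss <- sum((Di %*% Ej)^2)
      ssr <- sum((Rfull %*% Ej)^2)
      SSdist[j, i] <- ss
      Fdist[j, i] <- (ss / des$dfs[i]) / (ssr / df_res)
    }
  }
  SS <- SSdist[1L, ]
  Fobs <- Fdist[1L, ]
  SSR <- sum((Rfull %*% Y)^2)
  tol <- 1e-12 * pmax(1, abs(Fobs))
  pvals <- vapply(seq_len(Tn), function(i)
    mean(Fdist[, i] >= Fobs[i] - tol[i]), numeric(1))
  Z <- vapply(seq_len(Tn), function(i) {
    if (stats::sd(log(pmax(Fdist[, i], 1e-12))) == 0) {
      warning("degenerate permutation distribution for term '", terms[i], "'")
      0
    } else effect_size(Fobs[i], Fdist[, i], "log")
  }, numeric(1))
  names(pvals) <- names(Z) <- terms
  names(des$dfs) <- terms
  structure(
    list(terms = terms, SS = SS, df = des$dfs, MS = SS / des$dfs,
         R2 = SS / SST, F = Fobs, Z = Z, p = pvals,
         SS_residual = SSR, df_residual = df_res, SS_total = SST,
         n = n, p_dim = ncol(Y), n_permutations = iter,
         seed = seed, permutation_F = Fdist, permutation_SS = SSdist,
         Y = Y, data = data, designs = des$designs,
         full_design = des$designs[[Tn + 1L]], H_full = H[[Tn + 1L]]),
    class = "rrpp_fit"
  )
}

#' ANOVA table of an RRPP fit
#'
#' @param fit an `rrpp_fit`.
#' @return data.frame with one row per term plus Residuals and Total rows:
#'   Df, SS, MS, Rsq, F, Z, `Pr(>F)`.
#' @export
anova_table <- function(fit) {
  stopifnot(inherits(fit, "rrpp_fit"))
  k <- length(fit$terms)
  df <- data.frame(
    Df = c(fit$df, fit$df_residual, fit$n - 1L),
    SS = c(fit$SS, fit$SS_residual, fit$SS_total),
    MS = c(fit$MS, fit$SS_residual / fit$df_residual, NA),
    Rsq = c(fit$R2, fit$SS_residual / fit$SS_total, 1),
    F = c(fit$F, NA, NA),
    Z = c(fit$Z, NA, NA),
    `Pr(>F)` = c(fit$p, NA, NA),
    row.names = c(fit$terms, "Residuals", "Total"),
    check.names = FALSE
  )
  df
}

#' @export
print.rrpp_fit <- function(x, digits = 5, ...) {
  cat(sprintf("RRPP linear model: %d observations, %d response dimensions, %d permutations\n",
              x$n, x$p_dim, x$n_permutations))
  tab <- anova_table(x)
  tab$SS <- signif(tab$SS, digits); tab$MS <- signif(tab$MS, digits)
  tab$Rsq <- round(tab$Rsq, digits); tab$F <- signif(tab$F, digits)
  tab$Z <- round(tab$Z, 4); tab$`Pr(>F)` <- signif(tab$`Pr(>F)`, 4)
  print(tab)
  invisible(x)
}

# Least-squares means: predictions per group level at mean covariate values,
# averaged over the observed combinations of the other factors.
ls_means_engine <- function(fit, group) {
  data <- fit$data
  vars <- all.vars(stats::reformulate(fit$terms))
  if (!group %in% vars) stop("'", group, "' is not a variable of the model")
  if (!is.factor(data[[group]])) data[[group]] <- factor(data[[group]])
  fvars <- vars[vapply(vars, function(v) is.factor(data[[v]]) || is.character(data[[v]]),
                       logical(1))]
  nvars <- setdiff(vars, fvars)
  lev <- levels(droplevels(factor(data[[group]])))
  cnt <- table(factor(data[[group]], levels = lev))
  if (any(cnt == 0)) stop("group level(s) with no specimens: ",
                          paste(names(cnt)[cnt == 0], collapse = ", "))
  grid <- unique(data[, fvars, drop = FALSE])
  for (v in nvars) grid[[v]] <- mean(data[[v]])
  f <- stats::reformulate(fit$terms)
  Xg <- stats::model.matrix(f, data = grid)
  keep <- colnames(fit$full_design)
  Xg <- Xg[, keep, drop = FALSE]
  qr_full <- qr(fit$full_design)
  gidx <- split(seq_len(nrow(grid)), as.character(grid[[group]]))
  gidx <- gidx[lev]
  list(qr_full = qr_full, Xg = Xg, gidx = gidx, levels = lev)
}

ls_means_from_Y <- function(eng, Ystar) {
  beta <- qr.coef(eng$qr_full, Ystar)
  beta[is.na(beta)] <- 0
  pred <- eng$Xg %*% beta
  t(vapply(eng$gidx, function(ix) colMeans(pred[ix, , drop = FALSE]),
           numeric(ncol(Ystar))))
}

#' Post hoc pairwise group comparisons under RRPP
#'
#' Distances between least-squares group means (for shape data, the
#' Procrustes distance between covariate-adjusted group mean shapes), tested
#' by permuting the residuals of a null model fitted without the grouping
#' term(s) so that covariate effects are excluded from the test. For each
#' pair the observed distance d, the 95th percentile of the permuted
#' distances (UCL 95%), the effect size Z (identity scale) and the
#' permutation p-value are reported.
#'
#' @param fit_full `rrpp_fit` of the full model (null terms + group terms).
#' @param fit_null `rrpp_fit` of the null model (same Y, group terms absent).
#' @param group name of the grouping factor.
#' @param iter number of permutations (default 999).
#' @param seed integer seed.
#' @return An object of class `pairwise_result`: data.frame with columns
#'   `pair`, `d`, `UCL95`, `Z`, `p`, plus the LS means as an attribute.
#' @export
pairwise_groups <- function(fit_full, fit_null, group, iter = 999L, seed = NULL) {
  stopifnot(inherits(fit_full, "rrpp_fit"), inherits(fit_null, "rrpp_fit"))
  if (!isTRUE(all.equal(unname(fit_full$Y), unname(fit_null$Y))))
    stop("full and null models must share the same response matrix")
  if (!all(fit_null$terms %in% fit_full$terms))
    stop("null model terms must be a subset of the full model terms")
  eng <- ls_means_engine(fit_full, group)
  lev <- eng$levels
  if (length(lev) < 2L) stop("need at least two group levels")
  prs <- utils::combn(lev, 2L)
  pair_names <- paste(prs[1L, ], prs[2L, ], sep = ":")
  n <- fit_full$n
  fitted_null <- fit_null$H_full %*% fit_full$Y
  E_null <- fit_full$Y - fitted_null
  if (!is.null(seed)) set.seed(seed)
  dmat <- matrix(NA_real_, iter + 1L, ncol(prs), dimnames = list(NULL, pair_names))
  for (j in seq_len(iter + 1L)) {
    Ystar <- if (j == 1L) fit_full$Y else fitted_null + E_null[sample.int(n), , drop = FALSE]
    lsm <- ls_means_from_Y(eng, Ystar)
    dmat[j, ] <- apply(prs, 2L, function(pr)
      sqrt(sum((lsm[pr[1L], ] - lsm[pr[2L], ])^2)))
    if (j == 1L) lsm_obs <- lsm
  }
  d_obs <- dmat[1L, ]
  tol <- 1e-12 * pmax(1, abs(d_obs))
  res <- data.frame(
    pair = pair_names,
    d = d_obs,
    UCL95 = apply(dmat, 2L, stats::quantile, probs = 0.95, names = FALSE),
    Z = vapply(seq_along(d_obs), function(i)
      effect_size(d_obs[i], dmat[, i], "identity"), numeric(1)),
    p = vapply(seq_along(d_obs), function(i)
      mean(dmat[, i] >= d_obs[i] - tol[i]), numeric(1)),
    row.names = NULL
  )
  attr(res, "ls_means") <- lsm_obs
  attr(res, "n_permutations") <- iter
  class(res) <- c("pairwise_result", "data.frame")
  res
}

#' @export
print.pairwise_result <- function(x, digits = 5, ...) {
  cat(sprintf("Pairwise LS-mean distances (%d permutations)\n",
              attr(x, "n_permutations")))
  y <- as.data.frame(x)
  y$d <- signif(y$d, digits); y$UCL95 <- signif(y$UCL95, digits)
  y$Z <- round(y$Z, 4); y$p <- signif(y$p, 4)
  print(y)
  invisible(x)
}
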