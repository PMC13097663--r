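#' Allometric slope of a trait on body size
#'
#' Ordinary least-squares slope of log(Y) on log(SVL) (natural logs; the
#' slope is invariant to the log base). Estimated across all species and
#' sexes of the analysis subset for interspecific work, or within species for
#' intraspecific work.
#'
#' @param Y positive trait measurements.
#' @param SVL positive snout-vent lengths (mm), same length.
#' @return the slope b.
#' @export
fit_allometric_slope <- function(Y, SVL) {
  if (length(Y) != length(SVL)) stop("Y and SVL must have equal length")
  if (length(Y) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(Y)) || any(!is.finite(SVL)) || any(Y <= 0) || any(SVL <= 0))
    stop("Y and SVL must be positive and finite")
  lx <- log(SVL)
  if (stats::var(lx) == 0) stop("zero variance in SVL: slope undefined")
  unname(stats::coef(stats::lm(log(Y) ~ lx))[2L])
}

#' Fit the allometric model for a trait table
#'
#' Per-trait log-log slopes and the mean SVL of the analysis subset. With
#' `scope = "per_species"` the slopes and mean SVL are estimated within each
#' species separately (intraspecific analyses); with `"global"` across the
#' whole table (interspecific analyses).
#'
#' @param table a [trait_table]; incomplete rows are excluded.
#' @param scope `"global"` or `"per_species"`.
#' @param traits trait columns to model (default [trait_names()]).
#' @return An `allometric_model`: per-trait slopes, `mean_SVL`, `scope`.
#' @export
fit_allometric_model <- function(table, scope = c("global", "per_species"),
                                 traits = trait_names()) {
  scope <- match.arg(scope)
  tab <- table[table$complete, , drop = FALSE]
  if (!nrow(tab)) stop("no complete rows in trait table")
  if (scope == "global") {
    slopes <- vapply(traits, function(tr) fit_allometric_slope(tab[[tr]], tab$SVL),
                     numeric(1))
    mean_svl <- mean(tab$SVL)
  } else {
    sp <- levels(droplevels(tab$species))
    slopes <- sapply(sp, function(s) {
      sub <- tab[tab$species == s, , drop = FALSE]
      vapply(traits, function(tr) fit_allometric_slope(sub[[tr]], sub$SVL), numeric(1))
    })  # traits x species
    mean_svl <- vapply(sp, function(s) mean(tab$SVL[tab$species == s]), numeric(1))
  }
  structure(list(slopes = slopes, mean_SVL = mean_svl, scope = scope,
                 traits = traits),
            class = "allometric_model")
}

#' Size-correct a trait table
#'
#' Applies the allometric transformation Z_ij = Y_ij (mean_SVL / SVL_i)^b_j,
#' which scales every individual to the subset's mean body size and adjusts
#' trait values along the estimated allometric trajectory. With a
#' per-species model, each individual uses its species' slope and mean SVL.
#' SVL itself is excluded from the corrected variable set.
#'
#' @param table a [trait_table]; incomplete rows are excluded.
#' @param model an `allometric_model` from [fit_allometric_model()].
#' @return data.frame with the factor columns and size-corrected trait
#'   columns.
#' @export
size_correct <- function(table, model) {
  stopifnot(inherits(model, "allometric_model"))
  tab <- as.data.frame(table[table$complete, , drop = FALSE])
  traits <- model$traits
  out <- tab
  if (model$scope == "global") {
    for (tr in traits) {
      b <- model$slopes[[tr]]
      if (is.null(b) || is.na(b)) stop("no slope for trait '", tr, "'")
      out[[tr]] <- tab[[tr]] * (model$mean_SVL / tab$SVL)^b
    }
  } else {
    sp <- as.character(tab$species)
    missing_sp <- setdiff(unique(sp), colnames(model$slopes))
    if (length(missing_sp)) stop("no slopes for species: ",
                                 paste(missing_sp, collapse = ", "))
    for (tr in traits) {
      b <- model$slopes[tr, sp]
      msvl <- model$mean_SVL[sp]
      out[[tr]] <- tab[[tr]] * (msvl / tab$SVL)^b
    }
  }
  out
}

#' Standardize a corrected trait table into a response matrix
#'
#' Each column is centred and divided by its sample standard deviation
#' (n - 1 denominator).
#'
#' @param x data.frame or matrix of numeric trait columns (or a corrected
#'   table, from which [trait_names()] columns are taken).
#' @return n x p numeric matrix with zero column means and unit column sds.
#' @export
standardize_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- intersect(trait_names(), names(x))
    if (!length(cols)) cols <- names(x)[vapply(x, is.numeric, logical(1))]
    x <- as.matrix(x[, cols, drop = FALSE])
  }
  if (nrow(x) < 2L) stop("need at least 2 rows to standardize")
  sds <- apply(x, 2L, stats::sd)
  zero <- colnames(x)[sds == 0]
  if (length(zero)) stop("zero-variance column(s): ", paste(zero, collapse = ", "))
  scale(x, center = TRUE, scale = sds)[, , drop = FALSE]
}
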