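#' Analysis run configuration
#'
#' Bundles the preset model structure for one of the study-style analyses.
#' Presets encode the default term orders (covariates first, grouping
#' factors next, interactions last); `terms`, `null_terms` and `group` may
#' be overridden since sequential sums of squares depend on term order.
#'
#' * `"3d_species"`: shape ~ log_cs + sex + species + sex:species, pairwise
#'   on species against a null without the species terms.
#' * `"3d_region"`: shape ~ log_cs + sex + region (per-species subsets).
#' * `"2d_species"`: traits ~ sex + species + sex:species + island, global
#'   allometric slopes, pairwise on species.
#' * `"2d_region"`: traits ~ sex + region + region:island within one
#'   species, per-species allometric slopes, pairwise on region.
#' * `"2d_mahe"`: traits ~ sex + locality within one island, pairwise on
#'   locality.
#'
#' @param analysis preset tag.
#' @param iter permutations (default 9999; must be >= 99).
#' @param seed integer seed.
#' @param terms,null_terms,group optional overrides of the preset.
#' @param species_subset for intraspecific presets: the species to keep.
#' @param output_dir directory for the report bundle CSVs (`NULL`: not
#'   written).
#' @return list of class `run_config`.
#' @export
run_config <- function(analysis = c("3d_species", "3d_region", "2d_species",
                                    "2d_region", "2d_mahe"),
                       iter = 9999L, seed = 42L, terms = NULL,
                       null_terms = NULL, group = NULL,
                       species_subset = NULL, output_dir = NULL) {
  analysis <- match.arg(analysis)
  if (iter < 99L) stop("iter must be >= 99")
  preset <- switch(analysis,
    "3d_species" = list(terms = c("log_cs", "sex", "species", "sex:species"),
                        null_terms = c("log_cs", "sex"), group = "species"),
    "3d_region" = list(terms = c("log_cs", "sex", "region"),
                       null_terms = c("log_cs", "sex"), group = "region"),
    "2d_species" = list(terms = c("sex", "species", "sex:species", "island"),
                        null_terms = c("sex", "island"), group = "species"),
    "2d_region" = list(terms = c("sex", "region", "region:island"),
                       null_terms = c("sex"), group = "region"),
    "2d_mahe" = list(terms = c("sex", "locality"),
                     null_terms = c("sex"), group = "locality"))
  structure(list(analysis = analysis, iter = as.integer(iter), seed = as.integer(seed),
                 terms = terms %||% preset$terms,
                 null_terms = null_terms %||% preset$null_terms,
                 group = group %||% preset$group,
                 species_subset = species_subset, output_dir = output_dir),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from a YAML file
#'
#' The file holds the fields of [run_config()] (`analysis`, `iter`, `seed`,
#' `terms`, `null_terms`, `group`, `species_subset`, `output_dir`); absent
#' fields fall back to the preset defaults.
#'
#' @param path YAML file path.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("analysis", "iter", "seed", "terms", "null_terms", "group",
             "species_subset", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(run_config, cfg)
}

#' Format a permutation p-value for reporting
#'
#' Values below ten times the attainable minimum 1/(iter + 1) are printed as
#' an upper bound (e.g. "< 0.001" at 9999 permutations); raw values are kept
#' in all CSV output.
#'
#' @param p p-value(s).
#' @param iter number of permutations behind them.
#' @return character vector.
#' @export
format_p <- function(p, iter) {
  cut <- 10 / (iter + 1)
  ifelse(p < cut, paste0("< ", format(cut, scientific = FALSE)),
         trimws(formatC(p, digits = 4, format = "g")))
}

stage_log <- function(log, stage, msg) {
  c(log, sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg))
}

#' Run the 3D landmark shape analysis
#'
#' The full 3D pipeline: within-species estimation of missing landmarks,
#' generalized Procrustes analysis, bilateral-symmetry decomposition,
#' permutational multivariate ANOVA (RRPP) on the symmetric shape component
#' with log centroid size and sex as covariates, post hoc pairwise
#' LS-mean shape distances against a null model without the grouping term,
#' and PCA of the symmetric shapes with extreme-shape reconstruction along
#' PC1 and PC2.
#'
#' @param dataset a [landmark_dataset].
#' @param config a [run_config] with a `3d_*` analysis tag.
#' @return list of class `report_bundle`: `anova` (data.frame), `pairwise`,
#'   `pca_variance`, `pca_scores`, `pc_extremes`, `mean_shape`, `fits`,
#'   `specimen_log`, `log`. Written as CSVs under `config$output_dir` when
#'   set.
#' @export
run_3d_analysis <- function(dataset, config = run_config("3d_species")) {
  stopifnot(inherits(dataset, "landmark_dataset"), inherits(config, "run_config"))
  log <- character()
  n0 <- n_specimens(dataset)
  if (!is.null(config$species_subset)) {
    keep <- dataset$metadata$species %in% config$species_subset
    dataset <- assemble_dataset(dataset$configurations[keep],
                                dataset$metadata[keep, , drop = FALSE],
                                dataset$pairing, template = dataset$labels)
    log <- stage_log(log, "subset",
                     sprintf("kept %d of %d specimens (species %s)",
                             sum(keep), n0, paste(config$species_subset, collapse = "+")))
  }
  miss <- sum(dataset$missing_report$n_missing)
  est <- tryCatch(estimate_missing(dataset, group_by = "species"),
                  error = function(e) stop("stage estimate_missing failed: ",
                                           conditionMessage(e)))
  log <- stage_log(log, "estimate_missing",
                   sprintf("%d missing landmarks estimated across %d specimens",
                           miss, nrow(attr(est, "estimation_log"))))
  fit_gpa <- gpa(est)
  log <- stage_log(log, "gpa", sprintf("%d specimens aligned in %d iterations",
                                       n_specimens(est), fit_gpa$n_iterations))
  sym <- symmetry_decomposition(est)
  log <- stage_log(log, "symmetry", "symmetric component extracted")
  Y <- flatten_shapes(sym$symmetric)
  data <- est$metadata
  data$log_cs <- unname(sym$log_cs)
  fit_full <- fit_rrpp(Y, config$terms, data, iter = config$iter, seed = config$seed)
  fit_null <- fit_rrpp(Y, config$null_terms, data, iter = config$iter,
                       seed = config$seed)
  log <- stage_log(log, "rrpp", sprintf("model %s fitted with %d permutations",
                                        paste(config$terms, collapse = " + "),
                                        config$iter))
  pw <- NULL
  if (config$group %in% unlist(lapply(config$terms, function(t)
    all.vars(stats::reformulate(t))))) {
    pw <- pairwise_groups(fit_full, fit_null, config$group,
                          iter = config$iter, seed = config$seed)
    log <- stage_log(log, "pairwise", sprintf("%d group pairs compared", nrow(pw)))
  }
  pc <- pca(Y)
  mean_shape <- apply(sym$symmetric, c(1, 2), mean)
  extremes <- list(
    PC1_min = pc_extreme_shape(pc, mean_shape, 1L, min(pc$scores[, 1])),
    PC1_max = pc_extreme_shape(pc, mean_shape, 1L, max(pc$scores[, 1])),
    PC2_min = if (ncol(pc$scores) >= 2L)
      pc_extreme_shape(pc, mean_shape, 2L, min(pc$scores[, 2])),
    PC2_max = if (ncol(pc$scores) >= 2L)
      pc_extreme_shape(pc, mean_shape, 2L, max(pc$scores[, 2])))
  log <- stage_log(log, "pca", sprintf("PC1 %.1f%%, PC2 %.1f%% of variance",
                                       100 * pc$variance_fraction[1],
                                       100 * if (length(pc$variance_fraction) > 1)
                                         pc$variance_fraction[2] else 0))
  report <- structure(
    list(analysis = config$analysis,
         anova = anova_table(fit_full), pairwise = pw,
         pca_variance = data.frame(PC = seq_along(pc$eigenvalues),
                                   eigenvalue = pc$eigenvalues,
                                   variance_fraction = pc$variance_fraction),
         pca_scores = data.frame(specimen_id = rownames(Y), pc$scores[, seq_len(min(5L, ncol(pc$scores))), drop = FALSE],
                                 data[, intersect(c("species", "region", "sex"), names(data))]),
         pc_extremes = extremes, mean_shape = mean_shape,
         fits = list(full = fit_full, null = fit_null),
         symmetry = sym, pca = pc,
         specimen_log = data.frame(specimen_id = names(est$configurations),
                                   status = "used", reason = ""),
         log = log),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(report, config$output_dir, config)
  report
}

#' Run the 2D trait analysis
#'
#' The full 2D pipeline: incomplete rows dropped, per-trait allometric
#' slopes fitted (globally or within species per the preset), the
#' size-correction Z = Y (mean_SVL / SVL)^b applied, corrected variables
#' standardized into the response matrix, the RRPP model fitted, pairwise
#' LS-mean distances computed against the null without the grouping term,
#' and PCA of the standardized matrix (both loading conventions available in
#' the `pca` element).
#'
#' @param table a `trait_table`.
#' @param config a [run_config] with a `2d_*` analysis tag.
#' @return A `report_bundle`, as in [run_3d_analysis()].
#' @export
run_2d_analysis <- function(table, config = run_config("2d_species")) {
  stopifnot(inherits(table, "trait_table"), inherits(config, "run_config"))
  log <- character()
  spec_log <- data.frame(specimen_id = table$specimen_id,
                         status = "used", reason = "", stringsAsFactors = FALSE)
  spec_log$status[!table$complete] <- "excluded"
  spec_log$reason[!table$complete] <- "missing measurement"
  if (!is.null(config$species_subset)) {
    drop <- !(table$species %in% config$species_subset)
    spec_log$status[drop & spec_log$status == "used"] <- "excluded"
    spec_log$reason[drop & spec_log$reason == ""] <- "outside species subset"
    table <- trait_table(table[!drop, , drop = FALSE])
  }
  tab <- table[table$complete, , drop = FALSE]
  log <- stage_log(log, "filter", sprintf("%d complete specimens retained, %d excluded",
                                          nrow(tab), sum(spec_log$status == "excluded")))
  scope <- if (config$analysis == "2d_species") "global" else "per_species"
  model <- fit_allometric_model(table, scope = scope)
  corrected <- size_correct(table, model)
  X <- standardize_matrix(corrected)
  log <- stage_log(log, "allometry", sprintf("size correction with %s slopes (mean SVL %s mm)",
                                             scope, paste(round(model$mean_SVL, 1),
                                                          collapse = "/")))
  data <- droplevels(corrected[, setdiff(names(corrected), trait_names()), drop = FALSE])
  fit_full <- fit_rrpp(X, config$terms, data, iter = config$iter, seed = config$seed)
  fit_null <- fit_rrpp(X, config$null_terms, data, iter = config$iter,
                       seed = config$seed)
  log <- stage_log(log, "rrpp", sprintf("model %s fitted with %d permutations",
                                        paste(config$terms, collapse = " + "),
                                        config$iter))
  pw <- pairwise_groups(fit_full, fit_null, config$group,
                        iter = config$iter, seed = config$seed)
  log <- stage_log(log, "pairwise", sprintf("%d group pairs compared", nrow(pw)))
  pc <- pca(X)
  log <- stage_log(log, "pca", sprintf("PC1 %.1f%%, PC2 %.1f%% of variance",
                                       100 * pc$variance_fraction[1],
                                       100 * if (length(pc$variance_fraction) > 1)
                                         pc$variance_fraction[2] else 0))
  report <- structure(
    list(analysis = config$analysis,
         anova = anova_table(fit_full), pairwise = pw,
         pca_variance = data.frame(PC = seq_along(pc$eigenvalues),
                                   eigenvalue = pc$eigenvalues,
                                   variance_fraction = pc$variance_fraction),
         pca_scores = data.frame(specimen_id = corrected$specimen_id,
                                 pc$scores[, seq_len(min(5L, ncol(pc$scores))), drop = FALSE],
                                 data[, intersect(c("species", "region", "island", "sex"),
                                                  names(data))]),
         loadings = pc$loadings, eigenvector_loadings = pc$eigenvectors,
         allometric_model = model, corrected = corrected,
         fits = list(full = fit_full, null = fit_null), pca = pc,
         specimen_log = spec_log, log = log),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(report, config$output_dir, config)
  report
}

#' Write a report bundle to CSV files
#'
#' Writes `anova.csv`, `pairwise.csv` (with a formatted p column alongside
#' the raw values), `pca_scores.csv`, `pca_variance.csv` and `run.log`
#' under `dir`.
#'
#' @param report a `report_bundle`.
#' @param dir output directory (created if absent).
#' @param config the [run_config] used (for p-value formatting).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iter <- if (!is.null(config)) config$iter else 999L
  anova <- cbind(term = rownames(report$anova), report$anova)
  utils::write.csv(anova, file.path(dir, "anova.csv"), row.names = FALSE)
  if (!is.null(report$pairwise)) {
    pw <- as.data.frame(report$pairwise)
    pw$p_formatted <- format_p(pw$p, iter)
    utils::write.csv(pw, file.path(dir, "pairwise.csv"), row.names = FALSE)
  }
  utils::write.csv(report$pca_scores, file.path(dir, "pca_scores.csv"), row.names = FALSE)
  utils::write.csv(report$pca_variance, file.path(dir, "pca_variance.csv"),
                   row.names = FALSE)
  writeLines(c(report$log,
               sprintf("[specimens] %d used, %d excluded",
                       sum(report$specimen_log$status == "used"),
                       sum(report$specimen_log$status == "excluded"))),
             file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> analysis '%s'\n", x$analysis))
  cat("\nANOVA (full model):\n")
  print(round(x$anova, 5))
  if (!is.null(x$pairwise)) {
    cat("\nPairwise comparisons:\n")
    print(x$pairwise)
  }
  cat(sprintf("\nPC1 + PC2 variance: %.1f%%\n",
              100 * sum(x$pca_variance$variance_fraction[1:min(2, nrow(x$pca_variance))])))
  invisible(x)
}
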