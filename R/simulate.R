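random_rotation <- function(D) {
  Q <- qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Random mirror-symmetric tangent vector on a bilateral template: the left
# block and in-plane midline components are drawn freely, the right block is
# the mirrored left block, the midline out-of-plane (x) components are zero.
random_symmetric_vector <- function(k_pairs, k_midline, D, magnitude = 1,
                                    per_coord_sd = NULL) {
  sd0 <- if (is.null(per_coord_sd)) 1 else per_coord_sd
  left <- matrix(stats::rnorm(k_pairs * D, sd = sd0), k_pairs, D)
  mid <- matrix(stats::rnorm(k_midline * D, sd = sd0), k_midline, D)
  mid[, 1] <- 0
  right <- left
  right[, 1] <- -right[, 1]
  v <- rbind(left, right, mid)
  if (is.null(per_coord_sd)) {
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v * (magnitude / nv)
  }
  v
}

#' Parameters for the landmark-dataset simulator
#'
#' Defaults emulate the 3D skull dataset of the motivating study design:
#' a cranium-sized template of 54 bilateral landmark pairs plus 12 midline
#' landmarks (120 landmarks), three groups of 17, 16 and 9 specimens, group
#' mean-shape offsets sized to give pairwise Procrustes distances of the
#' order of 0.07-0.12, log-size allometry, a small sexual shape dimorphism,
#' fluctuating asymmetry, and digitisation noise, with landmarks missing
#' completely at random at a rate matching the study's 14-of-5040 missing
#' cranial coordinates.
#'
#' @param k_pairs number of bilateral landmark pairs (default 54).
#' @param k_midline number of midline landmarks (default 12).
#' @param groups list of `list(name, n, effect)`; `effect` is either a
#'   Procrustes-scale magnitude or a k x D tangent matrix.
#' @param allometry magnitude of the shape change per unit log centroid size
#'   (default 0.05).
#' @param size_meanlog,size_sdlog lognormal centroid-size distribution
#'   (default meanlog log(30) mm, sdlog 0.15).
#' @param sex_effect magnitude of the (symmetric) sexual dimorphism vector
#'   (default 0.02).
#' @param asymmetry_sd per-coordinate sd of fluctuating asymmetry (default
#'   0.001, i.e. 0.1% of unit centroid size).
#' @param noise_sd per-coordinate sd of symmetric digitisation noise
#'   (default 0.002).
#' @param directional_asymmetry optional k x D vector added to every
#'   specimen after the symmetric part (default none).
#' @param missing_rate probability a landmark is unobserved (default 0.003);
#'   never applied to more than 20% of a specimen's landmarks.
#' @param D dimensionality (default 3).
#' @param seed integer seed; every draw is reproducible from it.
#' @return list of class `landmark_sim_params`.
#' @export
landmark_sim_params <- function(k_pairs = 54L, k_midline = 12L,
                                groups = list(list(name = "A", n = 17L, effect = 0),
                                              list(name = "B", n = 16L, effect = 0.066),
                                              list(name = "C", n = 9L, effect = 0.107)),
                                allometry = 0.05,
                                size_meanlog = log(30), size_sdlog = 0.15,
                                sex_effect = 0.02,
                                asymmetry_sd = 0.001, noise_sd = 0.002,
                                directional_asymmetry = NULL,
                                missing_rate = 0.003, D = 3L, seed = 1L) {
  stopifnot(k_pairs >= 1L, k_midline >= 0L, D %in% c(2L, 3L),
            asymmetry_sd >= 0, noise_sd >= 0, missing_rate >= 0, missing_rate < 1)
  for (g in groups) stopifnot(g$n >= 1L)
  structure(as.list(environment()), class = "landmark_sim_params")
}

#' Simulate a bilateral landmark dataset with known ground truth
#'
#' Builds a mirror-symmetric template of `2 * k_pairs + k_midline` landmarks,
#' then for each specimen draws a size, adds group / sex / allometric
#' tangent-space offsets (all mirror-symmetric, applied to the unit-size
#' template so shape effects are size-free by construction), symmetric
#' digitisation noise and independent asymmetric noise, and finally applies a
#' random rotation, translation and scaling. Landmarks are masked completely
#' at random at `missing_rate` (at most 20% per specimen; at least one
#' complete specimen is kept per group).
#'
#' @param params a [landmark_sim_params].
#' @return list with `dataset` (a [landmark_dataset]) and `truth` (template,
#'   effect vectors, sizes, and pairwise Procrustes distances between the
#'   true group mean shapes).
#' @export
simulate_landmarks <- function(params = landmark_sim_params()) {
  stopifnot(inherits(params, "landmark_sim_params"))
  set.seed(params$seed)
  kp <- params$k_pairs; km <- params$k_midline; D <- params$D
  k <- 2L * kp + km
  # template: left block in x < 0, mirrored right block, midline at x = 0
  left <- cbind(-stats::runif(kp, 0.15, 1.1),
                matrix(stats::runif(kp * (D - 1L), -1, 1), kp, D - 1L))
  right <- left; right[, 1] <- -right[, 1]
  mid <- cbind(0, matrix(stats::runif(km * (D - 1L), -1, 1), km, D - 1L))
  template <- rbind(left, right, mid)
  template <- center_config(template)
  template[, 1] <- template[, 1] - mean(template[, 1]) # keep plane at x = 0
  cs0 <- centroid_size(template)
  if (!is.finite(cs0) || cs0 <= 0) stop("degenerate template")
  template <- template / cs0
  labels <- c(paste0("L", seq_len(kp)), paste0("R", seq_len(kp)),
              if (km) paste0("M", seq_len(km)))
  rownames(template) <- labels
  pairing <- pairing_map(cbind(paste0("L", seq_len(kp)), paste0("R", seq_len(kp))),
                         if (km) paste0("M", seq_len(km)) else character())
  grp_vec <- lapply(params$groups, function(g) {
    if (is.matrix(g$effect)) g$effect
    else random_symmetric_vector(kp, km, D, magnitude = g$effect)
  })
  sex_vec <- random_symmetric_vector(kp, km, D, magnitude = params$sex_effect)
  allo_vec <- random_symmetric_vector(kp, km, D, magnitude = params$allometry)
  norm_shape <- function(x) { x <- center_config(x); x / centroid_size(x) }
  group_means <- lapply(grp_vec, function(v) norm_shape(template + v))
  ng <- length(params$groups)
  truth_d <- matrix(0, ng, ng,
                    dimnames = rep(list(vapply(params$groups, `[[`, "", "name")), 2))
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    if (i < j) {
      R <- optimal_rotation(group_means[[j]], group_means[[i]])
      truth_d[i, j] <- truth_d[j, i] <-
        procrustes_distance(group_means[[j]] %*% R, group_means[[i]])
    }
  }
  configs <- list()
  meta <- list()
  sizes <- numeric(0)
  idx <- 0L
  for (gi in seq_along(params$groups)) {
    g <- params$groups[[gi]]
    for (j in seq_len(g$n)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", g$name, j)
      sex <- if (j %% 2L == 1L) "M" else "F"
      s <- stats::rlnorm(1, params$size_meanlog, params$size_sdlog)
      shape <- template + grp_vec[[gi]] +
        (sex == "M") * sex_vec +
        allo_vec * (log(s) - params$size_meanlog) +
        random_symmetric_vector(kp, km, D, per_coord_sd = params$noise_sd) +
        matrix(stats::rnorm(k * D, sd = params$asymmetry_sd), k, D)
      if (!is.null(params$directional_asymmetry))
        shape <- shape + params$directional_asymmetry
      R <- random_rotation(D)
      tr <- stats::runif(D, -10, 10)
      coords <- sweep(s * shape %*% R, 2, tr, `+`)
      miss <- stats::runif(k) < params$missing_rate
      cap <- floor(0.2 * k)
      if (sum(miss) > cap) miss[sample(which(miss), sum(miss) - cap)] <- FALSE
      if (k - sum(miss) < D + 2L) miss[] <- FALSE
      coords[miss, ] <- NA_real_
      configs[[idx]] <- landmark_config(coords, labels = labels,
                                        specimen_id = id, missing = miss)
      region <- if (j <= ceiling(g$n / 2)) "northern" else "southern"
      meta[[idx]] <- data.frame(
        specimen_id = id, species = g$name, sex = sex, region = region,
        island = sprintf("%s_%s_is%d", g$name, substr(region, 1, 1), 1L + j %% 2L),
        replicate_of = NA_character_, stringsAsFactors = FALSE)
      sizes[idx] <- s
    }
  }
  metadata <- do.call(rbind, meta)
  # keep at least one complete specimen per group (reference requirement)
  for (g in unique(metadata$species)) {
    gi <- which(metadata$species == g)
    if (all(vapply(configs[gi], function(cf) any(cf$missing), logical(1)))) {
      cf <- configs[[gi[1]]]
      full <- cf$coords
      full[cf$missing, ] <- 0
      configs[[gi[1]]] <- landmark_config(full, labels = cf$labels,
                                          specimen_id = cf$specimen_id,
                                          missing = rep(FALSE, nrow(full)))
    }
  }
  dataset <- assemble_dataset(configs, metadata, pairing, template = labels)
  list(dataset = dataset,
       truth = list(template = template, group_vectors = grp_vec,
                    group_means = group_means, pairwise_d = truth_d,
                    sex_vector = sex_vec, allometry_vector = allo_vec,
                    sizes = sizes, params = params))
}

#' Parameters for the trait-table simulator
#'
#' Defaults emulate the 2D external-morphometrics design: three species with
#' 246, 206 and 115 complete specimens, per-trait log-log allometry
#' log(Y) = log(a) + b log(SVL) + effects + noise with realistic gecko trait
#' proportions and slopes, species and sex effects on the log scale, a
#' lognormal SVL distribution per species, and an island-within-region
#' structure whose effect sizes are tunable (zero by default).
#'
#' @param groups list of `list(name, n, svl_meanlog)`.
#' @param slopes named per-trait allometric slopes b_j.
#' @param intercepts named per-trait log(a_j); defaults place typical trait
#'   sizes at SVL = 60 mm.
#' @param species_effect_sd sd of the per-species log-scale trait shifts
#'   (default 0.08).
#' @param sex_effect_sd sd of the log-scale sexual dimorphism (default 0.02).
#' @param region_effect_sd,island_effect_sd sds of log-scale regional and
#'   island-within-region shifts (defaults 0: no geographic structure).
#' @param n_islands_per_region islands per region (default 3).
#' @param svl_sdlog lognormal sdlog of SVL (default 0.08).
#' @param noise_sd residual sd on the log scale (default 0.05).
#' @param missing_rate probability a measurement cell is missing (default 0).
#' @param seed integer seed.
#' @return list of class `trait_sim_params`.
#' @export
trait_sim_params <- function(groups = list(list(name = "A", n = 246L, svl_meanlog = log(62)),
                                           list(name = "B", n = 206L, svl_meanlog = log(54)),
                                           list(name = "C", n = 115L, svl_meanlog = log(95))),
                             slopes = c(ED = 0.7, EED = 0.9, FTL = 1.0, HH = 1.1,
                                        HL = 0.95, HW = 1.05, IND = 0.8, IOD = 0.9,
                                        SED = 0.95, Weight = 2.9),
                             intercepts = NULL,
                             species_effect_sd = 0.08, sex_effect_sd = 0.02,
                             region_effect_sd = 0, island_effect_sd = 0,
                             n_islands_per_region = 3L,
                             svl_sdlog = 0.08, noise_sd = 0.05,
                             missing_rate = 0, seed = 1L) {
  traits <- trait_names()
  stopifnot(all(traits %in% names(slopes)))
  if (is.null(intercepts)) {
    typical <- c(ED = 3.5, EED = 5, FTL = 7, HH = 6, HL = 16, HW = 11,
                 IND = 2.5, IOD = 6, SED = 6.5, Weight = 10)
    intercepts <- log(typical[traits]) - slopes[traits] * log(60)
  }
  stopifnot(all(traits %in% names(intercepts)), noise_sd >= 0)
  structure(as.list(environment()), class = "trait_sim_params")
}

#' Simulate a morphometric trait table with known ground truth
#'
#' Draws per-specimen SVL from the species' lognormal size distribution and
#' generates each trait as log Y = log a + b log SVL + species + sex +
#' region + island + N(0, noise_sd^2), exponentiated back to measurement
#' units. Specimens are spread over regions (northern/southern) and islands
#' nested in regions.
#'
#' @param params a [trait_sim_params].
#' @return list with `table` (a `trait_table`) and `truth` (all generating
#'   effect vectors).
#' @export
simulate_traits <- function(params = trait_sim_params()) {
  stopifnot(inherits(params, "trait_sim_params"))
  set.seed(params$seed)
  traits <- params$traits
  nt <- length(traits)
  sp_eff <- lapply(params$groups, function(g)
    stats::rnorm(nt, sd = params$species_effect_sd))
  sex_eff <- stats::rnorm(nt, sd = params$sex_effect_sd)
  regions <- c("northern", "southern")
  reg_eff <- lapply(regions, function(r) stats::rnorm(nt, sd = params$region_effect_sd))
  names(reg_eff) <- regions
  islands <- unlist(lapply(regions, function(r)
    paste0(r, "_is", seq_len(params$n_islands_per_region))))
  isl_eff <- lapply(islands, function(i) stats::rnorm(nt, sd = params$island_effect_sd))
  names(isl_eff) <- islands
  # island effects are centred within each region, so island-level structure
  # never leaks into the regional means: a zero region effect stays zero
  for (r in regions) {
    ri <- grep(paste0("^", r, "_"), islands, value = TRUE)
    ctr <- Reduce(`+`, isl_eff[ri]) / length(ri)
    for (i in ri) isl_eff[[i]] <- isl_eff[[i]] - ctr
  }
  rows <- list()
  ridx <- 0L
  for (gi in seq_along(params$groups)) {
    g <- params$groups[[gi]]
    for (j in seq_len(g$n)) {
      ridx <- ridx + 1L
      sex <- if ((j %/% 2L) %% 2L == 0L) "M" else "F" # crossed with region
      region <- regions[1L + (j %% 2L == 0L)]
      island <- paste0(region, "_is", 1L + (j %% params$n_islands_per_region))
      svl <- stats::rlnorm(1, g$svl_meanlog, params$svl_sdlog)
      logy <- params$intercepts[traits] + params$slopes[traits] * log(svl) +
        sp_eff[[gi]] + (sex == "M") * sex_eff +
        reg_eff[[region]] + isl_eff[[island]] +
        stats::rnorm(nt, sd = params$noise_sd)
      y <- exp(logy)
      if (params$missing_rate > 0)
        y[stats::runif(nt) < params$missing_rate] <- NA_real_
      rows[[ridx]] <- data.frame(
        specimen_id = sprintf("%s_%03d", g$name, j), species = g$name,
        region = region, island = island, sex = sex, SVL = svl,
        t(y), stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  tab <- trait_table(do.call(rbind, rows))
  list(table = tab,
       truth = list(species_effects = sp_eff, sex_effect = sex_eff,
                    region_effects = reg_eff, island_effects = isl_eff,
                    slopes = params$slopes, intercepts = params$intercepts,
                    params = params))
}

#' Parameters for the CT phantom simulator
#'
#' A two-material phantom: bone-intensity geometric objects (ellipsoids,
#' tubes) in a uniform background, with additive Gaussian gray-value noise.
#' Defaults follow the two-material test conditions used throughout the
#' segmentation checks: means 180 (bone) and 60 (background), noise sd 10.
#'
#' @param shape grid dimensions (default 64^3).
#' @param objects list of `list(type = "ellipsoid", center, radii)` or
#'   `list(type = "tube", p0, p1, radius)` in voxel coordinates; default one
#'   centred ellipsoid plus one tube.
#' @param mean_bone,mean_background object and background intensities
#'   (defaults 180 and 60).
#' @param noise_sd Gaussian noise sd (default 10).
#' @param seed integer seed.
#' @return list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(64L, 64L, 64L), objects = NULL,
                           mean_bone = 180, mean_background = 60,
                           noise_sd = 10, seed = 1L) {
  if (!(mean_bone > mean_background))
    stop("mean_bone must exceed mean_background")
  if (is.null(objects))
    objects <- list(
      list(type = "ellipsoid", center = shape / 2, radii = shape * 0.28),
      list(type = "tube", p0 = c(shape[1] * 0.2, shape[2] * 0.75, shape[3] * 0.2),
           p1 = c(shape[1] * 0.85, shape[2] * 0.8, shape[3] * 0.85),
           radius = min(shape) * 0.06))
  structure(list(shape = as.integer(shape), objects = objects,
                 mean_bone = mean_bone, mean_background = mean_background,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_params")
}

#' Simulate a two-material CT phantom with ground truth
#'
#' @param params a [phantom_params].
#' @return list with `volume` (a [grey_volume]) and `truth` (a
#'   [binary_volume] mask of the noise-free geometry).
#' @export
simulate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  set.seed(params$seed)
  d <- params$shape
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  truth <- array(FALSE, d)
  for (ob in params$objects) {
    if (ob$type == "ellipsoid") {
      if (any(ob$center - ob$radii < 0.5) || any(ob$center + ob$radii > d + 0.5))
        stop("ellipsoid exceeds the grid")
      ex <- ((xs - ob$center[1]) / ob$radii[1])^2
      ey <- ((ys - ob$center[2]) / ob$radii[2])^2
      ez <- ((zs - ob$center[3]) / ob$radii[3])^2
      truth <- truth | (outer(outer(ex, ey, `+`), ez, `+`) <= 1)
    } else if (ob$type == "tube") {
      if (any(pmin(ob$p0, ob$p1) - ob$radius < 0.5) ||
          any(pmax(ob$p0, ob$p1) + ob$radius > d + 0.5))
        stop("tube exceeds the grid")
      grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
      v <- ob$p1 - ob$p0
      L2 <- sum(v^2)
      w <- sweep(grid, 2, ob$p0)
      t0 <- pmin(pmax((w %*% v) / L2, 0), 1)
      closest <- outer(as.vector(t0), v) + rep(ob$p0, each = nrow(grid))
      dist2 <- rowSums((grid - closest)^2)
      truth <- truth | array(dist2 <= ob$radius^2, d)
    } else stop("unknown object type: ", ob$type)
  }
  vox <- ifelse(truth, params$mean_bone, params$mean_background) +
    array(stats::rnorm(prod(d), sd = params$noise_sd), d)
  list(volume = grey_volume(vox), truth = binary_volume(truth))
}
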