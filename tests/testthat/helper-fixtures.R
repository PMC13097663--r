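# Shared fixture builders. All randomness is local to the calling test and
# controlled by explicit seeds.

rand_rotation <- function(D) {
  Q <- qr.Q(qr(matrix(rnorm(D * D), D, D)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# A small labelled k x D x n array of one shape under random similarity
# transforms (same shape, different pose/scale).
same_shape_array <- function(k = 8, D = 3, n = 5, seed = 1) {
  set.seed(seed)
  tmpl <- matrix(rnorm(k * D), k, D)
  arr <- array(NA_real_, c(k, D, n),
               dimnames = list(paste0("LM", seq_len(k)),
                               c("x", "y", "z")[seq_len(D)], paste0("s", seq_len(n))))
  for (i in seq_len(n))
    arr[, , i] <- sweep(tmpl %*% rand_rotation(D) * runif(1, 0.5, 2), 2,
                        runif(D, -5, 5), `+`)
  arr
}

# Tiny mirror-symmetric configuration: 2 bilateral pairs + 1 midline point.
toy_symmetric_config <- function() {
  coords <- rbind(
    L1 = c(-1, 0.5, 0), L2 = c(-0.8, -1, 0.3),
    R1 = c(1, 0.5, 0), R2 = c(0.8, -1, 0.3),
    M1 = c(0, 1.2, -0.4))
  list(coords = coords,
       pairing = pairing_map(cbind(c("L1", "L2"), c("R1", "R2")), "M1"))
}

# Small simulated bilateral dataset (fast defaults for unit tests).
small_landmark_sim <- function(seed = 1, n = 8, effect = 0.1, k_pairs = 8,
                               k_midline = 4, missing_rate = 0, ...) {
  simulate_landmarks(landmark_sim_params(
    k_pairs = k_pairs, k_midline = k_midline,
    groups = list(list(name = "A", n = n, effect = 0),
                  list(name = "B", n = n, effect = effect)),
    missing_rate = missing_rate, seed = seed, ...))
}

# Write a minimal Slicer markups JSON fixture.
write_mrk_json <- function(path, positions, labels = NULL) {
  if (is.null(labels)) labels <- paste0("F_", seq_along(positions))
  cps <- lapply(seq_along(positions), function(i)
    list(id = as.character(i), label = labels[i],
         position = positions[[i]], positionStatus = "defined"))
  jsonlite::write_json(
    list(`@schema` = "https://raw.githubusercontent.com/slicer/slicer/master/Modules/Loadable/Markups/Resources/Schema/markups-schema-v1.0.3.json",
         markups = list(list(type = "Fiducial", coordinateSystem = "LPS",
                             controlPoints = cps))),
    path, auto_unbox = TRUE, digits = NA)
  path
}
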