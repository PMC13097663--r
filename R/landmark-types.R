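#' Landmark configuration
#'
#' A single specimen's labelled landmark coordinates in 2 or 3 dimensions.
#' Missing (undigitised) landmarks are encoded by the logical `missing` mask;
#' their coordinate rows are `NA` and must never enter arithmetic. Coordinates
#' are assumed to be in millimetres in a right-handed axis system.
#'
#' @param coords numeric k x D matrix (D = 2 or 3), one row per landmark.
#' @param labels character vector of k unique landmark names. Defaults to the
#'   rownames of `coords`, or `LM1..LMk`.
#' @param specimen_id specimen identifier.
#' @param missing logical vector of length k; `TRUE` marks a landmark whose
#'   position is unknown. Rows flagged missing are set to `NA`.
#'
#' @return An object of class `landmark_config` with fields `specimen_id`,
#'   `coords`, `labels`, `missing`.
#' @export
landmark_config <- function(coords, labels = NULL, specimen_id = "specimen",
                            missing = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  k <- nrow(coords)
  D <- ncol(coords)
  if (k < 3L) stop("a landmark configuration needs at least 3 landmarks, got ", k)
  if (!D %in% c(2L, 3L)) stop("coordinates must be 2D or 3D, got D = ", D)
  if (is.null(labels)) {
    labels <- rownames(coords)
    if (is.null(labels)) labels <- paste0("LM", seq_len(k))
  }
  labels <- as.character(labels)
  if (length(labels) != k) stop("length(labels) != number of landmarks")
  dup <- labels[duplicated(labels)]
  if (length(dup)) stop("duplicate landmark labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(missing)) missing <- rowSums(is.na(coords)) > 0
  missing <- as.logical(missing)
  if (length(missing) != k) stop("length(missing) != number of landmarks")
  coords[missing, ] <- NA_real_
  if (any(is.na(coords[!missing, , drop = FALSE])))
    stop("NA coordinates present in landmarks not flagged as missing")
  rownames(coords) <- labels
  structure(
    list(specimen_id = as.character(specimen_id), coords = coords,
         labels = labels, missing = missing),
    class = "landmark_config"
  )
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("<landmark_config> %s: %d landmarks, %dD, %d missing\n",
              x$specimen_id, nrow(x$coords), ncol(x$coords), sum(x$missing)))
  invisible(x)
}

#' Bilateral pairing map
#'
#' Describes the object-symmetry structure of a landmark template: which
#' labels form (left, right) mirror pairs and which lie on the mid-sagittal
#' plane. Every label must appear exactly once.
#'
#' @param pairs two-column character matrix (or data.frame) of
#'   (left, right) label pairs; may have zero rows.
#' @param midline character vector of midline landmark labels.
#' @return An object of class `pairing_map`.
#' @export
pairing_map <- function(pairs, midline = character()) {
  pairs <- as.matrix(pairs)
  if (length(pairs) && ncol(pairs) != 2L)
    stop("'pairs' must have two columns (left, right)")
  if (!length(pairs)) pairs <- matrix(character(), ncol = 2)
  mode(pairs) <- "character"
  colnames(pairs) <- c("left", "right")
  midline <- as.character(midline)
  all_lab <- c(pairs[, 1], pairs[, 2], midline)
  dup <- all_lab[duplicated(all_lab)]
  if (length(dup))
    stop("labels appear more than once in pairing: ", paste(unique(dup), collapse = ", "))
  structure(list(pairs = pairs, midline = midline), class = "pairing_map")
}

#' @export
print.pairing_map <- function(x, ...) {
  cat(sprintf("<pairing_map> %d bilateral pairs + %d midline landmarks\n",
              nrow(x$pairs), length(x$midline)))
  invisible(x)
}

pairing_labels <- function(pairing) c(pairing$pairs[, 1], pairing$pairs[, 2], pairing$midline)

#' Assemble a validated landmark dataset
#'
#' Combines per-specimen configurations, a metadata table and a pairing map
#' into a validated dataset. Configurations are reordered to a common label
#' template (homology by label, not by digitisation order); file order is not
#' trusted. No specimen is silently dropped: every input configuration is
#' either in the output or raises an error.
#'
#' @param configs list of [landmark_config] objects sharing one label set.
#' @param metadata data.frame with at least `specimen_id`; typically also
#'   `species`, `region`, `island`, `sex`, `replicate_of`.
#' @param pairing a [pairing_map] covering all labels, or `NULL` for datasets
#'   without symmetry structure.
#' @param template character vector giving the canonical label order; default
#'   is the pairing's labels (left block, right block, midline) or the first
#'   configuration's order.
#' @return An object of class `landmark_dataset` with fields `configurations`,
#'   `pairing`, `metadata`, and attribute-free accessors; `missing_report`
#'   gives per-specimen missing-landmark counts.
#' @export
assemble_dataset <- function(configs, metadata, pairing = NULL, template = NULL) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  lab0 <- sort(configs[[1]]$labels)
  D <- ncol(configs[[1]]$coords)
  for (cf in configs) {
    if (!identical(sort(cf$labels), lab0)) {
      extra <- setdiff(cf$labels, lab0)
      miss <- setdiff(lab0, cf$labels)
      stop("label set mismatch for specimen '", cf$specimen_id, "'",
           if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
           if (length(miss)) paste0("; absent: ", paste(miss, collapse = ", ")))
    }
    if (ncol(cf$coords) != D)
      stop("dimension mismatch for specimen '", cf$specimen_id, "'")
  }
  if (is.null(template)) {
    template <- if (!is.null(pairing)) pairing_labels(pairing) else configs[[1]]$labels
  }
  if (!identical(sort(template), lab0))
    stop("template labels do not match configuration labels")
  if (!is.null(pairing)) {
    bad <- setdiff(pairing_labels(pairing), lab0)
    if (length(bad)) stop("pairing labels not present in configurations: ",
                          paste(bad, collapse = ", "))
    if (!setequal(pairing_labels(pairing), lab0))
      stop("pairing does not cover every landmark label")
  }
  configs <- lapply(configs, function(cf) {
    idx <- match(template, cf$labels)
    landmark_config(cf$coords[idx, , drop = FALSE], labels = template,
                    specimen_id = cf$specimen_id, missing = cf$missing[idx])
  })
  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  if (anyDuplicated(ids)) stop("duplicate specimen ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  metadata <- as.data.frame(metadata)
  if (!"specimen_id" %in% names(metadata)) stop("metadata must have a specimen_id column")
  absent <- setdiff(ids, metadata$specimen_id)
  if (length(absent)) stop("metadata missing for specimens: ", paste(absent, collapse = ", "))
  metadata <- metadata[match(ids, metadata$specimen_id), , drop = FALSE]
  rownames(metadata) <- NULL
  names(configs) <- ids
  missing_report <- data.frame(
    specimen_id = ids,
    n_missing = vapply(configs, function(cf) sum(cf$missing), integer(1)),
    row.names = NULL
  )
  structure(
    list(configurations = configs, pairing = pairing, metadata = metadata,
         labels = template, missing_report = missing_report),
    class = "landmark_dataset"
  )
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat(sprintf("<landmark_dataset> %d specimens x %d landmarks (%dD); %d missing coordinates total\n",
              length(x$configurations), length(x$labels),
              ncol(x$configurations[[1]]$coords), sum(x$missing_report$n_missing)))
  invisible(x)
}

#' Stack a complete dataset into a k x D x n array
#'
#' @param dataset a [landmark_dataset] with no missing landmarks.
#' @return numeric array with dimnames (labels, axes, specimen ids).
#' @export
dataset_array <- function(dataset) {
  if (sum(dataset$missing_report$n_missing) > 0)
    stop("dataset has missing landmarks; run estimate_missing() first")
  k <- length(dataset$labels)
  D <- ncol(dataset$configurations[[1]]$coords)
  n <- length(dataset$configurations)
  arr <- array(NA_real_, dim = c(k, D, n),
               dimnames = list(dataset$labels,
                               c("x", "y", "z")[seq_len(D)],
                               names(dataset$configurations)))
  for (i in seq_len(n)) arr[, , i] <- dataset$configurations[[i]]$coords
  arr
}

#' Number of specimens in a landmark dataset
#' @param dataset a [landmark_dataset].
#' @return integer count.
#' @export
n_specimens <- function(dataset) length(dataset$configurations)
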