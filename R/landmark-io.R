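#' Read 3D Slicer markup landmarks
#'
#' Reads a 3D Slicer markups fiducial file, either the JSON flavour
#' (`.mrk.json`) or the legacy FCSV table. Landmark order follows file order;
#' points whose coordinates are unset or non-finite are flagged in the missing
#' mask. Units are taken as the file's units (assumed mm).
#'
#' @param path path to a `.mrk.json` or `.fcsv` file.
#' @param specimen_id specimen identifier; default is the file base name.
#' @return A [landmark_config].
#' @export
read_slicer_markups <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(specimen_id))
    specimen_id <- sub("\\.(mrk\\.json|json|fcsv)$", "", basename(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                    error = function(e) stop("malformed Slicer markups JSON in '",
                                             path, "': ", conditionMessage(e)))
    if (is.null(obj$markups) || !length(obj$markups))
      stop("no markups element in ", path)
    cps <- obj$markups[[1]]$controlPoints
    if (is.null(cps) || !length(cps)) stop("no control points in ", path)
    k <- length(cps)
    coords <- matrix(NA_real_, k, 3)
    labels <- character(k)
    missing <- logical(k)
    for (i in seq_len(k)) {
      cp <- cps[[i]]
      labels[i] <- if (!is.null(cp$label) && nzchar(cp$label)) cp$label else paste0("F_", i)
      pos <- unlist(cp$position)
      defined <- is.null(cp$positionStatus) || identical(cp$positionStatus, "defined")
      if (!defined || length(pos) != 3L || any(!is.finite(pos))) {
        missing[i] <- TRUE
      } else {
        coords[i, ] <- as.numeric(pos)
      }
    }
  } else {
    lines <- readLines(path, warn = FALSE)
    body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
    if (!length(body_idx)) stop("no fiducial rows in ", path)
    k <- length(body_idx)
    coords <- matrix(NA_real_, k, 3)
    labels <- character(k)
    missing <- logical(k)
    for (j in seq_len(k)) {
      ln <- body_idx[j]
      fields <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
      if (length(fields) < 4L)
        stop("malformed FCSV row at line ", ln, " of '", path,
             "': expected at least id,x,y,z")
      xyz <- suppressWarnings(as.numeric(fields[2:4]))
      labels[j] <- if (length(fields) >= 12L && nzchar(trimws(fields[12])))
        trimws(fields[12]) else paste0("F_", j)
      if (any(is.na(xyz))) {
        blank <- !nzchar(trimws(fields[2:4]))
        if (all(blank | is.na(suppressWarnings(as.numeric(fields[2:4]))))) {
          missing[j] <- TRUE
        }
        if (any(!blank & is.na(xyz)))
          stop("non-numeric coordinate at line ", ln, " of '", path, "'")
      } else {
        coords[j, ] <- xyz
      }
    }
  }
  if (anyDuplicated(labels))
    stop("duplicate landmark labels in '", path, "': ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  landmark_config(coords, labels = labels, specimen_id = specimen_id,
                  missing = missing)
}

#' Read a TPS landmark file
#'
#' Parses the Rohlf TPS interchange format: records introduced by `LM=<k>`
#' (2D) or `LM3=<k>` (3D), followed by k coordinate rows and an optional
#' `ID=` line. Rows with non-finite coordinates are flagged missing.
#'
#' @param path path to a TPS file.
#' @return A list of [landmark_config], one per record, in file order.
#' @export
read_tps_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    hdr <- regmatches(lines[i], regexec("^LM(3?)\\s*=\\s*(\\d+)$", lines[i]))[[1]]
    if (!length(hdr)) stop("expected LM=/LM3= header at line ", i, " of '", path,
                           "', got: ", lines[i])
    D <- if (hdr[2] == "3") 3L else 2L
    k <- as.integer(hdr[3])
    rec <- rec + 1L
    if (i + k > length(lines))
      stop("record ", rec, " in '", path, "' declares ", k,
           " landmarks but the file ends early")
    coords <- matrix(NA_real_, k, D)
    for (j in seq_len(k)) {
      toks <- strsplit(lines[i + j], "\\s+")[[1]]
      if (all(toupper(toks) %in% c("NAN", "NA"))) next # missing landmark row
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) != D || any(is.na(vals)))
        stop("record ", rec, ", row ", j, " in '", path, "': expected ", D,
             " numeric coordinates, got: ", lines[i + j])
      coords[j, ] <- vals
    }
    i <- i + k + 1L
    id <- paste0("record_", rec)
    while (i <= length(lines) && !grepl("^LM", lines[i])) {
      kv <- regmatches(lines[i], regexec("^([A-Z]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
      if (length(kv) && kv[2] == "ID" && nzchar(kv[3])) id <- kv[3]
      i <- i + 1L
    }
    out[[rec]] <- landmark_config(coords, specimen_id = id)
  }
  out
}

#' Write landmark configurations as a TPS file
#'
#' @param configs a [landmark_config] or list of them (or a
#'   [landmark_dataset], whose configurations are written in order).
#' @param path output path.
#' @param digits significant digits written (default 12; round-trip safe
#'   well below 1e-9 for coordinates in mm).
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path, digits = 12) {
  if (inherits(configs, "landmark_dataset")) configs <- configs$configurations
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    D <- ncol(cf$coords)
    tag <- if (D == 3L) "LM3" else "LM"
    writeLines(sprintf("%s=%d", tag, nrow(cf$coords)), con)
    for (j in seq_len(nrow(cf$coords))) {
      if (cf$missing[j]) {
        writeLines(paste(rep("NaN", D), collapse = " "), con)
      } else {
        writeLines(paste(formatC(cf$coords[j, ], digits = digits, format = "g"),
                         collapse = " "), con)
      }
    }
    writeLines(sprintf("ID=%s", cf$specimen_id), con)
  }
  invisible(path)
}

.trait_names <- c("ED", "EED", "FTL", "HH", "HL", "HW", "IND", "IOD", "SED", "Weight")

#' Read a morphometric trait table
#'
#' Reads a CSV of external linear measurements: one row per specimen with
#' `specimen_id`, the factors `species`, `region`, `island`, `sex`, snout-vent
#' length `SVL` (mm), `Weight` (g) and the nine linear head/limb traits (mm):
#' ED, EED, FTL, HH, HL, HW, IND, IOD, SED. Rows with any missing measurement
#' are flagged (column `complete`), mirroring the convention of excluding
#' incomplete specimens from multivariate analyses.
#'
#' @param path CSV path (UTF-8, header row required).
#' @return A `trait_table`: a data.frame with a logical `complete` column.
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "species", "region", "island", "sex", "SVL", .trait_names)
  absent <- setdiff(need, names(df))
  if (length(absent)) stop("trait table lacks columns: ", paste(absent, collapse = ", "))
  num_cols <- c("SVL", .trait_names)
  for (cl in num_cols) {
    raw <- df[[cl]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(trimws(as.character(raw))) & is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", cl, "', row ", bad[1],
           ": '", raw[bad[1]], "'")
    df[[cl]] <- v
  }
  trait_table(df)
}

#' Construct / validate a trait table
#'
#' @param df data.frame with the columns described in [read_trait_table()].
#' @return A `trait_table` data.frame with a `complete` flag column.
#' @export
trait_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("specimen_id", "species", "sex", "SVL", .trait_names)
  absent <- setdiff(need, names(df))
  if (length(absent)) stop("trait table lacks columns: ", paste(absent, collapse = ", "))
  for (f in intersect(c("species", "region", "island", "sex"), names(df)))
    df[[f]] <- factor(df[[f]])
  meas <- c("SVL", .trait_names)
  df$complete <- rowSums(is.na(df[, meas, drop = FALSE])) == 0
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Names of the corrected trait set
#'
#' The nine linear traits plus Weight; SVL is excluded because it serves as
#' the size metric.
#' @return character vector of 10 trait names.
#' @export
trait_names <- function() .trait_names
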