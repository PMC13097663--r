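#' Write a CT volume
#'
#' Writes a [grey_volume] as either a raw-encoded NRRD file (`.nrrd`,
#' double precision, little endian) or a multipage 32-bit float TIFF stack
#' (`.tif`/`.tiff`, one page per slice along the third axis; intensities are
#' rescaled to [0, 1], with the original range recorded in a plain-text
#' `<path>.range` sidecar so [read_volume()] can restore the gray values).
#'
#' @param volume a [grey_volume].
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "grey_volume"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    d <- dim(volume$voxels)
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- c("NRRD0004",
             "type: double",
             "dimension: 3",
             paste("sizes:", paste(d, collapse = " ")),
             paste("spacings:", paste(format(volume$spacing, digits = 12), collapse = " ")),
             "endian: little",
             "encoding: raw",
             "")
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(volume$voxels), con, size = 8, endian = "little")
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rng <- range(volume$voxels)
    span <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(dim(volume$voxels)[3]), function(z)
      (volume$voxels[, , z] - rng[1]) / span)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    writeLines(format(c(rng[1], rng[1] + span), digits = 17),
               paste0(path, ".range"))
  } else stop("unsupported volume format: ", path)
  invisible(path)
}

#' Read a CT volume
#'
#' Reads raw-encoded NRRD files or multipage TIFF stacks written by
#' [write_volume()] (TIFF intensities are restored from the range recorded
#' in the description tag when present).
#'
#' @param path path to a `.nrrd` or `.tif`/`.tiff` file.
#' @return a [grey_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readLines(con, n = 1)
    if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
    fields <- list()
    repeat {
      ln <- readLines(con, n = 1)
      if (!length(ln) || !nzchar(ln)) break
      if (grepl("^#", ln)) next
      kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3) fields[[trimws(kv[2])]] <- trimws(kv[3])
    }
    sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
    if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
    if (!identical(fields$encoding, "raw"))
      stop("only raw NRRD encoding is supported, got: ", fields$encoding)
    type <- fields$type
    n <- prod(sizes)
    endian <- if (identical(fields$endian, "big")) "big" else "little"
    vox <- switch(type,
      "double" = readBin(con, numeric(), n = n, size = 8, endian = endian),
      "float" = readBin(con, numeric(), n = n, size = 4, endian = endian),
      "uchar" = , "uint8" = , "unsigned char" =
        as.numeric(readBin(con, integer(), n = n, size = 1, signed = FALSE)),
      "short" = , "int16" = readBin(con, integer(), n = n, size = 2, endian = endian),
      "ushort" = , "uint16" =
        readBin(con, integer(), n = n, size = 2, signed = FALSE, endian = endian),
      stop("unsupported NRRD type: ", type))
    spacing <- if (!is.null(fields$spacings))
      as.numeric(strsplit(fields$spacings, "\\s+")[[1]]) else c(1, 1, 1)
    grey_volume(array(vox, sizes), spacing)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- simplify2array(lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]
      p
    }))
    sidecar <- paste0(path, ".range")
    if (file.exists(sidecar)) {
      rng <- as.numeric(readLines(sidecar))
      arr <- arr * (rng[2] - rng[1]) + rng[1]
    }
    grey_volume(arr)
  } else stop("unsupported volume format: ", path)
}
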