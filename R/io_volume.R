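#' Read a 3D volume from NRRD or TIFF
#'
#' Supported on-disk formats are NRRD (raw encoding; lossless float) and
#' multi-page TIFF (16-bit unsigned integer, the native range of
#' light-sheet cameras; one page per z slice). Voxel pitch is taken from
#' NRRD `spacings` metadata when present; TIFF files carry no reliable
#' pitch metadata, so `pitch_override` is required for TIFF. The reader
#' fails rather than guessing a pitch.
#'
#' @param path path to a `.nrrd` file or a `.tif`/`.tiff` stack.
#' @param pitch_override optional per-axis pitch in micrometres
#'   ((z, y, x) order, or one value for all axes); overrides file
#'   metadata when given.
#' @return A [volume3d].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, pitch_override = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    parsed <- read_nrrd(path)
    pitch <- if (!is.null(pitch_override)) pitch_override else parsed$spacings
    if (is.null(pitch))
      stop("no voxel pitch: NRRD has no 'spacings' field and no pitch_override given")
    volume3d(parsed$data, pitch)
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(pitch_override))
      stop("no voxel pitch: TIFF carries no pitch metadata; supply pitch_override")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(!vapply(pages, is.matrix, logical(1))))
      stop("non-3D data: TIFF pages are not 2D grayscale")
    d2 <- dim(pages[[1]])
    arr <- array(0, c(length(pages), d2[1], d2[2]))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    volume3d(arr, pitch_override)
  } else {
    stop("unsupported volume format: .", ext, " (expected .nrrd or .tif/.tiff)")
  }
}

#' Write a 3D volume to NRRD or TIFF
#'
#' NRRD output stores double-precision intensities losslessly (raw
#' little-endian encoding) together with the voxel spacings. TIFF output
#' stores 16-bit unsigned integers: intensities must be integer-valued
#' and within \[0, 65535\], and the pitch is not stored in the file.
#'
#' @param volume a [volume3d].
#' @param path output path ending in `.nrrd` or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume3d"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") {
    write_nrrd(volume$data, path, spacings = volume$pitch_um)
  } else if (ext %in% c("tif", "tiff")) {
    x <- volume$data
    if (max(x) > 65535 || any(x != round(x)))
      stop("TIFF output is 16-bit unsigned integer: intensities must be integers in [0, 65535]; use NRRD for float data")
    pages <- lapply(seq_len(dim(x)[1]), function(z) x[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    stop("unsupported volume format: .", ext)
  }
  invisible(path)
}

# Minimal NRRD (v4) reader: raw encoding, little endian, dimension 3.
# Header is "key: value" lines terminated by a blank line; sizes are
# fastest-axis-first, matching R's column-major layout with dim (z, y, x).
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed NRRD: no blank line after header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  if (!identical(fields[["dimension"]], "3"))
    stop("non-3D data: NRRD dimension is ", fields[["dimension"]] %||% "missing")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("malformed NRRD sizes field")
  enc <- fields[["encoding"]] %||% "raw"
  if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  type <- fields[["type"]]
  n <- prod(sizes)
  data <- switch(type,
    "double" = , "float64" = readBin(con, "double", n, size = 8, endian = "little"),
    "float"  = , "float32" = readBin(con, "double", n, size = 4, endian = "little"),
    "int"    = , "int32"   = , "signed int" =
      readBin(con, "integer", n, size = 4, endian = "little"),
    "short"  = , "int16"   = , "signed short" =
      readBin(con, "integer", n, size = 2, endian = "little"),
    "unsigned short" = , "uint16" =
      readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
    "unsigned char" = , "uint8" =
      readBin(con, "integer", n, size = 1, signed = FALSE, endian = "little"),
    stop("unsupported NRRD type: ", type)
  )
  if (length(data) != n) stop("malformed NRRD: truncated data block")
  spacings <- NULL
  if (!is.null(fields[["spacings"]]))
    spacings <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  list(data = array(data, sizes), spacings = spacings)
}

write_nrrd <- function(data, path, spacings = NULL, type = c("double", "int32")) {
  type <- match.arg(type)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    paste0("type: ", if (type == "double") "double" else "int"),
    "dimension: 3",
    paste0("sizes: ", paste(dim(data), collapse = " ")),
    "encoding: raw",
    "endian: little"
  )
  if (!is.null(spacings))
    hdr <- c(hdr, paste0("spacings: ", paste(format(spacings, digits = 17), collapse = " ")))
  writeLines(c(hdr, ""), con)
  if (type == "double") {
    writeBin(as.vector(as.double(data)), con, size = 8, endian = "little")
  } else {
    writeBin(as.vector(as.integer(data)), con, size = 4, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
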