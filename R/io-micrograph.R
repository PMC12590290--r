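#' Micrograph record
#'
#' One 2D grayscale micrograph: the image matrix (rows = y, columns = x),
#' its identity and size, and an optional pixel size in Angstrom/pixel.
#'
#' @param image Numeric matrix of intensities (finite).
#' @param micrograph_id Identifier string (defaults to the file name).
#' @param pixel_size Optional Angstrom/pixel.
#' @param source_path Originating file path, if any.
#' @return A list of class `micrograph`.
#' @export
micrograph <- function(image, micrograph_id, pixel_size = NA_real_,
                       source_path = NA_character_) {
  stopifnot(is.matrix(image), nrow(image) > 0, ncol(image) > 0)
  if (any(!is.finite(image))) stop("micrograph contains non-finite intensities")
  structure(list(image = image, micrograph_id = micrograph_id,
                 width = ncol(image), height = nrow(image),
                 pixel_size = pixel_size, source_path = source_path),
            class = "micrograph")
}

#' Standardize an image to zero mean and unit variance
#'
#' The only intensity preprocessing applied before the detector. A variance
#' floor of 1e-6 guards constant images (which standardize to all zeros).
#' @param image Numeric matrix.
#' @export
standardize_image <- function(image) {
  (image - mean(image)) / max(stats::sd(image), 1e-6)
}

## ---- MRC (modes 0/1/2/6, single 2D section) --------------------------------

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head_ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- head_ints[1]; ny <- head_ints[2]; nz <- head_ints[3]
  mode <- head_ints[4]
  if (nz > 1)
    stop("multi-section stack (", nz, " sections); expected a single 2D image")
  cella <- {
    seek(con, 40)  # CELLA floats at byte 40
    readBin(con, "numeric", n = 3, size = 4, endian = "little")
  }
  seek(con, 92)    # NSYMBT: extended-header length in bytes
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny
  v <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode: ", mode))
  if (length(v) < n) stop("truncated MRC data")
  # MRC stores x fastest; build a (ny rows, nx cols) matrix
  img <- t(matrix(v, nx, ny))
  apix <- if (nx > 0 && cella[1] > 0) cella[1] / nx else NA_real_
  list(image = img, pixel_size = apix)
}

#' Write a 2D image as an MRC file (mode 2, float32)
#'
#' @param image Numeric matrix (rows = y).
#' @param path Output path.
#' @param pixel_size Angstrom/pixel recorded in the cell dimensions
#'   (optional).
#' @export
write_mrc <- function(image, path, pixel_size = NA_real_) {
  nx <- ncol(image); ny <- nrow(image)
  con <- file(path, "wb")
  on.exit(close(con))
  apix <- if (is.finite(pixel_size)) pixel_size else 1
  writeBin(as.integer(c(nx, ny, 1L, 2L, 0L, 0L, 0L, nx, ny, 1L)), con,
           size = 4, endian = "little")
  writeBin(as.numeric(c(nx * apix, ny * apix, apix)), con, size = 4,
           endian = "little")                       # CELLA
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(image), max(image), mean(image))), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(0L, 0L)), con, size = 4, endian = "little")  # ISPG, NSYMBT
  writeBin(raw(28 * 4), con)                        # EXTRA + ORIGIN, words 25-52
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(image)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")    # NLABL
  writeBin(raw(800), con)                           # labels
  writeBin(as.numeric(as.vector(t(image))), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a micrograph from MRC, PNG, or TIFF
#'
#' The image is standardized to zero mean and unit variance per micrograph
#' ([standardize_image()]); original size and (for MRC) pixel size are kept
#' in the record. Multi-section MRC stacks are rejected.
#'
#' @param path Image path with extension mrc/mrcs/png/tif/tiff.
#' @return A [micrograph()] record.
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  apix <- NA_real_
  if (ext %in% c("mrc", "mrcs")) {
    m <- read_mrc(path)
    img <- m$image
    apix <- m$pixel_size
  } else if (ext == "png") {
    img <- gray_from_array(png::readPNG(path))
  } else if (ext %in% c("tif", "tiff")) {
    img <- gray_from_array(tiff::readTIFF(path))
  } else {
    stop("unsupported micrograph format: .", ext)
  }
  if (any(!is.finite(img))) stop("non-finite intensities in ", path)
  micrograph(standardize_image(img), micrograph_id = basename(path),
             pixel_size = apix, source_path = path)
}

gray_from_array <- function(a) {
  if (length(dim(a)) == 3) {
    nc <- min(dim(a)[3], 3)
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  a
}
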