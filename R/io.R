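# Image file I/O. Images are plain numeric matrices indexed [row, col] in
# raw intensity units on the [0, 2^bit_depth - 1] scale; files are
# single-channel grayscale TIFF (preferred) or PNG.

#' Write an intensity matrix as a grayscale TIFF
#'
#' @param image Numeric matrix `[row, col]` in `[0, 2^bit_depth - 1]`.
#' @param path Output file path.
#' @param bit_depth 8 or 16; sets both the intensity scale and the sample
#'   depth of the file.
#' @return `path`, invisibly.
#' @export
write_intensity_tiff <- function(image, path, bit_depth = 16) {
  stopifnot(is.matrix(image), bit_depth %in% c(8L, 16L))
  max_int <- 2^bit_depth - 1
  scaled <- pmin(pmax(image / max_int, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

#' Read a grayscale image into an intensity matrix
#'
#' Reads TIFF or PNG; multi-channel images are reduced to their first
#' channel. Values are returned in raw intensity units (`[0, 1]` file values
#' scaled by `2^bits - 1`, where `bits` is the file's sample depth for TIFF
#' and 16 for PNG).
#'
#' @param path Image file path.
#' @return Numeric matrix `[row, col]` with attribute `bit_depth`.
#' @export
read_intensity_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(img, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
  } else if (ext == "png") {
    img <- png::readPNG(path)
    bits <- 16L
  } else {
    stop("unsupported image format '", ext, "' for ", path,
         " (expected TIFF or PNG)")
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- img * (2^bits - 1)
  attr(m, "bit_depth") <- as.integer(bits)
  m
}
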