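#' Validate an RGB raster
#'
#' Images in this package are plain numeric arrays of dimension
#' `height x width x 3` holding 8-bit intensities in `[0, 255]`
#' (whole numbers; stored as doubles for arithmetic convenience).
#' `as_rgb_image()` checks that contract and returns the array.
#'
#' @param pixels array to validate.
#' @return the validated `H x W x 3` array.
#' @export
as_rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    sn_format_error("an RGB image must be an H x W x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    sn_format_error("RGB intensities must lie in [0, 255]")
  pixels
}

#' Read a flat raster image (PNG, JPEG or single-plane TIFF)
#'
#' Returns an `H x W x 3` array of intensities in `[0, 255]`. Grayscale
#' images are replicated to three channels; an alpha channel is dropped.
#' For tiled pyramidal TIFFs written by this package use [open_pyramid()].
#'
#' @param path file path; format chosen by extension.
#' @return RGB array, see [as_rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) sn_io_error(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = {
      pyr <- tryCatch(open_pyramid(path), error = function(e) NULL)
      if (!is.null(pyr)) return(read_region(pyr, 1L, 0L, 0L,
                                            pyr$levels[[1]]$width,
                                            pyr$levels[[1]]$height))
      if (!requireNamespace("tiff", quietly = TRUE))
        sn_io_error("reading foreign TIFFs requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    sn_format_error(paste0("unsupported image extension: ", ext))
  )
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  as_rgb_image(round_half_up(x * 255))
}

#' Write a flat raster image as PNG
#'
#' @param image RGB array in `[0, 255]`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_rgb_image(image)
  png::writePNG(image / 255, path)
  invisible(path)
}
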