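# A fitted per-slide transform: everything needed to map any pixel of
# one source slide onto the target's chromatic profile. Estimated once
# per slide (globally), applied per pixel/tile -- estimating globally
# keeps tile boundaries seam-free.
source_transform <- function(stats, profile) {
  list(illuminant = stats$illuminant,
       stains_src = stats$stains,
       stains_target = profile$stains,
       ratio_h = profile$scale_h / stats$scale_h,
       ratio_e = profile$scale_e / stats$scale_e,
       scale_h_src = stats$scale_h, scale_e_src = stats$scale_e)
}

# the fixed per-pixel map: white balance -> OD -> source-stain
# separation -> per-stain linear rescale -> reconstruction in the
# TARGET stain basis against a neutral illuminant. Background pixels
# ride the same path (near-zero concentrations reconstruct to
# near-white, which is what lifts tissue/background contrast).
apply_stain_transform <- function(image, tf) {
  bal <- white_balance(image, tf$illuminant)
  od <- rgb_to_od(bal, c(255, 255, 255))
  conc <- compute_concentrations(od, tf$stains_src)
  conc[, , 1] <- conc[, , 1] * tf$ratio_h
  conc[, , 2] <- conc[, , 2] * tf$ratio_e
  reconstruct(conc, tf$stains_target, c(255, 255, 255))
}

#' Normalize an image to a target chromatic profile
#'
#' The four-stage pipeline: (i) tissue detection, (ii) illuminant
#' estimation and white balancing, (iii) stain separation with the
#' source's own (Macenko-estimated) stain matrix, and (iv) per-stain
#' chromatic matching -- each concentration channel is linearly
#' rescaled so the source's 99th-percentile tissue concentration equals
#' the target's, and pixels are reconstructed in the target's stain
#' basis against a neutral white illuminant.
#'
#' Because step (iv) is a positive per-stain rescale, the rank order of
#' stain amounts across pixels -- the local tissue structure -- is
#' preserved exactly; only the chromatic appearance changes.
#'
#' @param source RGB array to normalize.
#' @param profile a [stain_profile()] fitted on the target image.
#' @param params a [norm_params()] list.
#' @return normalized RGB array with the same dimensions as `source`.
#' @export
normalize_image <- function(source, profile, params = norm_params()) {
  if (!inherits(profile, "stain_profile"))
    sn_validation_error("profile must be a stain_profile")
  st <- source_stats(source, params)
  apply_stain_transform(source, source_transform(st, profile))
}

#' Normalize a whole-slide pyramid to a target profile
#'
#' Slide-level variant of [normalize_image()] honoring the WSI output
#' contract: the input pyramid is brought to 200x-equivalent
#' resolution (2x average pooling if finer than 0.35 um/px, see
#' [resample_to_200x()]), the source's chromatic statistics are
#' estimated ONCE from a stride-sampled composite (so tiles share one
#' transform and the mosaic has no seams), the fixed transform is
#' applied tile by tile, and the result is written as a tiled pyramidal
#' TIFF (JPEG quality 80 by default).
#'
#' Tiles with no pixel above the tissue OD threshold are counted as
#' `tiles_skipped`; they pass through the same transform (background
#' reconstructs to near-white), so the mosaic equals the whole-image
#' result exactly.
#'
#' @param pyramid a `"tile_pyramid"` from [open_pyramid()].
#' @param profile a [stain_profile()].
#' @param params a [norm_params()] list; `tile_size` controls both
#'   processing and output tiling.
#' @param output_path output TIFF path.
#' @param compression `"jpeg"` (default) or `"none"`.
#' @param jpeg_quality JPEG quality factor in `[1, 100]` (default 80).
#' @return a `"wsi_normalization"` summary: tile counts, the global
#'   transform parameters, output path and resolution.
#' @export
normalize_wsi <- function(pyramid, profile, params = norm_params(),
                          output_path, compression = c("jpeg", "none"),
                          jpeg_quality = 80) {
  compression <- match.arg(compression)
  if (!inherits(pyramid, "tile_pyramid"))
    sn_validation_error("pyramid must be a tile_pyramid (see open_pyramid)")
  if (!inherits(profile, "stain_profile"))
    sn_validation_error("profile must be a stain_profile")
  params <- as_norm_params(params)

  lvl <- pyramid$levels[[1]]
  img <- read_region(pyramid, 1L, 0L, 0L, lvl$width, lvl$height)
  rs <- resample_to_200x(img, pyramid$microns_per_pixel)
  img <- rs$image
  mpp <- rs$microns_per_pixel
  h <- dim(img)[1]; w <- dim(img)[2]

  # global estimation on a stride-decimated composite; stride 1 (all
  # pixels) up to 2048 px, so small slides estimate on everything
  stride <- max(1L, ceiling(max(h, w) / 2048L))
  comp <- img[seq(1L, h, stride), seq(1L, w, stride), , drop = FALSE]
  st <- source_stats(comp, params)
  tf <- source_transform(st, profile)

  ts <- params$tile_size
  out <- array(0, dim(img))
  ntx <- ceiling(w / ts); nty <- ceiling(h / ts)
  skipped <- 0L
  thr2 <- params$od_tissue_threshold^2
  for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
    ys <- ((ty - 1L) * ts + 1L):min(ty * ts, h)
    xs <- ((tx - 1L) * ts + 1L):min(tx * ts, w)
    tile <- img[ys, xs, , drop = FALSE]
    od <- rgb_to_od(white_balance(tile, tf$illuminant), c(255, 255, 255))
    if (max(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2) <= thr2)
      skipped <- skipped + 1L
    out[ys, xs, ] <- apply_stain_transform(tile, tf)
  }
  pyr <- write_pyramid(out, output_path, tile_size = ts,
                       compression = compression,
                       jpeg_quality = jpeg_quality,
                       microns_per_pixel = mpp,
                       magnification = "200x")
  structure(list(tiles_processed = ntx * nty - skipped,
                 tiles_skipped = skipped,
                 illuminant = tf$illuminant,
                 stains_source = tf$stains_src,
                 scale_h_source = tf$scale_h_src,
                 scale_e_source = tf$scale_e_src,
                 ratio_h = tf$ratio_h, ratio_e = tf$ratio_e,
                 microns_per_pixel = mpp,
                 output_path = output_path, pyramid = pyr),
            class = "wsi_normalization")
}

#' @export
print.wsi_normalization <- function(x, ...) {
  cat(sprintf(
    "<wsi_normalization: %d tiles processed, %d skipped, %.4g um/px -> %s>\n",
    x$tiles_processed, x$tiles_skipped, x$microns_per_pixel,
    x$output_path))
  invisible(x)
}
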