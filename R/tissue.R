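#' Normalization pipeline parameters
#'
#' Bundles the tunable thresholds of the pipeline. Defaults are
#' appropriate for 200x (~0.47 um/px) H&E material.
#'
#' @param beta OD-norm threshold for stain-vector estimation (see
#'   [estimate_stain_matrix()]).
#' @param alpha angular percentile for stain-vector estimation.
#' @param od_tissue_threshold OD Euclidean norm above which a pixel is
#'   provisionally tissue (default 0.10).
#' @param min_component_px connected components smaller than this are
#'   dropped from the tissue mask (default 64 px at 200x).
#' @param background_fraction_floor minimum fraction of background
#'   pixels required to trust the background median as illuminant;
#'   below it the illuminant falls back to the 99th percentile of all
#'   pixels (default 0.01).
#' @param tile_size processing/output tile edge in pixels (default 256).
#' @return a list of class `"norm_params"`.
#' @export
norm_params <- function(beta = 0.15, alpha = 1, od_tissue_threshold = 0.10,
                        min_component_px = 64L,
                        background_fraction_floor = 0.01,
                        tile_size = 256L) {
  p <- list(beta = beta, alpha = alpha,
            od_tissue_threshold = od_tissue_threshold,
            min_component_px = as.integer(min_component_px),
            background_fraction_floor = background_fraction_floor,
            tile_size = as.integer(tile_size))
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1))))
    sn_validation_error("all normalization parameters must be positive scalars")
  structure(p, class = "norm_params")
}

as_norm_params <- function(p) {
  if (inherits(p, "norm_params")) p else do.call(norm_params, as.list(p))
}

#' Detect tissue against background
#'
#' A pixel is provisionally tissue if its OD Euclidean norm (computed
#' against a provisional pure-white illuminant) exceeds
#' `od_tissue_threshold`. The raw mask is cleaned by a 3x3 morphological
#' opening then closing, and connected components smaller than
#' `min_component_px` are removed. An all-background result is valid
#' and emits a warning.
#'
#' @param image RGB array.
#' @param params a [norm_params()] list.
#' @return logical `H x W` matrix, `TRUE` = tissue.
#' @export
detect_tissue <- function(image, params = norm_params()) {
  image <- as_rgb_image(image)
  params <- as_norm_params(params)
  od <- rgb_to_od(image, c(255, 255, 255))
  nrm2 <- od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2
  m <- (nrm2 > params$od_tissue_threshold^2) * 1
  k <- EBImage::makeBrush(3, "box")
  m <- EBImage::closing(EBImage::opening(m, k), k)
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= params$min_component_px)
    m <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  } else {
    m <- matrix(FALSE, dim(image)[1], dim(image)[2])
  }
  if (!any(m)) warning("no tissue detected; returning an empty mask")
  m
}

#' Estimate the scan illuminant (white point)
#'
#' The illuminant is the per-channel median of the background
#' (non-tissue) pixels. When the background fraction falls below
#' `background_fraction_floor` (a slide with near-total tissue
#' coverage), the per-channel 99th percentile over all pixels is used
#' instead. The result is clipped to `[1, 255]`.
#'
#' @inheritParams detect_tissue
#' @param mask logical tissue mask from [detect_tissue()].
#' @return numeric length-3 white point.
#' @export
estimate_illuminant <- function(image, mask, params = norm_params()) {
  image <- as_rgb_image(image)
  params <- as_norm_params(params)
  bg <- !mask
  ill <- numeric(3)
  if (mean(bg) < params$background_fraction_floor) {
    for (c in 1:3)
      ill[c] <- stats::quantile(image[, , c], 0.99, names = FALSE)
  } else {
    for (c in 1:3) ill[c] <- stats::median(image[, , c][bg])
  }
  clamp(ill, 1, 255)
}

#' White-balance an image to a neutral illuminant
#'
#' Rescales each channel so the estimated white point maps to pure
#' white: `I'_c = round(I_c * 255 / I0_c)`, clipped to `[0, 255]`.
#'
#' @inheritParams rgb_to_od
#' @return RGB array with a neutral (255, 255, 255) background.
#' @export
white_balance <- function(image, illuminant) {
  image <- as_rgb_image(image)
  if (length(illuminant) != 3L || any(illuminant <= 0))
    sn_domain_error("illuminant must be 3 strictly positive channel values")
  out <- image
  for (c in 1:3)
    out[, , c] <- round_half_up(image[, , c] * 255 / illuminant[c])
  clamp(out, 0, 255)
}
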