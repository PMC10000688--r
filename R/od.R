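#' Convert an RGB image to optical density (absorbance)
#'
#' Applies the Beer-Lambert transform per channel,
#' `OD_c = -log10(max(I_c, 1) / I0_c)`, where `I0` is the illuminant
#' (incident-light) intensity. Intensities are clamped to at least 1
#' before the logarithm so that fully black pixels map to the finite
#' absorbance `log10(I0_c)` instead of infinity; absorbance is clipped
#' below at 0 for pixels brighter than the illuminant. Stains combine
#' additively in this space, which is what makes linear stain
#' separation possible.
#'
#' @param image RGB array, `H x W x 3`, values in `[0, 255]`.
#' @param illuminant length-3 positive vector, the per-channel white
#'   point (default pure white, `c(255, 255, 255)`).
#' @return `H x W x 3` array of non-negative base-10 absorbances.
#' @seealso [od_to_rgb()] for the inverse.
#' @export
rgb_to_od <- function(image, illuminant = c(255, 255, 255)) {
  image <- as_rgb_image(image)
  if (length(illuminant) != 3L || any(illuminant <= 0))
    sn_domain_error("illuminant must be 3 strictly positive channel values")
  od <- image
  for (c in 1:3)
    od[, , c] <- -log10(pmax(image[, , c], 1) / illuminant[c])
  pmax(od, 0)
}

#' Convert optical density back to RGB
#'
#' Inverse Beer-Lambert transform: `I_c = round(I0_c * 10^(-OD_c))`,
#' rounded half-up and clipped to `[0, 255]`. Together with
#' [rgb_to_od()] this is bit-exact on any 8-bit image whose intensities
#' are all at least 1 (the clamp in the forward transform is then
#' inactive).
#'
#' @param od `H x W x 3` array of finite non-negative absorbances.
#' @inheritParams rgb_to_od
#' @return RGB array, values in `[0, 255]`.
#' @export
od_to_rgb <- function(od, illuminant = c(255, 255, 255)) {
  if (!is.array(od) || length(dim(od)) != 3L || dim(od)[3] != 3L)
    sn_format_error("od must be an H x W x 3 array")
  if (anyNA(od) || any(!is.finite(od)) || min(od) < 0)
    sn_domain_error("optical densities must be finite and non-negative")
  if (length(illuminant) != 3L || any(illuminant <= 0))
    sn_domain_error("illuminant must be 3 strictly positive channel values")
  out <- od
  for (c in 1:3)
    out[, , c] <- round_half_up(illuminant[c] * 10^(-od[, , c]))
  clamp(out, 0, 255)
}
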