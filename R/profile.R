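# shared estimation path: everything normalization needs to know about
# one image (its own chromatic statistics)
source_stats <- function(image, params = norm_params()) {
  image <- as_rgb_image(image)
  params <- as_norm_params(params)
  mask <- detect_tissue(image, params)
  if (!any(mask))
    sn_insufficient_tissue_error("image contains no detectable tissue")
  ill <- estimate_illuminant(image, mask, params)
  bal <- white_balance(image, ill)
  od <- rgb_to_od(bal, c(255, 255, 255))
  stains <- estimate_stain_matrix(od, mask, params$beta, params$alpha)
  conc <- compute_concentrations(od, stains)
  m <- as.vector(mask)
  cc <- matrix(conc, ncol = 2L)
  list(mask = mask, illuminant = ill, balanced = bal, od = od,
       stains = stains, conc = conc,
       scale_h = stats::quantile(cc[m, 1], 0.99, names = FALSE),
       scale_e = stats::quantile(cc[m, 2], 0.99, names = FALSE))
}

#' Fit the chromatic profile of a target image
#'
#' The profile is the "fitted object" of stain normalization: it
#' records everything about the pathologist-chosen target image that
#' normalization reproduces on other slides -- the target's stain
#' matrix, its robust per-stain concentration scales (99th percentile
#' of each stain amount over tissue pixels, robust against isolated
#' saturated pixels) and its estimated illuminant. The fit runs the
#' full estimation pipeline: tissue detection, illuminant estimation,
#' white balancing, Macenko stain-vector estimation and stain
#' separation.
#'
#' Use [predict.stain_profile()] (or [normalize_image()]) to apply the
#' profile to a source image, and [write_stain_profile()] /
#' [read_stain_profile()] to persist it as a plain-text file.
#'
#' @param target RGB array, the target image.
#' @param params a [norm_params()] list.
#' @param source_id free-text identifier stored with the profile.
#' @return an object of class `"stain_profile"` with elements
#'   `stains` (2 x 3 matrix), `scale_h`, `scale_e`, `illuminant`,
#'   `params`, `source_id`.
#' @export
stain_profile <- function(target, params = norm_params(), source_id = "") {
  st <- source_stats(target, params)
  structure(list(stains = st$stains, scale_h = st$scale_h,
                 scale_e = st$scale_e, illuminant = st$illuminant,
                 params = as_norm_params(params),
                 source_id = as.character(source_id)),
            class = "stain_profile")
}

#' @export
print.stain_profile <- function(x, digits = 4, ...) {
  cat("Chromatic profile (H&E stain normalization target)\n")
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  cat("  stain matrix (rows unit-norm OD-RGB):\n")
  m <- format(round(x$stains, digits))
  cat(sprintf("    H: %s\n    E: %s\n",
              paste(m[1, ], collapse = " "), paste(m[2, ], collapse = " ")))
  cat(sprintf("  concentration scales (p99): H %.4g, E %.4g\n",
              x$scale_h, x$scale_e))
  cat(sprintf("  illuminant: %s\n",
              paste(round(x$illuminant, 1), collapse = " ")))
  invisible(x)
}

#' @export
coef.stain_profile <- function(object, ...) {
  cbind(object$stains, scale = c(object$scale_h, object$scale_e))
}

#' Apply a chromatic profile to a source image
#'
#' `predict()` on a fitted [stain_profile()] normalizes a new image to
#' the profile; equivalent to [normalize_image()].
#'
#' @param object a `"stain_profile"`.
#' @param image source RGB array.
#' @param params pipeline parameters; defaults to those stored in the
#'   profile.
#' @param ... unused.
#' @return normalized RGB array.
#' @export
predict.stain_profile <- function(object, image, params = NULL, ...) {
  normalize_image(image, object,
                  if (is.null(params)) object$params else params)
}

profile_fmt <- function(x) sprintf("%.12g", x)

#' Persist a chromatic profile as plain text
#'
#' Writes a small deterministic key-value file (one `key: values` line
#' per field) holding the stain vectors, concentration scales,
#' illuminant and pipeline parameters. Repeated writes of the same
#' profile are byte-identical.
#'
#' @param profile a `"stain_profile"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stain_profile <- function(profile, path) {
  if (!inherits(profile, "stain_profile"))
    sn_validation_error("not a stain_profile")
  p <- profile$params
  lines <- c(
    "stainnorm_profile: 1",
    paste0("source_id: ", profile$source_id),
    paste0("h_vector: ", paste(profile_fmt(profile$stains[1, ]), collapse = " ")),
    paste0("e_vector: ", paste(profile_fmt(profile$stains[2, ]), collapse = " ")),
    paste0("scale_h: ", profile_fmt(profile$scale_h)),
    paste0("scale_e: ", profile_fmt(profile$scale_e)),
    paste0("illuminant: ", paste(profile_fmt(profile$illuminant), collapse = " ")),
    paste0("beta: ", profile_fmt(p$beta)),
    paste0("alpha: ", profile_fmt(p$alpha)),
    paste0("od_tissue_threshold: ", profile_fmt(p$od_tissue_threshold)),
    paste0("min_component_px: ", p$min_component_px),
    paste0("background_fraction_floor: ", profile_fmt(p$background_fraction_floor)),
    paste0("tile_size: ", p$tile_size)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromatic profile written by [write_stain_profile()]
#'
#' @param path profile file path.
#' @return a `"stain_profile"`.
#' @export
read_stain_profile <- function(path) {
  if (!file.exists(path)) sn_io_error(paste0("no such file: ", path))
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(": ?", lines), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
  names(vals) <- keys
  if (!identical(unname(vals["stainnorm_profile"]), "1"))
    sn_format_error("not a stainnorm profile file")
  num <- function(k) as.numeric(strsplit(trimws(vals[[k]]), "\\s+")[[1]])
  params <- norm_params(beta = num("beta"), alpha = num("alpha"),
                        od_tissue_threshold = num("od_tissue_threshold"),
                        min_component_px = num("min_component_px"),
                        background_fraction_floor = num("background_fraction_floor"),
                        tile_size = num("tile_size"))
  structure(list(stains = stain_matrix(num("h_vector"), num("e_vector")),
                 scale_h = num("scale_h"), scale_e = num("scale_e"),
                 illuminant = num("illuminant"), params = params,
                 source_id = if (is.na(vals["source_id"])) "" else
                   unname(vals["source_id"])),
            class = "stain_profile")
}
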