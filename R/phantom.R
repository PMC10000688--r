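#' Specification of a synthetic H&E phantom
#'
#' Phantoms emulate H&E-stained prostate-like biopsy tissue at 200x
#' (~0.47 um/px): elliptical gland profiles whose stroma carries eosin,
#' scattered nuclear discs carrying hematoxylin, empty lumina and clean
#' background. Rendering is a Beer-Lambert forward model with known
#' stain matrix, per-pixel concentration ground truth and additive
#' Gaussian OD noise, quantized to 8 bits -- so every downstream
#' estimator can be scored against truth.
#'
#' The default OD noise (`noise_od_sigma = 0.005`) corresponds to about
#' one gray level of sensor noise at mid intensity on an 8-bit scanner.
#'
#' @param width,height image size in pixels (minimum 64).
#' @param n_glands number of elliptical gland profiles.
#' @param nucleus_density expected nuclei per 10^4 tissue pixels.
#' @param stain_matrix_true ground-truth stain matrix; defaults to the
#'   classical H/E reference vectors.
#' @param scale_h_true,scale_e_true maximum stain amounts (OD units);
#'   the 99th percentile of each true concentration channel over tissue
#'   sits just below these.
#' @param illuminant_true simulated scanner white point.
#' @param noise_od_sigma standard deviation of additive OD noise.
#' @param seed integer; phantoms are pure functions of their seed.
#' @return a list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(width = 512L, height = 512L, n_glands = 12L,
                         nucleus_density = 40,
                         stain_matrix_true =
                           stain_matrix(c(0.65, 0.70, 0.29),
                                        c(0.07, 0.99, 0.11)),
                         scale_h_true = 1.0, scale_e_true = 0.8,
                         illuminant_true = c(255, 255, 255),
                         noise_od_sigma = 0.005, seed = 1L) {
  if (width < 64L || height < 64L)
    sn_validation_error("phantom dimensions must be at least 64 px")
  if (noise_od_sigma < 0)
    sn_validation_error("noise_od_sigma must be non-negative")
  if (!is_stain_matrix(stain_matrix_true))
    sn_validation_error("stain_matrix_true is not a valid stain matrix")
  if (scale_h_true <= 0 || scale_e_true <= 0)
    sn_validation_error("stain scales must be positive")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_glands = as.integer(n_glands),
                 nucleus_density = nucleus_density,
                 stain_matrix_true = stain_matrix_true,
                 scale_h_true = scale_h_true, scale_e_true = scale_e_true,
                 illuminant_true = illuminant_true,
                 noise_od_sigma = noise_od_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# render an image from concentration fields + noise (shared by
# generate_phantom and degrade so degraded truth stays consistent)
render_phantom <- function(conc, stains, noise_od, illuminant) {
  od <- matrix(conc, ncol = 2L) %*% stains
  od <- array(od, c(dim(conc)[1:2], 3L)) + noise_od
  od_to_rgb(pmax(od, 0), illuminant)
}

#' Generate a synthetic H&E phantom with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `"he_phantom"` with elements `image`
#'   (quantized RGB), `concentrations_true` (`H x W x 2`), `mask_true`
#'   (logical), `noise_od` (the realized OD noise field, kept so
#'   [degrade()] can re-render consistently) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    ch <- matrix(0, h, w)
    ce <- matrix(0, h, w)
    tissue <- matrix(FALSE, h, w)
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    rmin <- 0.08 * min(h, w); rmax <- 0.16 * min(h, w)
    for (i in seq_len(spec$n_glands)) {
      cx <- stats::runif(1, 0.1 * w, 0.9 * w)
      cy <- stats::runif(1, 0.1 * h, 0.9 * h)
      a <- stats::runif(1, rmin, rmax)
      b <- stats::runif(1, rmin, rmax)
      th <- stats::runif(1, 0, pi)
      dx <- xx - cx; dy <- yy - cy
      u <- (dx * cos(th) + dy * sin(th)) / a
      v <- (-dx * sin(th) + dy * cos(th)) / b
      r2 <- u^2 + v^2
      ring <- r2 <= 1 & r2 > 0.35^2      # gland ring; inner part is lumen
      g_e <- stats::runif(1, 0.5, 1)
      n_ring <- sum(ring)
      if (n_ring) {
        ce[ring] <- spec$scale_e_true * g_e * stats::runif(n_ring, 0.7, 1)
        ch[ring] <- spec$scale_h_true * stats::runif(n_ring, 0, 0.08)
        tissue[ring] <- TRUE
      }
    }
    # nuclei: discs of high hematoxylin scattered over tissue
    t_idx <- which(tissue)
    n_nuc <- round(spec$nucleus_density * length(t_idx) / 1e4)
    if (n_nuc > 0 && length(t_idx)) {
      centers <- sample(t_idx, n_nuc, replace = TRUE)
      cyv <- (centers - 1) %% h + 1
      cxv <- (centers - 1) %/% h + 1
      radii <- stats::runif(n_nuc, 1.5, 3.5)
      amps <- spec$scale_h_true * stats::runif(n_nuc, 0.35, 1)
      for (i in seq_len(n_nuc)) {
        r <- radii[i]; ri <- ceiling(r)
        ys <- max(1, cyv[i] - ri):min(h, cyv[i] + ri)
        xs <- max(1, cxv[i] - ri):min(w, cxv[i] + ri)
        d2 <- outer((ys - cyv[i])^2, (xs - cxv[i])^2, "+")
        disc <- d2 <= r^2
        nd <- sum(disc)
        if (!nd) next
        sub_h <- ch[ys, xs, drop = FALSE]
        sub_e <- ce[ys, xs, drop = FALSE]
        sub_h[disc] <- amps[i] * stats::runif(nd, 0.85, 1)
        sub_e[disc] <- sub_e[disc] * 0.15
        ch[ys, xs] <- sub_h
        ce[ys, xs] <- sub_e
        sub_t <- tissue[ys, xs, drop = FALSE]; sub_t[disc] <- TRUE
        tissue[ys, xs] <- sub_t
      }
    }
    conc <- array(c(ch, ce), c(h, w, 2L))
    noise <- array(stats::rnorm(h * w * 3L, 0, spec$noise_od_sigma),
                   c(h, w, 3L))
    img <- render_phantom(conc, spec$stain_matrix_true, noise,
                          spec$illuminant_true)
    structure(list(image = img, concentrations_true = conc,
                   mask_true = tissue, noise_od = noise, spec = spec),
              class = "he_phantom")
  })
}

#' @export
print.he_phantom <- function(x, ...) {
  cat(sprintf("<he_phantom %dx%d, %d glands, tissue %.1f%%, seed %d>\n",
              x$spec$width, x$spec$height, x$spec$n_glands,
              100 * mean(x$mask_true), x$spec$seed))
  invisible(x)
}

#' Apply a suboptimal-staining degradation to a phantom
#'
#' Parametric stand-ins for the three suboptimal staining classes seen
#' in routine H&E material:
#' \describe{
#'   \item{reddish}{the eosin vector is rotated toward the red
#'     absorbance axis and the eosin amounts are boosted by
#'     `1 + severity` (over-eosinophilic appearance);}
#'   \item{greyish}{both stain vectors are blended toward the neutral
#'     gray axis by `0.7 * severity` (washed-out, desaturated hue);}
#'   \item{weak}{both concentration channels are multiplied by
#'     `1 - 0.7 * severity` (faint staining, poor contrast).}
#' }
#' Ground-truth concentrations and stain matrix are updated
#' consistently and the image is re-rendered with the phantom's stored
#' noise field, so `severity -> 0` reproduces the input exactly.
#'
#' @param phantom an `"he_phantom"` from [generate_phantom()].
#' @param mode one of `"reddish"`, `"greyish"`, `"weak"`.
#' @param severity degradation strength in `(0, 1]`.
#' @return a degraded `"he_phantom"`.
#' @export
degrade <- function(phantom, mode = c("reddish", "greyish", "weak"),
                    severity = 0.5) {
  if (!inherits(phantom, "he_phantom"))
    sn_validation_error("phantom must be an 'he_phantom' object")
  mode <- match.arg(mode)
  if (!is.numeric(severity) || length(severity) != 1 ||
      severity <= 0 || severity > 1)
    sn_validation_error("severity must be a scalar in (0, 1]")
  s <- phantom$spec$stain_matrix_true
  conc <- phantom$concentrations_true
  if (mode == "weak") {
    conc <- conc * (1 - 0.7 * severity)
  } else if (mode == "reddish") {
    wgt <- 0.5 * severity
    e <- (1 - wgt) * s[2, ] + wgt * c(1, 0, 0)
    s <- stain_matrix(s[1, ], e)
    conc[, , 2] <- conc[, , 2] * (1 + severity)
  } else { # greyish
    wgt <- 0.7 * severity
    g <- rep(1 / sqrt(3), 3)
    s <- stain_matrix((1 - wgt) * s[1, ] + wgt * g,
                      (1 - wgt) * s[2, ] + wgt * g)
  }
  out <- phantom
  out$spec$stain_matrix_true <- s
  out$concentrations_true <- conc
  out$image <- render_phantom(conc, s, phantom$noise_od,
                              phantom$spec$illuminant_true)
  out
}
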