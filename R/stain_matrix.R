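#' Construct a hematoxylin/eosin stain matrix
#'
#' A stain matrix is a `2 x 3` matrix of unit-norm, non-negative
#' absorbance directions in OD-RGB space: row 1 is hematoxylin (H),
#' row 2 eosin (E). Rows are renormalized to unit Euclidean norm and
#' validated: entries must be non-negative and the two directions must
#' be separated by at least 1 degree (otherwise per-pixel separation is
#' ill-posed).
#'
#' @param h,e length-3 non-negative vectors (need not be pre-normalized).
#' @return a `2 x 3` matrix with rownames `c("H", "E")`.
#' @examples
#' stain_matrix(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
#' @export
stain_matrix <- function(h, e) {
  if (length(h) != 3L || length(e) != 3L)
    sn_validation_error("stain vectors must have 3 components")
  if (anyNA(c(h, e)) || min(h) < 0 || min(e) < 0)
    sn_validation_error("stain vector entries must be non-negative")
  nh <- sqrt(sum(h^2)); ne <- sqrt(sum(e^2))
  if (nh == 0 || ne == 0) sn_validation_error("stain vectors must be non-zero")
  m <- rbind(H = h / nh, E = e / ne)
  colnames(m) <- c("R", "G", "B")
  if (angle_deg(m[1, ], m[2, ]) < 1)
    sn_degenerate_stain_error("stain vectors are within 1 degree of collinear")
  m
}

is_stain_matrix <- function(m) {
  is.matrix(m) && all(dim(m) == c(2L, 3L)) && min(m) >= 0 &&
    all(abs(rowSums(m^2) - 1) < 1e-9) && angle_deg(m[1, ], m[2, ]) >= 1
}

# flatten an H x W x 3 OD array to an N x 3 matrix
od_flat <- function(od) matrix(od, ncol = 3L)

#' Estimate the stain matrix from an image (Macenko method)
#'
#' Singular-direction estimation of the H and E absorbance vectors:
#' tissue OD pixels with Euclidean norm at least `beta` are projected
#' onto the plane spanned by the two principal components of their
#' covariance; the extreme directions at the `alpha` and `100 - alpha`
#' angular percentiles are mapped back to 3-space, negatives are
#' clipped, and the results renormalized. The vector with the larger
#' red-channel absorbance is labeled hematoxylin (H absorbs red more
#' strongly than E).
#'
#' @param od `H x W x 3` optical-density array (see [rgb_to_od()]).
#' @param mask optional logical `H x W` tissue mask; `NULL` uses all pixels.
#' @param beta OD-norm threshold for a pixel to count as stained
#'   tissue (default 0.15).
#' @param alpha robust angular percentile in percent (default 1).
#' @return a validated stain matrix (see [stain_matrix()]).
#' @section Errors: fewer than 100 qualifying pixels raises an
#'   insufficient-tissue error; an OD cloud of rank < 2 (a single pure
#'   stain) raises a degenerate-stain error.
#' @export
estimate_stain_matrix <- function(od, mask = NULL, beta = 0.15, alpha = 1) {
  x <- od_flat(od)
  if (!is.null(mask)) {
    if (length(mask) * 3L != length(x))
      sn_validation_error("mask dimensions do not match the image")
    x <- x[as.vector(mask), , drop = FALSE]
  }
  x <- x[rowSums(x^2) >= beta^2, , drop = FALSE]
  if (nrow(x) < 100L)
    sn_insufficient_tissue_error(sprintf(
      "only %d pixels exceed the OD threshold (need >= 100)", nrow(x)))

  cv <- stats::cov(x)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] <= max(eg$values[1] * 1e-6, 0))
    sn_degenerate_stain_error("OD covariance has rank < 2 (single stain?)")
  v <- eg$vectors[, 1:2, drop = FALSE]
  # orient the basis so projections land in a contiguous angular range
  if (mean(x %*% v[, 1]) < 0) v[, 1] <- -v[, 1]
  if (stats::median(x %*% v[, 2]) < 0) v[, 2] <- -v[, 2]

  p <- x %*% v
  phi <- atan2(p[, 2], p[, 1])
  q <- stats::quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE)
  back <- function(a) {
    u <- as.vector(v %*% c(cos(a), sin(a)))
    if (sum(u) < 0) u <- -u
    u <- pmax(u, 0)
    u / sqrt(sum(u^2))
  }
  v1 <- back(q[1]); v2 <- back(q[2])
  if (angle_deg(v1, v2) < 1)
    sn_degenerate_stain_error("extreme stain directions nearly coincide")
  if (v1[1] >= v2[1]) stain_matrix(v1, v2) else stain_matrix(v2, v1)
}

# Moore-Penrose pseudoinverse of the 2x3 stain matrix (3x2 result)
stain_pinv <- function(stains) t(stains) %*% solve(stains %*% t(stains))

#' Per-pixel stain concentrations
#'
#' Solves, for every pixel, the least-squares decomposition
#' `OD ~ cH * H + cE * E` of the 3-channel absorbance onto the two
#' stain vectors. The default solver is the pseudoinverse with
#' negative amounts clipped to zero; `method = "nnls"` solves the
#' exact two-variable non-negative least-squares problem instead
#' (checks the active-set candidates and keeps the best feasible one).
#'
#' @inheritParams estimate_stain_matrix
#' @param stains a `2 x 3` stain matrix.
#' @param method `"pinv"` (default) or `"nnls"`.
#' @return `H x W x 2` array of non-negative stain amounts (OD units),
#'   channel 1 = H, channel 2 = E.
#' @export
compute_concentrations <- function(od, stains, method = c("pinv", "nnls")) {
  method <- match.arg(method)
  if (!is_stain_matrix(stains)) sn_validation_error("invalid stain matrix")
  x <- od_flat(od)
  cc <- x %*% stain_pinv(stains)
  if (method == "nnls") {
    bad <- which(cc[, 1] < 0 | cc[, 2] < 0)
    if (length(bad)) {
      xb <- x[bad, , drop = FALSE]
      # single-stain candidates: projection onto each unit stain vector
      c1 <- pmax(xb %*% stains[1, ], 0)
      c2 <- pmax(xb %*% stains[2, ], 0)
      r1 <- rowSums((xb - c1 %*% t(stains[1, ]))^2)
      r2 <- rowSums((xb - c2 %*% t(stains[2, ]))^2)
      use1 <- r1 <= r2
      cc[bad, 1] <- ifelse(use1, c1, 0)
      cc[bad, 2] <- ifelse(use1, 0, c2)
    }
  }
  cc <- pmax(cc, 0)
  array(cc, c(dim(od)[1:2], 2L))
}

#' Reconstruct an RGB image from stain concentrations
#'
#' Forward Beer-Lambert rendering: per-pixel absorbance
#' `OD = cH * H + cE * E`, transmitted through the given illuminant
#' (see [od_to_rgb()]). Increasing either stain amount at a pixel can
#' only darken it.
#'
#' @param conc `H x W x 2` non-negative stain amounts.
#' @inheritParams compute_concentrations
#' @inheritParams rgb_to_od
#' @return RGB array in `[0, 255]`.
#' @export
reconstruct <- function(conc, stains, illuminant = c(255, 255, 255)) {
  if (!is.array(conc) || length(dim(conc)) != 3L || dim(conc)[3] != 2L)
    sn_format_error("conc must be an H x W x 2 array")
  if (anyNA(conc) || min(conc) < 0)
    sn_domain_error("stain concentrations must be non-negative")
  if (!is_stain_matrix(stains)) sn_validation_error("invalid stain matrix")
  od <- matrix(conc, ncol = 2L) %*% stains
  od_to_rgb(array(od, c(dim(conc)[1:2], 3L)), illuminant)
}
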