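#' Weighted Cohen's kappa for ordinal ratings
#'
#' Chance-corrected agreement between two raters on a fixed ordered
#' category scale. With `k` categories and disagreement weights
#' `w_ij = (i - j)^2 / (k - 1)^2` (quadratic, the default) the
#' statistic is `kappa = 1 - sum(w * O) / sum(w * E)`, where `O` is the
#' observed joint proportion table and `E` the outer product of the
#' marginals. The category scale is fixed in advance (default Grade
#' Groups 0-5) even when some categories are unobserved, so the
#' quadratic weights encode the full ordinal distance.
#'
#' @param a,b equal-length rating vectors; every value must be in
#'   `categories`.
#' @param categories ordered category scale (default `0:5`).
#' @param weighting `"quadratic"` (default) or `"linear"`.
#' @return the kappa coefficient (at most 1).
#' @section Errors: when the expected disagreement is zero (both
#'   raters stuck on one identical category) kappa is undefined and an
#'   undefined-agreement error is raised rather than a number returned.
#' @examples
#' weighted_kappa(c(0, 0, 1, 2), c(0, 1, 1, 2), categories = 0:2) # 0.8
#' @export
weighted_kappa <- function(a, b, categories = 0:5,
                           weighting = c("quadratic", "linear")) {
  weighting <- match.arg(weighting)
  if (length(a) != length(b))
    sn_validation_error("rating vectors must have equal length")
  if (length(a) < 1) sn_validation_error("need at least one rating pair")
  if (!all(a %in% categories) || !all(b %in% categories))
    sn_validation_error("ratings outside the category scale")
  k <- length(categories)
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  o <- table(fa, fb) / length(a)
  e <- outer(rowSums(o), colSums(o))
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- if (weighting == "quadratic") (d / (k - 1))^2 else d / (k - 1)
  denom <- sum(w * e)
  if (denom <= .Machine$double.eps)
    sn_undefined_agreement_error(
      "no marginal variability: weighted kappa is undefined")
  1 - sum(w * o) / denom
}

#' Paired t-test returning the triple (t, df, p)
#'
#' Thin contract wrapper around [stats::t.test()] with `paired = TRUE`:
#' `t = mean(d) / (sd(d) / sqrt(n))` on the differences `d = x - y`
#' with sample (n-1) standard deviation, `df = n - 1`, two-sided p by
#' default. A zero-variance difference vector (including `x == y`
#' elementwise) is a degenerate design and raises a
#' degenerate-variance error instead of returning `t = Inf`/`NaN`.
#'
#' @param x,y paired measurements, equal length `n >= 2`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with elements `t`, `df`, `p`.
#' @export
paired_t_test <- function(x, y,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y))
    sn_validation_error("paired samples must have equal length")
  if (length(x) < 2) sn_validation_error("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    sn_degenerate_variance_error(
      "differences have zero variance; paired t-test undefined")
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Confusion matrix over a fixed category scale
#'
#' @param a,b equal-length rating vectors (rows index `a`, columns `b`).
#' @param categories fixed ordered scale (default Grade Groups `0:5`).
#' @return integer `k x k` contingency table; entries sum to `n`.
#' @export
confusion_matrix <- function(a, b, categories = 0:5) {
  if (length(a) != length(b))
    sn_validation_error("rating vectors must have equal length")
  bad <- which(!(a %in% categories) | !(b %in% categories))
  if (length(bad))
    sn_validation_error(sprintf(
      "rating outside categories at record %d (a=%s, b=%s)",
      bad[1], a[bad[1]], b[bad[1]]))
  tab <- table(factor(a, levels = categories),
               factor(b, levels = categories))
  m <- matrix(as.integer(tab), length(categories), length(categories),
              dimnames = list(a = categories, b = categories))
  m
}

#' Robust distribution summary with optional threshold fraction
#'
#' Mean, sample standard deviation, median and quartiles (linear
#' interpolation between order statistics), Tukey outliers (beyond
#' 1.5 x IQR from the nearer quartile -- the "+" marks of a boxplot)
#' and, when `threshold` is given, the fraction of values strictly
#' greater than it.
#'
#' @param values numeric vector, `n >= 1`.
#' @param threshold optional cut point (e.g. 90 s for diagnosis times).
#' @return list with `n`, `mean`, `sd`, `median`, `p25`, `p75`,
#'   `outliers`, and `frac_gt_threshold` when `threshold` is supplied.
#' @export
summarize_distribution <- function(values, threshold = NULL) {
  if (length(values) < 1 || anyNA(values))
    sn_validation_error("values must be non-empty and free of NA")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  out <- list(n = length(values), mean = mean(values),
              sd = if (length(values) > 1) stats::sd(values) else NA_real_,
              median = q[2], p25 = q[1], p75 = q[3],
              outliers = values[values < q[1] - 1.5 * iqr |
                                values > q[3] + 1.5 * iqr])
  if (!is.null(threshold))
    out$frac_gt_threshold <- mean(values > threshold)
  out
}
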