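# expected rating distribution of the discretized latent-Gaussian
# ordinal rater: P(rating = r | true grade g) with latent noise tau
rating_probs <- function(g, tau, k = 6L) {
  cuts <- seq(0.5, k - 1.5)                    # thresholds between categories
  p <- diff(c(0, stats::pnorm((cuts - g) / tau), 1))
  p
}

# closed-form expected quadratic weighted kappa between two independent
# re-ratings of the same truth, as a function of latent noise tau
expected_intra_kappa <- function(tau, gg_distribution) {
  k <- length(gg_distribution)
  pm <- t(vapply(seq_len(k) - 1, rating_probs, numeric(k), tau = tau, k = k))
  o <- matrix(0, k, k)
  for (g in seq_len(k))
    o <- o + gg_distribution[g] * (pm[g, ] %o% pm[g, ])
  e <- outer(rowSums(o), colSums(o))
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  w <- (d / (k - 1))^2
  1 - sum(w * o) / sum(w * e)
}

# invert the kappa curve: latent noise achieving a target intra-rater
# quadratic weighted kappa (0 for a target of 1)
calibrate_rater_noise <- function(target, gg_distribution) {
  if (target >= 1) return(0)
  f <- function(tau) expected_intra_kappa(tau, gg_distribution) - target
  stats::uniroot(f, c(1e-4, 25), tol = 1e-8)$root
}

#' Specification of a simulated paired reader study
#'
#' Defines the generative model for a two-pathologist, two-arm
#' (original vs. normalized) paired slide-rating study: per-slide true
#' Grade Group, ordinal GG ratings through a discretized
#' latent-Gaussian rater whose noise is calibrated (closed form + root
#' finding) to a target intra-rater quadratic weighted kappa,
#' clipped-rounded Gaussian quality and confidence scores (1-10), and
#' log-normal diagnosis times with a per-(slide, pathologist)
#' difficulty effect shared across arms.
#'
#' Defaults mirror a 93-slide prostate biopsy study read by two
#' pathologists: quality medians around 6/10 and 5/10 on original
#' slides rising by `quality_shift` when normalized; median times of
#' 72 s and 39.6 s shrinking by `time_ratio`; confidence means 7.0 and
#' 6.2 rising by `confidence_shift` with a thinner lower tail
#' (`confidence_sd_scale`) on normalized slides; intra-rater kappa
#' target 0.89. The true Grade-Group case mix of such studies is not
#' published, so the default is uniform over 0-5 -- a placeholder, not
#' an estimate. Setting `quality_shift = 0`, `time_ratio = 1`,
#' `confidence_shift = 0`, `confidence_sd_scale = 1` yields an exact
#' null study (both arms exchangeable).
#'
#' @param n_slides number of slides (default 93).
#' @param quality_shift additive quality improvement in the normalized
#'   arm (10-point scale).
#' @param time_ratio multiplicative factor on normalized-arm times,
#'   in `(0, 1]`.
#' @param confidence_shift additive confidence improvement in the
#'   normalized arm.
#' @param gg_distribution 6 probabilities (Grade Groups 0-5) summing
#'   to 1.
#' @param intra_rater_kappa_target expected original-vs-normalized
#'   quadratic weighted kappa per pathologist, in `(0, 1]`.
#' @param seed integer; the simulator is a pure function of it.
#' @param quality_baseline,quality_sd original-arm quality score mean
#'   per pathologist and common sd.
#' @param confidence_baseline,confidence_sd confidence score mean and
#'   sd per pathologist (original arm).
#' @param confidence_sd_scale factor on the confidence sd in the
#'   normalized arm (< 1 thins the low-confidence tail).
#' @param time_median_s original-arm median diagnosis time per
#'   pathologist, seconds.
#' @param time_sdlog residual log-scale spread of times.
#' @param time_slide_sdlog sd of the per-(slide, pathologist)
#'   difficulty effect shared by both arms (this is what makes the
#'   design informatively paired).
#' @return a list of class `"reader_study_spec"`.
#' @export
reader_study_spec <- function(n_slides = 93L, quality_shift = 2,
                              time_ratio = 0.85, confidence_shift = 1,
                              gg_distribution = rep(1 / 6, 6),
                              intra_rater_kappa_target = 0.89,
                              seed = 1L,
                              quality_baseline = c(P1 = 6, P2 = 5),
                              quality_sd = 1.5,
                              confidence_baseline = c(P1 = 7.0, P2 = 6.2),
                              confidence_sd = c(P1 = 1.8, P2 = 2.4),
                              confidence_sd_scale = 0.7,
                              time_median_s = c(P1 = 72, P2 = 39.6),
                              time_sdlog = 0.35,
                              time_slide_sdlog = 0.25) {
  if (n_slides < 2) sn_validation_error("n_slides must be at least 2")
  if (length(gg_distribution) != 6 ||
      abs(sum(gg_distribution) - 1) > 1e-9 || any(gg_distribution < 0))
    sn_validation_error("gg_distribution must be 6 probabilities summing to 1")
  if (time_ratio <= 0 || time_ratio > 1)
    sn_validation_error("time_ratio must be in (0, 1]")
  if (intra_rater_kappa_target <= 0 || intra_rater_kappa_target > 1)
    sn_validation_error("intra_rater_kappa_target must be in (0, 1]")
  structure(list(n_slides = as.integer(n_slides),
                 quality_shift = quality_shift, time_ratio = time_ratio,
                 confidence_shift = confidence_shift,
                 gg_distribution = gg_distribution,
                 intra_rater_kappa_target = intra_rater_kappa_target,
                 seed = as.integer(seed),
                 quality_baseline = quality_baseline,
                 quality_sd = quality_sd,
                 confidence_baseline = confidence_baseline,
                 confidence_sd = confidence_sd,
                 confidence_sd_scale = confidence_sd_scale,
                 time_median_s = time_median_s, time_sdlog = time_sdlog,
                 time_slide_sdlog = time_slide_sdlog),
            class = "reader_study_spec")
}

#' Simulate a paired two-pathologist rating table
#'
#' Draws one complete rating table under a [reader_study_spec()]: one
#' record per (slide, pathologist, arm) with quality (1-10), Grade
#' Group (0-5), confidence (1-10) and diagnosis time (seconds).
#' Slide identifiers are kept stable across arms (in a live study they
#' would be re-randomized per arm to blind the readers; the paired
#' analysis needs the linkage, so the table keeps it).
#'
#' @param spec a [reader_study_spec()].
#' @return a `data.frame` with columns `slide_id`, `pathologist`,
#'   `arm`, `quality`, `gg`, `confidence`, `time_s`.
#' @export
simulate_reader_study <- function(spec = reader_study_spec()) {
  if (!inherits(spec, "reader_study_spec"))
    spec <- do.call(reader_study_spec, spec)
  tau <- calibrate_rater_noise(spec$intra_rater_kappa_target,
                               spec$gg_distribution)
  n <- spec$n_slides
  paths <- c("P1", "P2"); arms <- c("original", "normalized")
  with_seed(spec$seed, {
    true_gg <- sample(0:5, n, replace = TRUE, prob = spec$gg_distribution)
    rows <- vector("list", 4L)
    i <- 0L
    for (p in 1:2) {
      diff_sp <- stats::rnorm(n, 0, spec$time_slide_sdlog)
      for (a in 1:2) {
        i <- i + 1L
        norm_arm <- arms[a] == "normalized"
        gg <- if (tau == 0) true_gg else
          clamp(round_half_up(true_gg + stats::rnorm(n, 0, tau)), 0, 5)
        quality <- clamp(round_half_up(stats::rnorm(
          n, spec$quality_baseline[p] + norm_arm * spec$quality_shift,
          spec$quality_sd)), 1, 10)
        csd <- spec$confidence_sd[p] *
          if (norm_arm) spec$confidence_sd_scale else 1
        confidence <- clamp(round_half_up(stats::rnorm(
          n, spec$confidence_baseline[p] + norm_arm * spec$confidence_shift,
          csd)), 1, 10)
        time_s <- spec$time_median_s[p] *
          exp(diff_sp + stats::rnorm(n, 0, spec$time_sdlog)) *
          if (norm_arm) spec$time_ratio else 1
        rows[[i]] <- data.frame(
          slide_id = sprintf("S%03d", seq_len(n)),
          pathologist = paths[p], arm = arms[a],
          quality = as.integer(quality), gg = as.integer(gg),
          confidence = as.integer(confidence),
          time_s = round(time_s, 1),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

ratings_columns <- c("slide_id", "pathologist", "arm", "quality", "gg",
                     "confidence", "time_s")

#' Write / read a rating table as CSV
#'
#' The on-disk schema is a plain CSV with header
#' `slide_id, pathologist, arm, quality, gg, confidence, time_s`.
#'
#' @param records rating `data.frame` (see [simulate_reader_study()]).
#' @param path CSV path.
#' @return `path` (write) or the validated `data.frame` (read).
#' @export
write_ratings <- function(records, path) {
  utils::write.csv(records[, ratings_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) sn_io_error(paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ratings_columns, names(df))
  if (length(missing_cols))
    sn_format_error(paste0("rating CSV is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  df
}
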