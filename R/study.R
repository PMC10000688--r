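#' Run the paired reader-study analysis
#'
#' Aggregates a complete paired rating table (each slide rated by both
#' pathologists in both arms) into the study statistics:
#' \itemize{
#'   \item quadratic weighted Cohen's kappa on Grade Group -- intra-rater
#'     per pathologist (original vs. normalized) and inter-rater per arm
#'     (P1 vs. P2);
#'   \item paired t-tests (original vs. normalized, per pathologist) on
#'     quality, confidence and diagnosis time, at a 5% significance
#'     convention, two-sided;
#'   \item distribution summaries per metric, arm and pathologist, with
#'     the fraction of diagnosis times above 90 s;
#'   \item 6 x 6 Grade-Group confusion matrices for the four rater
#'     comparisons.
#' }
#' No multiple-testing correction is applied across the six tests; the
#' printed report notes this.
#'
#' @param records rating `data.frame` with the columns of
#'   [simulate_reader_study()] (or [read_ratings()]).
#' @param time_threshold_s threshold for the slow-diagnosis fraction
#'   (default 90 s).
#' @return an object of class `"study_result"`.
#' @export
run_study <- function(records, time_threshold_s = 90) {
  missing_cols <- setdiff(ratings_columns, names(records))
  if (length(missing_cols))
    sn_validation_error(paste0("rating table is missing column(s): ",
                               paste(missing_cols, collapse = ", ")))
  slides <- sort(unique(records$slide_id))
  paths <- c("P1", "P2"); arms <- c("original", "normalized")
  want <- expand.grid(slide_id = slides, pathologist = paths, arm = arms,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$slide_id, d$pathologist, d$arm, sep = "|")
  have <- key(records)
  if (anyDuplicated(have))
    sn_validation_error(paste0("duplicate rating cell(s): ",
                               paste(utils::head(have[duplicated(have)], 3),
                                     collapse = "; ")))
  miss <- setdiff(key(want), have)
  if (length(miss))
    sn_validation_error(paste0(
      "incomplete paired design; missing (slide, pathologist, arm) cell(s): ",
      paste(utils::head(miss, 5), collapse = "; "),
      if (length(miss) > 5) sprintf(" ... and %d more", length(miss) - 5)))

  cell <- function(p, a, col) {
    d <- records[records$pathologist == p & records$arm == a, ]
    d[[col]][match(slides, d$slide_id)]
  }
  kappas <- list(
    intra_p1 = weighted_kappa(cell("P1", "original", "gg"),
                              cell("P1", "normalized", "gg")),
    intra_p2 = weighted_kappa(cell("P2", "original", "gg"),
                              cell("P2", "normalized", "gg")),
    inter_original = weighted_kappa(cell("P1", "original", "gg"),
                                    cell("P2", "original", "gg")),
    inter_normalized = weighted_kappa(cell("P1", "normalized", "gg"),
                                      cell("P2", "normalized", "gg")))
  confusion <- list(
    intra_p1 = confusion_matrix(cell("P1", "original", "gg"),
                                cell("P1", "normalized", "gg")),
    intra_p2 = confusion_matrix(cell("P2", "original", "gg"),
                                cell("P2", "normalized", "gg")),
    inter_original = confusion_matrix(cell("P1", "original", "gg"),
                                      cell("P2", "original", "gg")),
    inter_normalized = confusion_matrix(cell("P1", "normalized", "gg"),
                                        cell("P2", "normalized", "gg")))
  metrics <- c("quality", "confidence", "time_s")
  tests <- list(); summaries <- list()
  for (p in paths) {
    tests[[p]] <- list(); summaries[[p]] <- list()
    for (m in metrics) {
      x <- cell(p, "original", m); y <- cell(p, "normalized", m)
      tests[[p]][[m]] <- paired_t_test(x, y)
      thr <- if (m == "time_s") time_threshold_s else NULL
      summaries[[p]][[m]] <- list(
        original = summarize_distribution(x, thr),
        normalized = summarize_distribution(y, thr))
    }
  }
  structure(list(n_slides = length(slides), kappas = kappas,
                 tests = tests, summaries = summaries,
                 confusion = confusion,
                 time_threshold_s = time_threshold_s),
            class = "study_result")
}

fmt_p <- function(p) if (p < 1e-4) "< 0.0001" else sprintf("= %.4f", p)

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Paired reader study: %d slides, 2 pathologists, 2 arms\n",
              x$n_slides))
  cat("\nGrade Group agreement (quadratic weighted Cohen's kappa):\n")
  cat(sprintf("  intra-rater  P1 (orig vs norm): %.4f\n", x$kappas$intra_p1))
  cat(sprintf("  intra-rater  P2 (orig vs norm): %.4f\n", x$kappas$intra_p2))
  cat(sprintf("  inter-rater  original:          %.4f\n",
              x$kappas$inter_original))
  cat(sprintf("  inter-rater  normalized:        %.4f\n",
              x$kappas$inter_normalized))
  for (p in names(x$tests)) {
    cat(sprintf("\n%s, original vs normalized (paired t-test, two-sided):\n", p))
    for (m in names(x$tests[[p]])) {
      tt <- x$tests[[p]][[m]]
      so <- x$summaries[[p]][[m]]$original
      sn <- x$summaries[[p]][[m]]$normalized
      cat(sprintf(
        "  %-10s %6.1f +/- %-5.1f -> %6.1f +/- %-5.1f (median %.1f -> %.1f), t(%d) = %.3f, p %s\n",
        m, so$mean, so$sd, sn$mean, sn$sd, so$median, sn$median,
        tt$df, tt$t, fmt_p(tt$p)))
    }
    to <- x$summaries[[p]]$time_s
    cat(sprintf("  time > %g s: %.0f%% original vs %.0f%% normalized\n",
                x$time_threshold_s, 100 * to$original$frac_gt_threshold,
                100 * to$normalized$frac_gt_threshold))
  }
  cat("\nNote: p-values are unadjusted; no multiple-testing correction",
      "is applied across the six tests.\n")
  invisible(x)
}

#' Tidy per-metric statistics of a study result
#'
#' @param object a `"study_result"`.
#' @param ... unused.
#' @return a `data.frame`, one row per (pathologist, metric, arm).
#' @export
summary.study_result <- function(object, ...) {
  rows <- list()
  for (p in names(object$summaries)) for (m in names(object$summaries[[p]]))
    for (a in c("original", "normalized")) {
      s <- object$summaries[[p]][[m]][[a]]
      tt <- object$tests[[p]][[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        pathologist = p, metric = m, arm = a, n = s$n, mean = s$mean,
        sd = s$sd, median = s$median, p25 = s$p25, p75 = s$p75,
        frac_gt_threshold = if (is.null(s$frac_gt_threshold)) NA_real_
                            else s$frac_gt_threshold,
        t = tt$t, df = tt$df, p_value = tt$p,
        stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a study result to disk
#'
#' Emits `report.txt` (the printed report), `statistics.csv` (the tidy
#' summary) and one `confusion_<comparison>.csv` per Grade-Group
#' confusion matrix.
#'
#' @param result a `"study_result"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(utils::capture.output(print(result)),
             file.path(dir, "report.txt"))
  utils::write.csv(summary(result), file.path(dir, "statistics.csv"),
                   row.names = FALSE)
  for (nm in names(result$confusion))
    utils::write.csv(result$confusion[[nm]],
                     file.path(dir, paste0("confusion_", nm, ".csv")))
  invisible(dir)
}
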