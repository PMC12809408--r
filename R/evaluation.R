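#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' sample outranks a uniformly chosen negative one, with ties counted 1/2.
#'
#' @param scores numeric vector.
#' @param labels binary 0/1 vector; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps all distinct score thresholds; at each, `call = 1` iff
#' `score > threshold`. The curve starts at (0, 0) and ends at (1, 1).
#'
#' @inheritParams auroc
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    call <- scores > t
    c(fpr = sum(call & labels == 0L) / n0, tpr = sum(call & labels == 1L) / n1)
  }, c(fpr = 0, tpr = 0)))
  out <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  if (utils::tail(out$fpr, 1L) < 1 || utils::tail(out$tpr, 1L) < 1) {
    out <- rbind(out, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  out
}

#' Confusion matrix, precision and recall
#'
#' With no predicted positives, precision is undefined; it is reported as 1.0
#' with `zero_positive_flag = TRUE` so the convention stays auditable.
#'
#' @param calls binary 0/1 predictions.
#' @param labels binary 0/1 truth.
#' @return list with `confusion` (tp, fp, fn, tn), `precision`, `recall`,
#'   `zero_positive_flag`.
#' @export
confusion_stats <- function(calls, labels) {
  calls <- as.integer(calls)
  labels <- as.integer(labels)
  if (length(calls) != length(labels)) {
    stop("calls and labels must have equal length")
  }
  tp <- sum(calls == 1L & labels == 1L)
  fp <- sum(calls == 1L & labels == 0L)
  fn <- sum(calls == 0L & labels == 1L)
  tn <- sum(calls == 0L & labels == 0L)
  zero_pos <- (tp + fp) == 0L
  precision <- if (zero_pos) 1.0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0L) NA_real_ else tp / (tp + fn)
  list(confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
       precision = precision, recall = recall,
       zero_positive_flag = zero_pos)
}

#' Calibration curve
#'
#' Equal-width bins on [0, 1]; a score of exactly 1.0 falls in the last bin.
#' Empty bins are omitted.
#'
#' @param scores numeric in [0, 1].
#' @param labels binary 0/1.
#' @param n_bins number of bins (default 10, minimum 2).
#' @return data.frame with `bin_mid`, `mean_score`, `frac_positive`, `n`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10L) {
  if (n_bins < 2L) {
    stop("n_bins must be at least 2")
  }
  if (any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]")
  }
  labels <- as.integer(labels)
  bin <- pmin(floor(scores * n_bins) + 1L, n_bins)
  rows <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin_mid = (b - 0.5) / n_bins,
               mean_score = mean(scores[sel]),
               frac_positive = mean(labels[sel]),
               n = sum(sel))
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control; adjusted values are monotone and
#' returned in the original order. Delegates to `stats::p.adjust` after
#' validating the input range.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Time to peak secretion after a stimulus
#'
#' For a dynamic secretion trace, subtracts the mean over the baseline window
#' from every value, then returns the time from stimulus onset to the maximum
#' baseline-subtracted value within the stimulus window. Ties take the
#' earliest time; a flat trace within the window is flagged.
#'
#' @param times numeric, strictly increasing timepoints (minutes).
#' @param values secretion measurement at each timepoint.
#' @param baseline_window length-2 numeric `(t_start, t_end)` preceding the
#'   stimulus window.
#' @param stimulus_window length-2 numeric `(t_start, t_end)` containing at
#'   least 2 timepoints.
#' @return list with `time_to_peak` (minutes from stimulus onset),
#'   `peak_value` (baseline-subtracted), `flat_flag`.
#' @export
time_to_peak <- function(times, values, baseline_window, stimulus_window) {
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  rng <- range(times)
  win_ok <- function(w) length(w) == 2L && w[1] < w[2] &&
    w[1] >= rng[1] && w[2] <= rng[2]
  if (!win_ok(baseline_window) || !win_ok(stimulus_window)) {
    stop("windows must be ordered pairs within the time range")
  }
  if (baseline_window[2] > stimulus_window[1]) {
    stop("baseline window must precede the stimulus window")
  }
  in_base <- times >= baseline_window[1] & times <= baseline_window[2]
  in_stim <- times >= stimulus_window[1] & times <= stimulus_window[2]
  if (sum(in_stim) < 2L) {
    stop("stimulus window must contain at least 2 timepoints")
  }
  if (!any(in_base)) {
    stop("baseline window contains no timepoints")
  }
  adj <- values - mean(values[in_base])
  st <- times[in_stim]
  sv <- adj[in_stim]
  peak_idx <- which(sv == max(sv))[1L]  # ties -> earliest
  flat <- max(sv) - min(sv) < .Machine$double.eps^0.5
  list(time_to_peak = st[peak_idx] - stimulus_window[1],
       peak_value = sv[peak_idx], flat_flag = flat)
}

#' Full benchmark report for a score vector
#'
#' Bundles ROC/AUROC, the calibration curve, the confusion matrix at the
#' fixed threshold, and (optionally) Pearson R-squared and Spearman rho
#' against an external reference score vector.
#'
#' @param scores SID scores in [0, 1] (or a `sid_result`).
#' @param labels binary 0/1 truth.
#' @param threshold classification threshold (default 0.5, strict `>`).
#' @param reference optional numeric reference scores for the same samples.
#' @param n_bins calibration bins (default 10).
#' @return an `eval_report` list: `auroc`, `roc_points`, `calibration_bins`,
#'   `confusion`, `precision`, `recall`, `score_correlation` (or NULL).
#' @export
benchmark_scores <- function(scores, labels, threshold = 0.5,
                             reference = NULL, n_bins = 10L) {
  if (inherits(scores, "sid_result")) {
    scores <- scores$sid
  }
  labels <- as.integer(labels)
  cs <- confusion_stats(sid_classify(scores, threshold), labels)
  corr <- NULL
  if (!is.null(reference)) {
    if (length(reference) != length(scores)) {
      stop("reference scores must match sample count")
    }
    corr <- list(pearson_r2 = stats::cor(scores, reference)^2,
                 spearman_rho = stats::cor(scores, reference,
                                           method = "spearman"))
  }
  structure(
    list(auroc = auroc(scores, labels),
         roc_points = roc_points(scores, labels),
         calibration_bins = calibration_curve(scores, labels, n_bins),
         confusion = cs$confusion,
         precision = cs$precision,
         recall = cs$recall,
         zero_positive_flag = cs$zero_positive_flag,
         score_correlation = corr),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUROC = %.3f, precision = %.3f, recall = %.3f\n",
              x$auroc, x$precision, x$recall))
  cat(sprintf("  confusion: tp=%d fp=%d fn=%d tn=%d\n",
              x$confusion["tp"], x$confusion["fp"],
              x$confusion["fn"], x$confusion["tn"]))
  invisible(x)
}
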