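#' Kolmogorov-Smirnov distance between counts and a fitted count model
#'
#' Fits a Poisson or negative binomial distribution to integer count data
#' by the method of moments (Poisson: mean; NB: mean and variance) and
#' returns the sup-norm distance D between the empirical CDF and the
#' fitted CDF evaluated on the integers. Smaller D means the family fits
#' better; comparing D under the two families quantifies overdispersion.
#' When the sample variance does not exceed the mean, the negative
#' binomial is not identifiable and the fit falls back to Poisson (with
#' `fallback = TRUE`).
#'
#' @param values Integer count vector, length >= 100.
#' @param family `"poisson"` or `"negative_binomial"`.
#' @return List with `D`, `family` (family actually used), `fallback`,
#'   and the fitted parameters.
#' @export
ks_fit_distance <- function(values, family = c("poisson",
                                               "negative_binomial")) {
  family <- match.arg(family)
  if (length(values) < 100) stop("need at least 100 values")
  m <- mean(values)
  v <- stats::var(values)
  fallback <- FALSE
  if (family == "negative_binomial" && v <= m) {
    family <- "poisson"
    fallback <- TRUE
  }
  ks <- seq(0L, max(values))
  ecdf_k <- cumsum(tabulate(values + 1L, nbins = max(values) + 1L)) /
    length(values)
  if (family == "poisson") {
    fit <- stats::ppois(ks, lambda = m)
    pars <- list(lambda = m)
  } else {
    size <- m^2 / (v - m)
    fit <- stats::pnbinom(ks, mu = m, size = size)
    pars <- list(mu = m, size = size)
  }
  list(D = max(abs(ecdf_k - fit)), family = family, fallback = fallback,
       params = pars)
}

#' Reciprocal overlap of two intervals
#'
#' Computes the overlap fraction of each interval (overlap length divided
#' by its own length) and whether both reach the threshold — the standard
#' matching rule for structural-variant benchmarking. The threshold test
#' is inclusive (a reciprocal overlap of exactly 50% is a match at the
#' default threshold).
#'
#' @param a,b Numeric `c(start, end)`, 0-based half-open, same chromosome.
#' @param threshold Matching threshold (default 0.5).
#' @return List with `frac_a`, `frac_b`, `match`.
#' @export
reciprocal_overlap <- function(a, b, threshold = 0.5) {
  ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  frac_a <- ov / (a[2] - a[1])
  frac_b <- ov / (b[2] - b[1])
  list(frac_a = frac_a, frac_b = frac_b,
       match = frac_a >= threshold && frac_b >= threshold)
}

event_type <- function(df) {
  if (!is.null(df$cn)) ifelse(df$cn < 2, "del", ifelse(df$cn > 2, "dup", "neutral"))
  else if (!is.null(df$state))
    ifelse(df$state %in% c("double_loss", "loss"), "del",
           ifelse(df$state %in% c("gain", "multi_gain"), "dup", "neutral"))
  else rep(NA_character_, nrow(df))
}

#' Score calls against a truth set by reciprocal overlap
#'
#' Matches calls to truth events at >= 50% reciprocal overlap. A truth
#' event counts as one true positive when at least one call matches it;
#' additional calls matching the same event are neither TP nor FP. A call
#' matching no truth event is a false positive. Precision is
#' TP / (TP + FP) (NA when there are no calls), recall (= TPR) is
#' TP / number of truth events, and the F-measure their harmonic mean.
#' Metrics are also broken down by truth-event size class: small
#' (<= 20 kb), medium (20-100 kb), large (> 100 kb).
#'
#' @param calls,truth data.frames with `chrom`, `start`, `end` (bases,
#'   half-open) and optionally `cn`/`state`.
#' @param threshold Reciprocal-overlap threshold.
#' @param require_state_match Additionally require deletion/duplication
#'   direction to agree (uses `cn` or `state` columns).
#' @param size_breaks Size-class boundaries in bp.
#' @return An `overlap_metrics` list: `tp`, `n_fp`, `fn`, `precision`,
#'   `recall`, `tpr`, `f_measure`, `by_size`.
#' @export
score_calls <- function(calls, truth, threshold = 0.5,
                        require_state_match = FALSE,
                        size_breaks = c(20e3, 100e3)) {
  core <- function(calls, truth) {
    n_calls <- nrow(calls)
    n_truth <- nrow(truth)
    call_type <- event_type(calls)
    truth_type <- event_type(truth)
    call_matched <- logical(n_calls)
    truth_matched <- logical(n_truth)
    for (i in seq_len(n_calls)) {
      for (j in seq_len(n_truth)) {
        if (calls$chrom[i] != truth$chrom[j]) next
        if (require_state_match &&
            !is.na(call_type[i]) && !is.na(truth_type[j]) &&
            call_type[i] != truth_type[j]) next
        ro <- reciprocal_overlap(c(calls$start[i], calls$end[i]),
                                 c(truth$start[j], truth$end[j]), threshold)
        if (ro$match) {
          call_matched[i] <- TRUE
          truth_matched[j] <- TRUE
        }
      }
    }
    tp <- sum(truth_matched)
    n_fp <- sum(!call_matched)
    precision <- if (n_calls == 0) NA_real_ else tp / (tp + n_fp)
    recall <- if (n_truth == 0) NA_real_ else tp / n_truth
    f <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0)
      NA_real_ else 2 * precision * recall / (precision + recall)
    list(tp = tp, n_fp = n_fp, fn = n_truth - tp, precision = precision,
         recall = recall, tpr = recall, f_measure = f)
  }
  res <- core(calls, truth)
  size_class <- function(df) {
    sz <- df$end - df$start
    cut(sz, breaks = c(0, size_breaks, Inf),
        labels = c("small", "medium", "large"))
  }
  res$by_size <- lapply(stats::setNames(nm = c("small", "medium", "large")),
                        function(cl) {
                          core(calls[size_class(calls) == cl, , drop = FALSE],
                               truth[size_class(truth) == cl, , drop = FALSE])
                        })
  class(res) <- "overlap_metrics"
  res
}

#' @export
print.overlap_metrics <- function(x, ...) {
  cat(sprintf("overlap_metrics: TP %d, FP %d, FN %d | precision %.3f, recall %.3f, F %.3f\n",
              x$tp, x$n_fp, x$fn, x$precision, x$recall, x$f_measure))
  invisible(x)
}

#' Breakpoint distances between predicted and true events
#'
#' For each truth event, the predicted event minimizing the summed
#' boundary distance is selected and the absolute start and end
#' differences are reported (in the units of the inputs, typically window
#' indices). Events with no prediction on their chromosome get `NA`
#' distances.
#'
#' @param predicted,truth data.frames with `chrom`, `start`, `end` in a
#'   common coordinate unit.
#' @return data.frame with one row per truth event: `d_start`, `d_end`.
#' @export
breakpoint_distance <- function(predicted, truth) {
  out <- data.frame(d_start = rep(NA_real_, nrow(truth)),
                    d_end = rep(NA_real_, nrow(truth)))
  for (j in seq_len(nrow(truth))) {
    cand <- predicted[predicted$chrom == truth$chrom[j], , drop = FALSE]
    if (!nrow(cand)) next
    ds <- abs(cand$start - truth$start[j])
    de <- abs(cand$end - truth$end[j])
    i <- which.min(ds + de)
    out$d_start[j] <- ds[i]
    out$d_end[j] <- de[i]
  }
  out
}

#' Copy-number concordance statistics
#'
#' Pearson correlation, regression slope (predicted on true) and correct
#' classification rate (CCR: fraction of regions with exactly the right
#' integer copy number) between predicted and true copy numbers.
#'
#' @param predicted,true Paired numeric vectors.
#' @return List with `pearson_r`, `slope`, `ccr`, `n`.
#' @export
cn_concordance <- function(predicted, true) {
  stopifnot(length(predicted) == length(true))
  ok <- !is.na(predicted) & !is.na(true)
  p <- predicted[ok]; t <- true[ok]
  n <- length(p)
  r <- if (n < 3 || stats::sd(p) == 0 || stats::sd(t) == 0) NA_real_
  else stats::cor(p, t)
  slope <- if (n < 2 || stats::sd(t) == 0) NA_real_
  else unname(stats::coef(stats::lm(p ~ t))[2])
  list(pearson_r = r, slope = slope, ccr = mean(p == t), n = n)
}

#' Write evaluation metrics as tab-delimited report
#'
#' @param metrics An `overlap_metrics` object.
#' @param path File path.
#' @export
write_metrics <- function(metrics, path) {
  rows <- function(m, class) data.frame(
    class = class, tp = m$tp, fp = m$n_fp, fn = m$fn,
    precision = m$precision, recall = m$recall, f_measure = m$f_measure)
  df <- rbind(rows(metrics, "all"),
              do.call(rbind, Map(rows, metrics$by_size,
                                 names(metrics$by_size))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
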