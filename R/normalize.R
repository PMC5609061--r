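#' Median normalization of a coverage profile for one covariate
#'
#' Corrects GC-content or mappability bias by equalizing the per-bin
#' medians to the genome-wide median: each window value is multiplied by
#' `m / m_bin`, where `m` is the overall median over usable windows and
#' `m_bin` the median of the windows sharing the window's covariate bin
#' (GC percent 0..100, or mappability 0, 0.1, ..., 1).
#'
#' Bins holding fewer than `min_bin_count` windows have unstable medians
#' and borrow the median of the nearest well-populated bin (ties to the
#' lower bin); if no bin is well populated the overall median is used and
#' the values pass through unchanged. Bins whose median is 0 cannot be
#' rescaled; their windows are masked instead of divided.
#'
#' @param profile A [coverage_profile()].
#' @param covariate `"gc"` or `"mappability"`; the corresponding window
#'   annotation must be present.
#' @param min_bin_count Minimum windows per bin for a trusted median.
#' @return A `coverage_profile` with corrected values (and possibly more
#'   masked windows).
#' @export
median_normalize <- function(profile, covariate = c("gc", "mappability"),
                             min_bin_count = 30L) {
  covariate <- match.arg(covariate)
  windows <- profile$windows
  key <- switch(covariate,
                gc = windows$gc,
                mappability = as.integer(round_half_up(windows$map * 10)))
  if (all(is.na(key)))
    stop("windows carry no '", covariate, "' annotation")
  usable <- profile$usable & !is.na(key)
  if (!any(usable)) stop("all windows are masked; cannot normalize")

  m <- stats::median(profile$values[usable])
  bins <- sort(unique(key[usable]))
  bin_median <- vapply(bins, function(b)
    stats::median(profile$values[usable & key == b]), numeric(1))
  bin_count <- vapply(bins, function(b) sum(usable & key == b), integer(1))

  trusted <- bin_count >= min_bin_count
  if (any(trusted)) {
    for (i in which(!trusted)) {
      j <- which(trusted)
      bin_median[i] <- bin_median[j[which.min(abs(bins[j] - bins[i]))]]
    }
  } else {
    bin_median[] <- m
  }

  med_of <- bin_median[match(key, bins)]
  zero_bin <- !is.na(med_of) & med_of == 0
  values <- profile$values
  ok <- usable & !zero_bin
  values[ok] <- profile$values[ok] * m / med_of[ok]
  profile$values <- values
  profile$usable <- ok
  profile
}

#' Normalize a profile to the two-copy scale
#'
#' The full single-sample ("nocontrol") normalization: median-normalize for
#' GC content, then for mappability, rescale so the genome-wide median over
#' usable windows equals 2 (two copies), and log2-transform the halved
#' values so 0 corresponds to the diploid state. Windows with value <= 0 or
#' unusable annotation are masked; their coordinates are preserved so
#' downstream segments can span them.
#'
#' @inheritParams median_normalize
#' @return A `normalized_profile` with fields `norm_values` (two-copy
#'   scale), `log2_values`, `usable` and `windows`.
#' @export
normalize_two_copy <- function(profile, min_bin_count = 30L) {
  corr <- median_normalize(profile, "gc", min_bin_count = min_bin_count)
  corr <- median_normalize(corr, "mappability", min_bin_count = min_bin_count)
  usable <- corr$usable & corr$values > 0
  if (!any(usable)) stop("all windows are masked; cannot normalize")
  scale <- 2 / stats::median(corr$values[usable])
  norm <- corr$values * scale
  log2v <- rep(NA_real_, length(norm))
  log2v[usable] <- log2(norm[usable] / 2)
  structure(list(sample_id = corr$sample_id, windows = corr$windows,
                 norm_values = norm, log2_values = log2v, usable = usable),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf(
    "normalized_profile '%s': %d windows (%d usable), median CN %.2f\n",
    x$sample_id, length(x$norm_values), sum(x$usable),
    stats::median(x$norm_values[x$usable])))
  invisible(x)
}

#' Paired test/control log2-ratio signal
#'
#' Forms the per-window log2 ratio between a bias-corrected test and
#' control sample on the same grid (tumor/normal design). Each sample is
#' corrected independently before the ratio is taken. Windows where either
#' sample is masked, or where the control (or test) value is <= 0, are
#' masked.
#'
#' @param test,control Two [normalize_two_copy()] results, or raw
#'   [coverage_profile()]s (then each is normalized first).
#' @param min_bin_count Passed to [normalize_two_copy()] when raw profiles
#'   are supplied.
#' @return A `normalized_profile` whose `log2_values` are the paired
#'   ratios; `norm_values` is the ratio on the two-copy scale
#'   (`2 * test / control`).
#' @export
paired_log2 <- function(test, control, min_bin_count = 30L) {
  if (inherits(test, "coverage_profile"))
    test <- normalize_two_copy(test, min_bin_count = min_bin_count)
  if (inherits(control, "coverage_profile"))
    control <- normalize_two_copy(control, min_bin_count = min_bin_count)
  if (length(test$norm_values) != length(control$norm_values) ||
      !all(test$windows$start == control$windows$start) ||
      !all(test$windows$chrom == control$windows$chrom))
    stop("test and control are not on the same window grid")
  usable <- test$usable & control$usable &
    control$norm_values > 0 & test$norm_values > 0
  ratio <- rep(NA_real_, length(test$norm_values))
  ratio[usable] <- test$norm_values[usable] / control$norm_values[usable]
  log2v <- rep(NA_real_, length(ratio))
  log2v[usable] <- log2(ratio[usable])
  structure(list(sample_id = paste0(test$sample_id, "_vs_",
                                    control$sample_id),
                 windows = test$windows,
                 norm_values = 2 * ratio, log2_values = log2v,
                 usable = usable),
            class = "normalized_profile")
}

#' Pool control samples by window-wise summation
#'
#' The pooled-control design compares a test sample against the sum of the
#' read counts of several controls in each window; downstream analysis is
#' identical to the paired design against the pooled profile.
#'
#' @param controls Non-empty list of [coverage_profile()]s on one grid.
#' @return A `coverage_profile` holding the window-wise sums.
#' @export
pool_controls <- function(controls) {
  if (!length(controls)) stop("'controls' must contain at least one profile")
  ref <- controls[[1]]
  values <- ref$values
  usable <- ref$usable
  for (p in controls[-1]) {
    if (length(p$values) != length(values) ||
        !all(p$windows$start == ref$windows$start) ||
        !all(p$windows$chrom == ref$windows$chrom))
      stop("control profiles are not on the same window grid")
    values <- values + p$values
    usable <- usable & p$usable
  }
  coverage_profile(values, ref$windows,
                   sample_id = paste0("pool_of_", length(controls)),
                   mode = ref$mode, mq_threshold = ref$mq_threshold,
                   usable = usable)
}

#' Write a normalized profile as a per-window table
#'
#' Extends the coverage table with `norm`, `log2` and `usable` columns.
#'
#' @param profile A `normalized_profile`.
#' @param path File path.
#' @export
write_normalized <- function(profile, path) {
  df <- data.frame(chrom = profile$windows$chrom,
                   start = profile$windows$start,
                   end = profile$windows$end,
                   norm = profile$norm_values,
                   log2 = profile$log2_values,
                   usable = profile$usable)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
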