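#' Per-window coverage profiles
#'
#' A `coverage_profile` holds one raw per-window signal for one sample:
#' read counts (`mode = "rc"`, short reads — each read increments the window
#' containing its leftmost mapping position) or mean depth of coverage
#' (`mode = "doc"`, long reads — mean per-base aligned depth over the
#' window). Reads failing the filters (unmapped, secondary, supplementary,
#' duplicate, or mapping quality <= `mq_threshold`) are ignored.
#'
#' @param values Numeric vector, one value per window.
#' @param windows The `window_grid` the values refer to.
#' @param sample_id Sample label.
#' @param mode `"rc"` or `"doc"`.
#' @param mq_threshold Mapping-quality threshold used (reads with
#'   MQ <= threshold were discarded).
#' @param usable Optional logical mask; defaults to the grid's mask.
#' @return A `coverage_profile` object.
#' @export
coverage_profile <- function(values, windows, sample_id = "sample",
                             mode = c("rc", "doc"), mq_threshold = 10L,
                             usable = NULL) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) != nrow(windows))
    stop("length(values) must equal the number of windows")
  if (any(!is.finite(values)) || any(values < 0))
    stop("coverage values must be finite and >= 0")
  if (mode == "rc" && any(values != floor(values)))
    stop("read counts must be integers")
  if (is.null(usable)) usable <- windows$usable
  structure(list(sample_id = sample_id, windows = windows, values = values,
                 mode = mode, mq_threshold = as.integer(mq_threshold),
                 usable = usable),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage_profile '%s' (%s): %d windows, total %.0f, mean %.2f\n",
              x$sample_id, x$mode, length(x$values), sum(x$values),
              mean(x$values)))
  invisible(x)
}

bam_flag_filter <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE,
                         isDuplicate = FALSE)
}

check_bam_chroms <- function(bam, windows) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  extra <- setdiff(names(hdr), unique(windows$chrom))
  if (length(extra))
    warning("alignments on chromosomes absent from the window grid are ",
            "skipped: ", paste(extra, collapse = ", "))
  invisible(hdr)
}

#' Count reads per window (RC signal)
#'
#' Each primary, mapped, non-duplicate alignment with mapping quality
#' strictly greater than `mq_threshold` is assigned to the single window
#' containing its leftmost mapping position.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param windows A `window_grid`.
#' @param mq_threshold Discard reads with MQ <= this value (default 10).
#' @param sample_id Sample label; defaults to the BAM basename.
#' @return A `coverage_profile` with `mode = "rc"`.
#' @export
count_reads <- function(bam, windows, mq_threshold = 10L,
                        sample_id = sub("\\.bam$", "", basename(bam))) {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for ", bam)
  check_bam_chroms(bam, windows)
  param <- Rsamtools::ScanBamParam(flag = bam_flag_filter(),
                                   what = c("rname", "pos"),
                                   mapqFilter = as.integer(mq_threshold) + 1L)
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  values <- integer(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    sel <- which(windows$chrom == chrom)
    keep <- which(as.character(rec$rname) == chrom)
    if (!length(keep)) next
    # windows are consecutive within a chromosome: locate by start offset
    idx <- findInterval(rec$pos[keep] - 1L, windows$start[sel])
    idx <- idx[idx >= 1L & (rec$pos[keep] - 1L) < windows$end[sel[length(sel)]]]
    tab <- tabulate(idx, nbins = length(sel))
    values[sel] <- tab
  }
  coverage_profile(values, windows, sample_id = sample_id, mode = "rc",
                   mq_threshold = mq_threshold)
}

#' Mean depth of coverage per window (DOC signal)
#'
#' Per-base aligned depth averaged over the window; intended for reads
#' longer than the window (third-generation data), where counting read
#' starts under-represents throughput. A read spanning several windows
#' contributes to each in proportion to its overlap. Aligned bases are the
#' reference positions covered by M/=/X CIGAR operations; deletions (D) in
#' the read do not contribute.
#'
#' @inheritParams count_reads
#' @return A `coverage_profile` with `mode = "doc"`.
#' @export
mean_depth <- function(bam, windows, mq_threshold = 10L,
                       sample_id = sub("\\.bam$", "", basename(bam))) {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for ", bam)
  check_bam_chroms(bam, windows)
  param <- Rsamtools::ScanBamParam(flag = bam_flag_filter(),
                                   mapqFilter = as.integer(mq_threshold) + 1L)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  covered <- GenomicAlignments::grglist(aln, drop.D.ranges = TRUE)
  cov <- GenomicRanges::coverage(unlist(covered))
  values <- numeric(nrow(windows))
  for (chrom in unique(windows$chrom)) {
    if (!chrom %in% names(cov)) next
    sel <- which(windows$chrom == chrom)
    v <- IRanges::Views(cov[[chrom]],
                        start = windows$start[sel] + 1L,
                        end = pmin(windows$end[sel], length(cov[[chrom]])))
    values[sel] <- IRanges::viewSums(v) / (windows$end[sel] - windows$start[sel])
  }
  coverage_profile(values, windows, sample_id = sample_id, mode = "doc",
                   mq_threshold = mq_threshold)
}

#' Write / read a per-window coverage table
#'
#' Tab-delimited `chrom start end value`, 0-based half-open; round-trips a
#' `coverage_profile` against its window grid.
#'
#' @param profile A `coverage_profile`.
#' @param path File path.
#' @param windows `window_grid` to attach on read.
#' @inheritParams coverage_profile
#' @export
write_coverage <- function(profile, path) {
  df <- data.frame(chrom = profile$windows$chrom,
                   start = profile$windows$start,
                   end = profile$windows$end,
                   value = profile$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path, windows, sample_id = "sample",
                          mode = c("rc", "doc"), mq_threshold = 10L) {
  mode <- match.arg(mode)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (nrow(df) != nrow(windows) ||
      !all(df$chrom == windows$chrom & df$start == windows$start))
    stop("coverage table does not match the window grid")
  coverage_profile(df$value, windows, sample_id = sample_id, mode = mode,
                   mq_threshold = mq_threshold)
}
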