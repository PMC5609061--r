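#' Tile a genome into consecutive non-overlapping windows
#'
#' Builds the window grid on which all read-depth signals are computed.
#' Windows are consecutive, non-overlapping and cover every base of each
#' chromosome exactly once; the last window of a chromosome may be shorter
#' than `window_size`. Coordinates are 0-based half-open throughout the
#' package (BED convention); VCF output converts to 1-based.
#'
#' A trailing short window is kept but marked unusable for normalization
#' when it is shorter than half of `window_size`, so that a systematically
#' low count in the final window cannot distort bin medians.
#'
#' @param chrom_lengths Named integer/numeric vector of chromosome lengths
#'   in bp.
#' @param window_size Window size in bp; must be >= 50.
#' @return A `window_grid` data.frame with columns `chrom`, `start`, `end`,
#'   `gc` (integer percent, `NA` until annotated), `map` (mappability bin,
#'   `NA` until annotated) and `usable`.
#' @examples
#' build_windows(c(chr1 = 250), window_size = 100)
#' @export
build_windows <- function(chrom_lengths, window_size) {
  window_size <- as.integer(window_size)
  if (length(window_size) != 1L || is.na(window_size) || window_size < 50L)
    stop("'window_size' must be a single integer >= 50")
  if (length(chrom_lengths) == 0L || is.null(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths))))
    stop("'chrom_lengths' must be a non-empty named vector")
  if (any(chrom_lengths < 1))
    stop("chromosome lengths must be >= 1")

  pieces <- lapply(names(chrom_lengths), function(chrom) {
    len <- as.numeric(chrom_lengths[[chrom]])
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    data.frame(chrom = chrom, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  win <- do.call(rbind, pieces)
  win$gc <- NA_integer_
  win$map <- NA_real_
  # short trailing windows below 50% of window_size are excluded from
  # normalization (usable = FALSE) but keep their coordinates
  win$usable <- (win$end - win$start) >= window_size / 2
  attr(win, "window_size") <- window_size
  class(win) <- c("window_grid", "data.frame")
  win
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows of %d bp on %d chromosome(s)\n",
              nrow(x), attr(x, "window_size"),
              length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# round half away from zero (base round() is round-half-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Annotate windows with GC content percent
#'
#' GC percent of a window is `100 * (#G + #C) / (#A + #C + #G + #T)` rounded
#' half away from zero to an integer bin in 0..100. Ambiguous bases (N and
#' other IUPAC codes) are excluded from numerator and denominator; a window
#' with no unambiguous base gets `gc = NA` and is flagged unusable.
#'
#' @param windows A `window_grid`.
#' @param reference Path to an indexed FASTA file, an [Rsamtools::FaFile],
#'   or a named [Biostrings::DNAStringSet] covering all windows.
#' @return `windows` with the `gc` column filled.
#' @export
annotate_gc <- function(windows, reference) {
  seqs <- window_sequences(windows, reference)
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- rowSums(freq[, c("G", "C"), drop = FALSE])
  windows$gc <- ifelse(acgt > 0L,
                       as.integer(round_half_up(100 * gc / acgt)),
                       NA_integer_)
  windows$usable <- windows$usable & !is.na(windows$gc)
  windows
}

window_sequences <- function(windows, reference) {
  gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1L, end = windows$end))
  if (is.character(reference))
    reference <- Rsamtools::FaFile(reference)
  if (methods::is(reference, "FaFile")) {
    lens <- Rsamtools::seqinfo(reference)
    bad <- !(windows$chrom %in% GenomeInfoDb::seqnames(lens))
    if (any(bad))
      stop("windows on chromosomes absent from the reference: ",
           paste(unique(windows$chrom[bad]), collapse = ", "))
    return(Rsamtools::scanFa(reference, gr))
  }
  if (methods::is(reference, "DNAStringSet")) {
    bad <- !(windows$chrom %in% names(reference))
    if (any(bad))
      stop("windows on chromosomes absent from the reference: ",
           paste(unique(windows$chrom[bad]), collapse = ", "))
    if (any(windows$end > Biostrings::width(reference)[
          match(windows$chrom, names(reference))]))
      stop("window extends beyond the reference sequence")
    return(Biostrings::DNAStringSet(reference[gr]))
  }
  stop("'reference' must be a FASTA path, FaFile or DNAStringSet")
}

#' Annotate windows with mappability bins
#'
#' Mappability is the inverse of the number of genomic locations a sequence
#' originating at a position maps to (1 = unique). The per-window score is
#' the mean of the track value over the window's bases, with positions
#' missing from the track counted as 0 (unmappable), rounded to the nearest
#' 0.1 bin (half up), giving bins 0.0, 0.1, ..., 1.0.
#'
#' @param windows A `window_grid`.
#' @param track Path to a bedGraph file (0-based half-open), or a data.frame
#'   with columns `chrom`, `start`, `end`, `value`.
#' @return `windows` with the `map` column filled.
#' @export
annotate_mappability <- function(windows, track) {
  if (is.character(track)) {
    gr <- rtracklayer::import(track, format = "bedGraph")
    track <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        value = gr$score,
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (any(track$value < 0 | track$value > 1))
    stop("mappability track values must lie in [0, 1]")

  win_gr <- GenomicRanges::GRanges(
    windows$chrom, IRanges::IRanges(windows$start + 1L, windows$end))
  trk_gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1L, track$end))
  hits <- GenomicRanges::findOverlaps(win_gr, trk_gr)
  ov <- GenomicRanges::pintersect(win_gr[S4Vectors::queryHits(hits)],
                                  trk_gr[S4Vectors::subjectHits(hits)])
  wsum <- rep(0, nrow(windows))
  contrib <- GenomicRanges::width(ov) * track$value[S4Vectors::subjectHits(hits)]
  agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
  wsum[as.integer(names(agg))] <- as.numeric(agg)
  mean_map <- wsum / (windows$end - windows$start)
  windows$map <- bin_mappability(mean_map)
  windows
}

#' Round mappability scores to 0.1 bins
#'
#' @param x Numeric vector in \[0, 1\].
#' @return `x` rounded half-up to the nearest multiple of 0.1.
#' @export
bin_mappability <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("mappability values must lie in [0, 1]")
  round_half_up(x * 10) / 10
}

#' Write / read a window annotation table
#'
#' Tab-delimited with header `chrom start end gc map`; coordinates 0-based
#' half-open. On read, usability is re-derived (short trailing windows and
#' all-N windows).
#'
#' @param windows A `window_grid`.
#' @param path Output file path.
#' @return `write_windows` returns `path` invisibly; `read_windows` returns
#'   a `window_grid`.
#' @export
write_windows <- function(windows, path) {
  utils::write.table(
    as.data.frame(windows)[, c("chrom", "start", "end", "gc", "map")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  win <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(win)))
  if (is.null(win$gc)) win$gc <- NA_integer_
  if (is.null(win$map)) win$map <- NA_real_
  widths <- win$end - win$start
  window_size <- as.integer(max(widths))
  win$usable <- widths >= window_size / 2 & !is.na(win$gc)
  attr(win, "window_size") <- window_size
  class(win) <- c("window_grid", "data.frame")
  win
}
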