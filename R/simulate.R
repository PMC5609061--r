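#' Describe the ground truth of a simulated coverage profile
#'
#' Holds the embedded copy-number events and the sampling model for a
#' simulated sample. The expected read count of a two-copy window is
#' `coverage_x * window_size / read_length` (e.g. 30 for a 30x experiment
#' with 100 bp windows and 100 bp reads); counts are drawn from a
#' negative binomial with variance `phi * mean`, reproducing the
#' overdispersion (index of dispersion > 1) of real whole-genome
#' read-count data.
#'
#' @param events data.frame with columns `chrom`, `start_window`,
#'   `end_window` (inclusive window indices) and `cn` (integer 0..6, != 2),
#'   non-overlapping; may have zero rows.
#' @param coverage_x Nominal sequencing coverage.
#' @param window_size Window size in bp.
#' @param read_length Read length in bp used to convert coverage to an
#'   expected count (default 100).
#' @param phi Index of dispersion (variance / mean) of the counts; > 1
#'   gives a negative binomial, `phi = 1` the Poisson limit. Default 3.
#' @param seed Optional integer seed for reproducibility.
#' @return A `sim_truth` object; `base_mean` is the two-copy expectation.
#' @export
sim_truth <- function(events, coverage_x = 30, window_size = 100,
                      read_length = 100, phi = 3, seed = NULL) {
  if (nrow(events)) {
    stopifnot(all(events$cn %in% c(0:1, 3:6)),
              all(events$end_window >= events$start_window))
  }
  base_mean <- coverage_x * window_size / read_length
  structure(list(events = events, base_mean = base_mean, phi = phi,
                 coverage_x = coverage_x, window_size = window_size,
                 read_length = read_length, seed = seed),
            class = "sim_truth")
}

truth_cn_per_window <- function(truth, n_windows, chrom = NULL) {
  cn <- rep(2L, n_windows)
  ev <- truth$events
  if (!is.null(chrom) && nrow(ev)) ev <- ev[ev$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(ev)))
    cn[ev$start_window[i]:ev$end_window[i]] <- ev$cn[i]
  cn
}

#' Default multiplicative GC bias
#'
#' Unimodal factor peaking at 45% GC and falling to 60% of the maximum at
#' both extremes, emulating the empirical pattern that read counts are
#' highest at intermediate GC content and depressed at both tails.
#'
#' @param gc Integer GC percent vector (0..100).
#' @return Multiplicative bias factors in \[0.6, 1\].
#' @export
default_gc_bias <- function(gc) {
  d <- abs(gc - 45) / ifelse(gc < 45, 45, 55)
  1 - 0.4 * d^2
}

#' Default multiplicative mappability bias
#'
#' Linearly depressed coverage in poorly mappable windows.
#'
#' @param map Mappability bins in \[0, 1\].
#' @return Multiplicative bias factors in \[0.5, 1\].
#' @export
default_map_bias <- function(map) 0.5 + 0.5 * map

#' Simulate a per-window read-count profile
#'
#' Draws window counts from a negative binomial with mean
#' `base_mean * cn/2 * gc_bias(gc) * map_bias(map)` and variance
#' `phi * mean`. Double-loss windows (CN 0) use a floor of 0.1 copies so
#' their expectation stays positive (residual mis-mapping). `phi = 1`
#' falls back to Poisson sampling.
#'
#' @param windows A `window_grid` (its `gc`/`map` annotations feed the
#'   bias functions; unannotated windows get gc 45 / map 1).
#' @param truth A [sim_truth()].
#' @param gc_bias,map_bias Functions mapping gc percent / mappability bin
#'   to a positive factor, or `NULL` for no bias.
#' @param sample_id Sample label.
#' @return A `coverage_profile` with `mode = "rc"`.
#' @export
simulate_rc <- function(windows, truth, gc_bias = NULL, map_bias = NULL,
                        sample_id = "sim") {
  if (!is.null(truth$seed)) set.seed(truth$seed)
  n <- nrow(windows)
  gc <- ifelse(is.na(windows$gc), 45L, windows$gc)
  map <- ifelse(is.na(windows$map), 1, windows$map)
  cn <- numeric(n)
  for (chrom in unique(windows$chrom)) {
    sel <- which(windows$chrom == chrom)
    cn[sel] <- truth_cn_per_window(truth, length(sel), chrom = chrom)
  }
  gf <- if (is.null(gc_bias)) rep(1, n) else gc_bias(gc)
  mf <- if (is.null(map_bias)) rep(1, n) else map_bias(map)
  if (any(gf <= 0) || any(mf <= 0)) stop("bias factors must be > 0")
  mu <- truth$base_mean * pmax(cn, 0.1) / 2 * gf * mf
  if (any(mu <= 0)) stop("non-positive simulated means")
  values <- if (truth$phi <= 1) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = mu / (truth$phi - 1))
  coverage_profile(values, windows, sample_id = sample_id, mode = "rc")
}

#' Simulate one synthetic chromosome with a single embedded event
#'
#' Builds a chromosome of `n_windows` windows (default 1000) containing
#' one deletion or duplication of `event_size` consecutive windows placed
#' uniformly at random, the remainder being two-copy, and draws the
#' counts with [simulate_rc()]. This is the unit of the resolution
#' benchmarks: the caller is scored by whether it recovers the event at
#' 50% reciprocal overlap.
#'
#' @param event_size Number of consecutive windows in the event (N); must
#'   be <= `n_windows / 2`.
#' @param event_cn Integer copy number of the event (0..6, not 2).
#' @param n_windows Windows per chromosome.
#' @param coverage_x,window_size,read_length,phi,seed See [sim_truth()].
#' @param gc_bias,map_bias See [simulate_rc()]; default flat.
#' @param chrom Chromosome name.
#' @return A list with `profile` (`coverage_profile`), `truth`
#'   (`sim_truth`) and `windows`.
#' @export
make_synthetic_chromosome <- function(event_size, event_cn,
                                      n_windows = 1000L, coverage_x = 30,
                                      window_size = 100L, read_length = 100,
                                      phi = 3, seed = NULL,
                                      gc_bias = NULL, map_bias = NULL,
                                      chrom = "chrS") {
  if (event_size < 1 || event_size > n_windows / 2)
    stop("'event_size' must lie in [1, n_windows/2]")
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(n_windows - event_size + 1L, 1L)
  events <- data.frame(chrom = chrom, start_window = start,
                       end_window = start + event_size - 1L,
                       cn = as.integer(event_cn), stringsAsFactors = FALSE)
  truth <- sim_truth(events, coverage_x = coverage_x,
                     window_size = window_size, read_length = read_length,
                     phi = phi, seed = NULL)
  lengths <- stats::setNames(n_windows * window_size, chrom)
  windows <- build_windows(lengths, window_size)
  windows$gc <- 45L
  windows$map <- 1
  profile <- simulate_rc(windows, truth, gc_bias = gc_bias,
                         map_bias = map_bias)
  list(profile = profile, truth = truth, windows = windows)
}

#' Median two-copy-normalized signal of simulated regions
#'
#' Simulates regions of given copy numbers (each of `n_windows_per_region`
#' windows) embedded in a two-copy background, normalizes the whole
#' profile to the two-copy scale, and returns the median normalized value
#' of each region. Supports threshold-based detection analyses (a
#' deletion is recovered when its median is <= 1.5, a duplication when it
#' is >= 2.5) and copy-number regression.
#'
#' @param region_cns Integer vector of region copy numbers (0..6).
#' @param n_windows_per_region Windows per region.
#' @param coverage_x,window_size,read_length,phi,seed See [sim_truth()].
#' @param n_background Two-copy background windows; default three times
#'   the total event windows (and at least 2000), so the genome-wide
#'   median sits firmly on the diploid level as in a real genome.
#' @return data.frame with `cn` and `median_norm` per region.
#' @export
simulate_region_medians <- function(region_cns, n_windows_per_region,
                                    coverage_x = 30, window_size = 100L,
                                    read_length = 100, phi = 3,
                                    n_background = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region_cns <- as.integer(region_cns)
  n_reg <- length(region_cns)
  if (is.null(n_background))
    n_background <- max(2000L, 3L * n_reg * n_windows_per_region)
  n_total <- n_background + n_reg * n_windows_per_region
  starts <- n_background + (seq_len(n_reg) - 1L) * n_windows_per_region + 1L
  ev <- data.frame(chrom = "chrS", start_window = starts,
                   end_window = starts + n_windows_per_region - 1L,
                   cn = region_cns, stringsAsFactors = FALSE)
  # CN-2 "regions" behave like background by construction
  truth <- sim_truth(ev[ev$cn != 2L, , drop = FALSE], coverage_x = coverage_x,
                     window_size = window_size, read_length = read_length,
                     phi = phi, seed = NULL)
  windows <- build_windows(stats::setNames(n_total * window_size, "chrS"),
                           window_size)
  windows$gc <- 45L
  windows$map <- 1
  profile <- simulate_rc(windows, truth)
  norm <- normalize_two_copy(profile)
  med <- vapply(seq_len(n_reg), function(i) {
    sel <- ev$start_window[i]:ev$end_window[i]
    stats::median(norm$norm_values[sel])
  }, numeric(1))
  data.frame(cn = region_cns, median_norm = med)
}

#' Write / read a truth BED file
#'
#' BED-like `chrom start end cn` table (0-based half-open, base
#' coordinates) describing simulated events.
#'
#' @param truth A `sim_truth`.
#' @param windows The `window_grid` used for simulation.
#' @param path File path.
#' @export
write_truth_bed <- function(truth, windows, path) {
  ev <- truth$events
  rows <- lapply(seq_len(nrow(ev)), function(i) {
    sel <- which(windows$chrom == ev$chrom[i])
    data.frame(chrom = ev$chrom[i],
               start = windows$start[sel[ev$start_window[i]]],
               end = windows$end[sel[ev$end_window[i]]],
               cn = ev$cn[i])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_bed
#' @param path File path.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file must have at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "cn"
  df
}

#' Write a SAM fixture for alignment-level tests
#'
#' Emits a minimal SAM file (header plus one line per read) that can be
#' converted to an indexed BAM with [Rsamtools::asBam()]. Intended for
#' small synthetic fixtures exercising the read-counting code.
#'
#' @param reads data.frame with columns `chrom`, `pos` (1-based leftmost),
#'   `mapq`, `cigar`, and optionally `flag` (default 0) and `seq`.
#' @param chrom_lengths Named vector of chromosome lengths for the header.
#' @param path Output path (should end in `.sam`).
#' @export
write_sam_fixture <- function(reads, chrom_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (chrom in names(chrom_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom,
                       as.integer(chrom_lengths[[chrom]])), con)
  flag <- if (is.null(reads$flag)) rep(0L, nrow(reads)) else reads$flag
  o <- order(match(reads$chrom, names(chrom_lengths)), reads$pos)
  for (i in o) {
    len <- sum(as.integer(
      regmatches(reads$cigar[i],
                 gregexpr("[0-9]+(?=[MIS=X])", reads$cigar[i], perl = TRUE))[[1]]))
    seq <- if (is.null(reads$seq)) strrep("A", len) else reads$seq[i]
    writeLines(sprintf("r%04d\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       i, flag[i], reads$chrom[i], reads$pos[i],
                       reads$mapq[i], reads$cigar[i], seq,
                       strrep("I", nchar(seq))), con)
  }
  invisible(path)
}
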