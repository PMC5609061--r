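#' Analysis run configuration
#'
#' Bundles the options of a full analysis run in one validated object.
#' Three experimental designs are supported: `"nocontrol"` (single sample
#' normalized to two copies — population/germline studies), `"paired"`
#' (log2 ratio of a test against its matched control — tumor/normal), and
#' `"pooling"` (test against the window-wise sum of a control pool).
#'
#' @param mode One of `"nocontrol"`, `"paired"`, `"pooling"`.
#' @param window_size Window size in bp (>= 50; 100/200/500/1000 are the
#'   recommended values — small windows for high coverage, large ones for
#'   low coverage).
#' @param mq_threshold Mapping-quality threshold for read filtering.
#' @param coverage_mode `"rc"` (read counts) or `"doc"` (depth of
#'   coverage, for long reads).
#' @param eta,omega,K_max,baum_welch Segmentation parameters, see
#'   [estimate_params()].
#' @param cellularity Optional fixed cellularity for calling, or `NULL`
#'   to estimate it on a grid.
#' @param min_bin_count Minimum windows per covariate bin, see
#'   [median_normalize()].
#' @param seed Optional integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("nocontrol", "paired", "pooling"),
                       window_size = 1000L, mq_threshold = 10L,
                       coverage_mode = c("rc", "doc"), eta = 1e-3,
                       omega = 0.1, K_max = 40L, baum_welch = FALSE,
                       cellularity = NULL, min_bin_count = 30L,
                       seed = NULL) {
  mode <- match.arg(mode)
  coverage_mode <- match.arg(coverage_mode)
  if (window_size < 50) stop("'window_size' must be >= 50")
  structure(list(mode = mode, window_size = as.integer(window_size),
                 mq_threshold = as.integer(mq_threshold),
                 coverage_mode = coverage_mode, eta = eta, omega = omega,
                 K_max = as.integer(K_max), baum_welch = baum_welch,
                 cellularity = cellularity,
                 min_bin_count = as.integer(min_bin_count), seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML key-value file
#'
#' Flat key-value file; keys mirror the arguments of [run_config()].
#' Entries in `overrides` (e.g. parsed command-line flags) take
#' precedence over the file.
#'
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Named list of values overriding the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full analysis on coverage profiles
#'
#' Normalization, segmentation and calling for one test sample, following
#' the configured design: `nocontrol` normalizes the test to the two-copy
#' scale (and genotypes absolute copy numbers); `paired` corrects test
#' and control independently and segments their log2 ratio; `pooling`
#' first sums the controls window-wise and proceeds as `paired`.
#'
#' @param test A [coverage_profile()] for the test sample.
#' @param controls A `coverage_profile` (paired) or list of them
#'   (pooling); `NULL` for nocontrol.
#' @param config A [run_config()].
#' @return List with `profile` (`normalized_profile`), `segments`,
#'   `model`, `calls`.
#' @export
run_analysis <- function(test, controls = NULL, config = run_config()) {
  profile <- switch(
    config$mode,
    nocontrol = normalize_two_copy(test,
                                   min_bin_count = config$min_bin_count),
    paired = {
      if (is.null(controls)) stop("'paired' mode requires a control")
      if (is.list(controls) && !inherits(controls, "coverage_profile"))
        controls <- controls[[1]]
      paired_log2(test, controls, min_bin_count = config$min_bin_count)
    },
    pooling = {
      if (is.null(controls)) stop("'pooling' mode requires controls")
      if (inherits(controls, "coverage_profile")) controls <- list(controls)
      paired_log2(test, pool_controls(controls),
                  min_bin_count = config$min_bin_count)
    })
  segments <- slm_segment(profile, omega = config$omega, eta = config$eta,
                          K_max = config$K_max,
                          baum_welch = config$baum_welch)
  model <- fit_call_model(segments, cellularity = config$cellularity)
  calls <- call_segments(segments, model)
  if (config$mode == "nocontrol")
    calls <- genotype_absolute(profile, calls)
  list(profile = profile, segments = segments, model = model, calls = calls)
}

#' Write CNV calls in VCF format
#'
#' Emits VCFv4.2 with symbolic alleles: `<DEL>` for losses (double loss
#' has CN 0) and `<DUP>` for gains, `INFO` fields `END`, `SVTYPE`,
#' `SVLEN`, and a single sample with `FORMAT` fields `CN` (integer copy
#' number), `CNS` (state label) and `CNP` (posterior probability of the
#' state). Neutral segments are not emitted. Positions are converted to
#' the 1-based VCF convention.
#'
#' @param calls A `cnv_calls` data.frame.
#' @param path Output path.
#' @param sample_id Sample column name.
#' @param chrom_lengths Optional named vector adding `##contig` headers.
#' @export
write_vcf <- function(calls, path, sample_id = "sample",
                      chrom_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rdcnv",
    "##ALT=<ID=DEL,Description=\"Deletion relative to the two-copy state\">",
    "##ALT=<ID=DUP,Description=\"Duplication relative to the two-copy state\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##FORMAT=<ID=CN,Number=1,Type=Integer,Description=\"Integer copy number\">",
    "##FORMAT=<ID=CNS,Number=1,Type=String,Description=\"Copy-number state\">",
    "##FORMAT=<ID=CNP,Number=1,Type=Float,Description=\"Posterior probability of the state\">"),
    con)
  if (!is.null(chrom_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                       as.integer(chrom_lengths)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_id), collapse = "\t"), con)
  ev <- calls[calls$state != "neutral" & !is.na(calls$cn), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    svtype <- if (ev$cn[i] < 2) "DEL" else "DUP"
    svlen <- (ev$end[i] - ev$start[i]) * if (svtype == "DEL") -1L else 1L
    writeLines(sprintf(
      "%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
      ev$chrom[i], ev$start[i] + 1L, sprintf("rdcnv_%d", i), "N",
      paste0("<", svtype, ">"), ".", "PASS",
      sprintf("END=%d;SVTYPE=%s;SVLEN=%d", ev$end[i], svtype,
              as.integer(svlen)),
      "CN:CNS:CNP",
      sprintf("%d:%s:%.4f", ev$cn[i], ev$state[i], ev$prob[i])), con)
  }
  invisible(path)
}

#' Convert calls to a BED-like data.frame of non-neutral events
#'
#' @param calls A `cnv_calls` data.frame.
#' @return data.frame `chrom start end cn state` of non-neutral calls.
#' @export
calls_to_events <- function(calls) {
  ev <- calls[calls$state != "neutral", , drop = FALSE]
  data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
             cn = ev$cn, state = ev$state, stringsAsFactors = FALSE)
}
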