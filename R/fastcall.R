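#' Expected log2 levels of the five copy-number states
#'
#' With cellularity `c` (fraction of cells carrying the alteration), a
#' region of CN copies in the aberrant cells has expected two-copy-scaled
#' level `c * CN + 2 * (1 - c)`, hence log2 value
#' `log2(max(c * CN + 2 * (1 - c), eps) / 2)` for CN in 0..4. The floor
#' `eps` (0.1 copies) keeps the double-loss mean finite, reflecting the
#' residual mis-mapped coverage real homozygous deletions retain.
#'
#' @param cellularity Cellularity in (0, 1].
#' @param eps Copy-number floor for the double-loss state.
#' @return Numeric vector of five state means (log2 scale), increasing.
#' @export
state_means <- function(cellularity = 1, eps = 0.1) {
  cn <- 0:4
  log2(pmax(cellularity * cn + 2 * (1 - cellularity), eps) / 2)
}

# Boundaries between states: copy-number-space midpoints (0.5, 1.5, 2.5,
# 3.5 copies), cellularity-adjusted and log2-transformed. At c = 1 these
# reproduce the raw-scale calling thresholds (a two-copy-scale median
# <= 1.5 is a loss, >= 2.5 a gain).
state_bounds <- function(cellularity = 1, eps = 0.1) {
  mid <- c(0.5, 1.5, 2.5, 3.5)
  log2(pmax(cellularity * mid + 2 * (1 - cellularity), eps) / 2)
}

state_labels <- c("double_loss", "loss", "neutral", "gain", "multi_gain")

# Assign each value to one of the five brackets. The neutral bracket is
# open on both sides: values exactly on the loss/neutral boundary go to
# loss, values on the neutral/gain boundary go to gain, so boundary
# medians are never called neutral.
bracket_of <- function(x, bounds) {
  k <- findInterval(x, bounds, left.open = TRUE) + 1L   # boundary -> lower
  k[x >= bounds[3]] <- pmax(k[x >= bounds[3]], 4L)      # >= gain cut -> gain
  k[x >= bounds[4]] <- 5L
  k
}

#' Fit the five-state truncated-Gaussian calling model
#'
#' Models segment mean log2 values as a mixture of five Gaussians with
#' means anchored at the cellularity-adjusted copy-number expectations
#' ([state_means()]), a shared standard deviation, and each component
#' truncated and renormalized to its own bracket (brackets delimited by
#' the cellularity-adjusted state boundaries). Because brackets are
#' disjoint, component membership is determined by thresholding, which is
#' what makes the caller fast; the free parameters (weights, shared sd,
#' and cellularity when not supplied) are estimated by maximum likelihood
#' with segments weighted by their number of windows. Cellularity is
#' searched on the grid 0.1, 0.2, ..., 1.0.
#'
#' With fewer than 5 segments the model falls back to fixed thresholds
#' (-1.5, -0.42, 0.32, 1.0 on the log2 scale) with a nominal sd.
#'
#' @param segments A `segment_set` from [slm_segment()].
#' @param cellularity Optional fixed cellularity in (0, 1].
#' @param eps Copy-number floor for the double-loss state.
#' @return A `call_model` list: `state_means`, `state_sd`, `weights`,
#'   `cellularity`, `truncation_bounds`, `fallback`, `loglik`.
#' @export
fit_call_model <- function(segments, cellularity = NULL, eps = 0.1) {
  x <- segments$mean_log2
  wts <- segments$n_windows
  if (length(x) < 5L) {
    cc <- if (is.null(cellularity)) 1 else cellularity
    return(structure(list(state_means = state_means(cc, eps),
                          state_sd = 0.1, weights = rep(0.2, 5),
                          cellularity = cc,
                          truncation_bounds = c(-1.5, -0.42, 0.32, 1.0),
                          fallback = TRUE, loglik = NA_real_),
                     class = "call_model"))
  }
  grid <- if (is.null(cellularity)) seq(0.1, 1.0, by = 0.1) else cellularity
  best <- NULL
  for (cc in grid) {
    fit <- fit_at_cellularity(x, wts, cc, eps)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$fallback <- FALSE
  class(best) <- "call_model"
  best
}

fit_at_cellularity <- function(x, wts, cc, eps) {
  mu <- state_means(cc, eps)
  bounds <- state_bounds(cc, eps)
  k <- bracket_of(x, bounds)
  wsum <- sum(wts)
  weights <- vapply(1:5, function(s) sum(wts[k == s]) / wsum, numeric(1))
  lo <- c(-Inf, bounds); hi <- c(bounds, Inf)
  trunc_loglik <- function(sd) {
    z <- stats::pnorm(hi[k], mu[k], sd) - stats::pnorm(lo[k], mu[k], sd)
    d <- stats::dnorm(x, mu[k], sd) / pmax(z, 1e-300)
    sum(wts * (log(pmax(weights[k], 1e-300)) + log(pmax(d, 1e-300))))
  }
  opt <- stats::optimize(trunc_loglik, interval = c(1e-3, 2), maximum = TRUE)
  list(state_means = mu, state_sd = opt$maximum, weights = weights,
       cellularity = cc, truncation_bounds = bounds, loglik = opt$objective)
}

#' @export
print.call_model <- function(x, ...) {
  cat(sprintf(
    "call_model: cellularity %.1f, sd %.3f%s\n  state means: %s\n  weights: %s\n",
    x$cellularity, x$state_sd, if (x$fallback) " (fixed-threshold fallback)" else "",
    paste(sprintf("%.3f", x$state_means), collapse = " "),
    paste(sprintf("%.3f", x$weights), collapse = " ")))
  invisible(x)
}

#' Posterior state probabilities for segment means
#'
#' Posterior over the five states under the fitted truncated mixture.
#' Components live on disjoint brackets, so the posterior of a segment is
#' concentrated on the bracket containing its mean.
#'
#' @param x Numeric vector of segment mean log2 values.
#' @param model A `call_model`.
#' @return Matrix (length(x) x 5) of posteriors; rows sum to 1.
#' @export
state_posterior <- function(x, model) {
  bounds <- model$truncation_bounds
  lo <- c(-Inf, bounds); hi <- c(bounds, Inf)
  post <- matrix(0, length(x), 5,
                 dimnames = list(NULL, state_labels))
  k <- bracket_of(x, bounds)
  dens <- sapply(1:5, function(s) {
    z <- stats::pnorm(hi[s], model$state_means[s], model$state_sd) -
      stats::pnorm(lo[s], model$state_means[s], model$state_sd)
    inside <- k == s
    ifelse(inside,
           model$weights[s] *
             stats::dnorm(x, model$state_means[s], model$state_sd) /
             pmax(z, 1e-300),
           0)
  })
  dens <- matrix(dens, ncol = 5)
  rs <- rowSums(dens)
  zero <- rs <= 0
  if (any(zero)) dens[cbind(which(zero), k[zero])] <- 1
  post[] <- dens / pmax(rowSums(dens), 1e-300)
  post
}

#' Call copy-number states for segments
#'
#' Assigns each segment the maximum-posterior state under the fitted
#' model, with its posterior probability and integer copy number:
#' double loss = 0, loss = 1, neutral = 2, gain = 3 and multiple gain >= 4
#' (refined to `round(2 * 2^mean_log2)` when the model cellularity is 1,
#' supporting genotypes of 4, 5, 6+ copies).
#'
#' @param segments A `segment_set`.
#' @param model A `call_model` from [fit_call_model()].
#' @return A `cnv_calls` data.frame: `chrom`, `start`, `end`, `n_windows`,
#'   `mean_log2`, `state`, `cn`, `prob`.
#' @export
call_segments <- function(segments, model) {
  x <- segments$mean_log2
  post <- state_posterior(x, model)
  k <- max.col(post, ties.method = "first")
  cn <- c(0L, 1L, 2L, 3L, 4L)[k]
  multi <- k == 5L
  if (any(multi) && model$cellularity == 1)
    cn[multi] <- pmax(4L, as.integer(round_half_up(2 * 2^x[multi])))
  calls <- data.frame(chrom = segments$chrom,
                      start = segments$start,
                      end = segments$end,
                      n_windows = segments$n_windows,
                      mean_log2 = x,
                      state = state_labels[k],
                      cn = cn,
                      prob = post[cbind(seq_along(k), k)],
                      stringsAsFactors = FALSE)
  class(calls) <- c("cnv_calls", "data.frame")
  calls
}

#' Absolute copy-number genotyping from the two-copy-scaled signal
#'
#' Estimates the integer copy number of each called region as the rounded
#' median of the two-copy-scaled normalized values over its windows (valid
#' in the single-sample design, where the signal is on the absolute
#' scale). When the rounded median disagrees with the five-state call, the
#' copy number wins and the state label is re-derived from it, keeping the
#' state/CN correspondence consistent. Regions whose windows are all
#' masked get `cn = NA`.
#'
#' @param profile The `normalized_profile` the calls were derived from.
#' @param calls A `cnv_calls` data.frame.
#' @return `calls` with refreshed `cn` (and possibly `state`).
#' @export
genotype_absolute <- function(profile, calls) {
  windows <- profile$windows
  for (i in seq_len(nrow(calls))) {
    sel <- which(windows$chrom == calls$chrom[i] &
                   windows$start < calls$end[i] &
                   windows$end > calls$start[i] &
                   profile$usable)
    if (!length(sel)) {
      calls$cn[i] <- NA_integer_
      next
    }
    med <- stats::median(profile$norm_values[sel])
    cn <- as.integer(round_half_up(med))
    calls$cn[i] <- cn
    implied <- state_labels[pmin(cn, 4L) + 1L]
    if (!is.na(cn) && implied != calls$state[i]) calls$state[i] <- implied
  }
  calls
}

#' Write a calls table
#'
#' Tab-delimited `chrom start end n_windows mean_log2 state cn prob`.
#'
#' @param calls A `cnv_calls` data.frame.
#' @param path File path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
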