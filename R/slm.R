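#' Shifting-level-model parameters
#'
#' The shifting level model writes an ordered signal as x_i = m_i + e_i:
#' an unobserved mean level m_i that persists from window to window and,
#' with probability `eta` per step, jumps to a new value drawn from
#' N(`mu`, `sigma2_mu`); e_i is white noise with variance `sigma2_eps`.
#' Discretizing the level space to `levels` turns the model into a hidden
#' Markov model whose states are the candidate levels, with transition
#' matrix A_ij = (1 - eta) * 1[i == j] + eta * w_j, where w_j is the
#' (normalized) density of level j under the level process, Gaussian
#' emissions N(x; level_j, sigma2_eps), and initial distribution w.
#'
#' @param mu Global mean of the level process.
#' @param sigma2_mu Variance of the level process (> 0).
#' @param sigma2_eps White-noise variance (> 0).
#' @param eta Jump probability per step, in (0, 1).
#' @param levels Strictly increasing vector of >= 2 candidate levels.
#' @return An `slm_params` object.
#' @export
slm_params <- function(mu, sigma2_mu, sigma2_eps, eta, levels) {
  stopifnot(sigma2_mu > 0, sigma2_eps > 0, eta > 0, eta < 1,
            length(levels) >= 2, !is.unsorted(levels, strictly = TRUE))
  structure(list(mu = mu, sigma2_mu = sigma2_mu, sigma2_eps = sigma2_eps,
                 eta = eta, levels = as.numeric(levels)),
            class = "slm_params")
}

#' Build the HMM specification for an SLM
#'
#' Computes the level weights w (density of each candidate level under the
#' level process, normalized), the full transition matrix and the initial
#' distribution. The transition matrix is returned for inspection and for
#' small-instance exact computations; the Viterbi decoder exploits its
#' `(1-eta) I + eta 1 w'` structure and never materializes it.
#'
#' @param params An [slm_params()].
#' @return A list with `params`, `w`, `log_trans` (K x K), `log_init`.
#' @export
build_hmm <- function(params) {
  w <- level_weights(params)
  K <- length(params$levels)
  A <- matrix(rep(params$eta * w, each = K), nrow = K)
  diag(A) <- diag(A) + (1 - params$eta)
  list(params = params, w = w, log_trans = log(A), log_init = log(w))
}

level_weights <- function(params) {
  w <- stats::dnorm(params$levels, params$mu, sqrt(params$sigma2_mu))
  if (!any(w > 0) || !all(is.finite(w)))
    w <- rep(1, length(params$levels))
  w / sum(w)
}

#' Estimate SLM parameters from a signal
#'
#' Method-of-moments initialization: `mu` is the signal mean; the signal
#' variance s2 is split into noise variance `sigma2_eps = (1 - omega) * s2`
#' and level variance `sigma2_mu = omega * s2`, the latter floored at
#' `(span / 4)^2` where span is the spread of the candidate levels — the
#' level process must place non-negligible prior mass on every candidate
#' level, otherwise jumps to strong copy-number levels (a duplication at
#' +0.58, a deletion at -1) are priced out regardless of the evidence.
#' Candidate levels are a grid of `K = min(K_max, #distinct smoothed
#' values)` equally spaced points spanning the range of the 5-window
#' running-median smoothed signal, which is robust to single-window
#' outliers. Optionally refined by up to `max_iter` Baum-Welch sweeps
#' updating `eta` and `sigma2_eps` (monotone non-decreasing
#' log-likelihood).
#'
#' @param signal Numeric vector of (log2) values, no NAs, length >= 10.
#' @param omega Fraction of total variance assigned to the level process.
#' @param eta Jump probability per step.
#' @param K_max Maximum number of candidate levels.
#' @param baum_welch Refine by Baum-Welch EM sweeps.
#' @param max_iter Maximum EM sweeps when `baum_welch = TRUE`.
#' @return An `slm_params`, or `NULL` for degenerate input (fewer than 10
#'   windows or zero variance), signalling the single-segment shortcut.
#' @export
estimate_params <- function(signal, omega = 0.1, eta = 1e-3, K_max = 40L,
                            baum_welch = FALSE, max_iter = 10L) {
  n <- length(signal)
  if (n < 10L) return(NULL)
  s2 <- stats::var(signal)
  if (!is.finite(s2) || s2 <= 0) return(NULL)
  smoothed <- stats::runmed(signal, k = 5)
  K <- min(K_max, length(unique(smoothed)))
  if (K < 2L) return(NULL)
  levels <- seq(min(smoothed), max(smoothed), length.out = K)
  if (levels[1] == levels[K]) return(NULL)
  span <- levels[K] - levels[1]
  params <- slm_params(mu = mean(signal),
                       sigma2_mu = max(omega * s2, (span / 4)^2),
                       sigma2_eps = (1 - omega) * s2, eta = eta,
                       levels = levels)
  if (baum_welch)
    params <- baum_welch_refine(signal, params, max_iter = max_iter)$params
  params
}

# Scaled forward-backward pass exploiting the rank-one-plus-diagonal
# transition structure; O(n K) per sweep.
slm_forward_backward <- function(signal, params) {
  n <- length(signal)
  w <- level_weights(params)
  lv <- params$levels
  K <- length(lv)
  se <- sqrt(params$sigma2_eps)
  eta <- params$eta
  emis <- matrix(vapply(lv, function(l) stats::dnorm(signal, l, se),
                        numeric(n)), nrow = n)
  emis <- pmax(emis, 1e-300)                       # n x K
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K)
  cvec <- numeric(n)
  a <- w * emis[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  for (i in 2:n) {
    a <- ((1 - eta) * alpha[i - 1, ] + eta * w) * emis[i, ]
    cvec[i] <- sum(a)
    alpha[i, ] <- a / cvec[i]
  }
  beta[n, ] <- 1
  for (i in (n - 1):1) {
    # (A b)_i = (1-eta) b_i + eta * sum_j w_j b_j, with b_j = emis * beta
    b <- emis[i + 1, ] * beta[i + 1, ]
    beta[i, ] <- ((1 - eta) * b + eta * sum(w * b)) / cvec[i + 1]
  }
  list(alpha = alpha, beta = beta, c = cvec, emis = emis, w = w,
       loglik = sum(log(cvec)))
}

# EM sweeps updating eta and sigma2_eps (levels, mu, sigma2_mu fixed).
baum_welch_refine <- function(signal, params, max_iter = 10L, tol = 1e-6) {
  n <- length(signal)
  logliks <- numeric(0)
  for (it in seq_len(max_iter)) {
    fb <- slm_forward_backward(signal, params)
    logliks <- c(logliks, fb$loglik)
    gamma <- fb$alpha * fb$beta
    gamma <- gamma / rowSums(gamma)
    # expected jump count: P(z_{i-1} = 1 | x) summed over steps
    jumps <- 0
    for (i in 2:n) {
      b <- fb$emis[i, ] * fb$beta[i, ]
      pj <- params$eta * sum(fb$w * b) / fb$c[i]   # alpha rows sum to 1
      jumps <- jumps + pj
    }
    resid2 <- vapply(seq_along(params$levels),
                     function(j) sum(gamma[, j] * (signal - params$levels[j])^2),
                     numeric(1))
    new_eta <- min(max(jumps / (n - 1), 1e-12), 1 - 1e-12)
    new_s2 <- max(sum(resid2) / n, 1e-12)
    if (it > 1 && abs(logliks[it] - logliks[it - 1]) < tol) break
    params$eta <- new_eta
    params$sigma2_eps <- new_s2
  }
  list(params = params, logliks = logliks)
}

#' Viterbi decoding of an SLM signal
#'
#' Returns the most probable hidden level sequence under the SLM-HMM,
#' using the structured transition matrix for an O(n K) pass. Ties are
#' broken toward staying in the previous state, favoring longer segments.
#'
#' @param signal Numeric vector without NAs.
#' @param params An [slm_params()].
#' @return A list: `path` (level index per window), `levels` (decoded level
#'   values), `logp` (joint log-probability of the path).
#' @export
viterbi <- function(signal, params) {
  n <- length(signal)
  w <- level_weights(params)
  lv <- params$levels
  K <- length(lv)
  se <- sqrt(params$sigma2_eps)
  log_w <- log(w)
  log_stay <- log((1 - params$eta) + params$eta * w)
  log_jump <- log(params$eta) + log_w
  emis <- matrix(vapply(lv, function(l) stats::dnorm(signal, l, se,
                                                     log = TRUE),
                        numeric(n)), nrow = n)
  if (n == 1L) {
    path <- which.max(log_w + emis[1, ])
    return(list(path = path, levels = lv[path],
                logp = (log_w + emis[1, ])[path]))
  }
  delta <- log_w + emis[1, ]
  ptr <- matrix(0L, n, K)
  for (i in 2:n) {
    o <- order(delta, decreasing = TRUE)
    best <- o[1]; second <- o[2]
    stay <- delta + log_stay
    jump_from <- rep(best, K)
    jump_val <- delta[best] + log_jump
    jump_val[best] <- delta[second] + log_jump[best]
    jump_from[best] <- second
    take_stay <- stay >= jump_val            # ties favor staying
    delta <- ifelse(take_stay, stay, jump_val) + emis[i, ]
    ptr[i, ] <- ifelse(take_stay, seq_len(K), jump_from)
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  logp <- delta[path[n]]
  for (i in n:2) path[i - 1] <- ptr[i, path[i]]
  list(path = path, levels = lv[path], logp = logp)
}

#' Segment a normalized profile with the shifting level model
#'
#' Chromosomes are segmented independently. Masked windows are removed
#' before decoding and the segment coordinates re-expanded afterwards, so
#' segments may span masked windows. Chromosomes with fewer than 10 usable
#' windows, or a constant signal, yield a single segment.
#'
#' @param profile A `normalized_profile` (or a list with `windows`,
#'   `log2_values`, `usable`).
#' @param omega,eta,K_max,baum_welch,max_iter See [estimate_params()].
#' @param params Optional fixed [slm_params()] used for every chromosome
#'   (skips estimation).
#' @return A `segment_set` data.frame with columns `chrom`, `start`, `end`
#'   (bases, 0-based half-open over the spanned usable windows),
#'   `start_window`, `end_window` (inclusive indices into the full grid),
#'   `n_windows` (usable windows), `mean_log2` (decoded level) and
#'   `emp_mean` (empirical mean of member windows).
#' @export
slm_segment <- function(profile, omega = 0.1, eta = 1e-3, K_max = 40L,
                        baum_welch = FALSE, max_iter = 10L, params = NULL) {
  windows <- profile$windows
  out <- list()
  for (chrom in unique(windows$chrom)) {
    sel <- which(windows$chrom == chrom)
    use <- sel[profile$usable[sel] & !is.na(profile$log2_values[sel])]
    if (!length(use)) next
    x <- profile$log2_values[use]
    p <- if (is.null(params))
      estimate_params(x, omega = omega, eta = eta, K_max = K_max,
                      baum_welch = baum_welch, max_iter = max_iter)
    else params
    if (is.null(p)) {
      lev <- rep(1L, length(x))
      lv_val <- mean(x)
    } else {
      vit <- viterbi(x, p)
      lev <- vit$path
      lv_val <- p$levels
    }
    runs <- rle(lev)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    seg <- data.frame(
      chrom = chrom,
      start = windows$start[use[idx_start]],
      end = windows$end[use[idx_end]],
      start_window = use[idx_start],
      end_window = use[idx_end],
      n_windows = runs$lengths,
      mean_log2 = if (is.null(p)) lv_val else lv_val[runs$values],
      emp_mean = vapply(seq_along(runs$values), function(k)
        mean(x[idx_start[k]:idx_end[k]]), numeric(1)),
      stringsAsFactors = FALSE)
    out[[chrom]] <- seg
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  class(seg) <- c("segment_set", "data.frame")
  seg
}

#' Write a segment table
#'
#' Tab-delimited `chrom start end n_windows mean_log2`.
#'
#' @param segments A `segment_set`.
#' @param path File path.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(
    as.data.frame(segments)[, c("chrom", "start", "end", "n_windows",
                                "mean_log2")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
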