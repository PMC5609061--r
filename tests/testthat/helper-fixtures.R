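# shared fixtures: small grids, simulated profiles and a brute-force
# Viterbi oracle used by several test files

flat_grid <- function(n, window_size = 100L, chrom = "chr1", gc = 45L,
                      map = 1) {
  win <- build_windows(stats::setNames(n * window_size, chrom), window_size)
  win$gc <- gc
  win$map <- map
  win
}

# truth events of a sim_truth as a BED-like data.frame (base coordinates)
truth_events_df <- function(truth, windows) {
  ev <- truth$events
  do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    sel <- which(windows$chrom == ev$chrom[i])
    data.frame(chrom = ev$chrom[i],
               start = windows$start[sel[ev$start_window[i]]],
               end = windows$end[sel[ev$end_window[i]]],
               cn = ev$cn[i], stringsAsFactors = FALSE)
  }))
}

# detect the event of one synthetic chromosome; returns TRUE on a TP at
# 50% reciprocal overlap with matching direction
detect_event <- function(sim, window_size) {
  res <- run_analysis(sim$profile, NULL,
                      run_config(mode = "nocontrol",
                                 window_size = window_size))
  ev <- calls_to_events(res$calls)
  truth <- truth_events_df(sim$truth, sim$windows)
  score_calls(ev, truth, require_state_match = TRUE)$tp == 1L
}

pipeline_tpr <- function(cn, N, nrep, seed0, coverage_x, window_size) {
  hits <- vapply(seq_len(nrep), function(i) {
    sim <- make_synthetic_chromosome(N, cn, coverage_x = coverage_x,
                                     window_size = window_size,
                                     seed = seed0 + i)
    detect_event(sim, window_size)
  }, logical(1))
  mean(hits)
}

# exhaustive-enumeration decoder: argmax over all K^n level paths of the
# joint log-probability; independent of the dynamic-programming code
enumerate_best_path <- function(signal, params) {
  K <- length(params$levels)
  n <- length(signal)
  hmm <- build_hmm(params)
  emis <- matrix(vapply(params$levels,
                        function(l) stats::dnorm(signal, l,
                                                 sqrt(params$sigma2_eps),
                                                 log = TRUE),
                        numeric(n)), nrow = n)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  tot <- hmm$log_init[paths[, 1]]
  for (i in seq_len(n)) tot <- tot + emis[i, ][paths[, i]]
  if (n > 1)
    for (i in 2:n) tot <- tot + hmm$log_trans[cbind(paths[, i - 1],
                                                    paths[, i])]
  best <- which.max(tot)
  list(path = as.integer(paths[best, ]), logp = tot[best])
}

random_slm_instance <- function(n_max = 8, K_max = 3) {
  n <- sample(2:n_max, 1)
  K <- sample(2:K_max, 1)
  lv <- sort(stats::rnorm(K))
  while (any(diff(lv) < 0.05)) lv <- sort(stats::rnorm(K))
  params <- slm_params(mu = stats::rnorm(1),
                       sigma2_mu = stats::runif(1, 0.3, 2),
                       sigma2_eps = stats::runif(1, 0.02, 0.5),
                       eta = stats::runif(1, 0.001, 0.3),
                       levels = lv)
  list(signal = stats::rnorm(n, sample(lv, n, replace = TRUE),
                             sqrt(params$sigma2_eps)),
       params = params)
}
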