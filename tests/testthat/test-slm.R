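test_that("the HMM specification is a proper probability model", {
  set.seed(61)
  for (rep in 1:10) {
    inst <- random_slm_instance()
    hmm <- build_hmm(inst$params)
    A <- exp(hmm$log_trans)
    expect_equal(rowSums(A), rep(1, length(inst$params$levels)))
    expect_equal(sum(exp(hmm$log_init)), 1)
  }
  # symmetric two-level model has uniform level weights
  p <- slm_params(mu = 0, sigma2_mu = 1, sigma2_eps = 0.1, eta = 0.01,
                  levels = c(-0.7, 0.7))
  expect_equal(build_hmm(p)$w, c(0.5, 0.5))
})

test_that("a vanishing jump probability yields a single constant level", {
  set.seed(62)
  p <- slm_params(mu = 0, sigma2_mu = 1, sigma2_eps = 1, eta = 1e-12,
                  levels = c(-1, 0, 1))
  v <- viterbi(rnorm(100), p)
  expect_equal(length(unique(v$path)), 1L)
})

test_that("method-of-moments estimates recover noise parameters", {
  set.seed(63)
  x <- rnorm(10000)
  p <- estimate_params(x)
  expect_lt(abs(p$mu), 0.05)
  expect_lt(abs(p$sigma2_eps / 0.9 - 1), 0.1)   # (1 - omega) * s2
  # degenerate inputs fall back to NULL (single-segment shortcut)
  expect_null(estimate_params(rep(1, 100)))
  expect_null(estimate_params(rnorm(5)))
})

test_that("Baum-Welch refinement never decreases the log-likelihood", {
  set.seed(64)
  x <- c(rnorm(60, 0, 0.3), rnorm(40, 1, 0.3))
  p <- estimate_params(x)
  bw <- rdcnv:::baum_welch_refine(x, p, max_iter = 8)
  expect_true(all(diff(bw$logliks) > -1e-6))
})

test_that("Viterbi equals the exhaustive-enumeration argmax", {
  set.seed(65)
  for (trial in 1:60) {
    inst <- random_slm_instance(n_max = 8, K_max = 3)
    v <- viterbi(inst$signal, inst$params)
    e <- enumerate_best_path(inst$signal, inst$params)
    expect_equal(v$logp, e$logp, tolerance = 1e-9)
  }
})

test_that("known small decoding instances give the expected paths", {
  # constant zero signal with a matching level decodes as one segment
  p <- slm_params(mu = 0, sigma2_mu = 1, sigma2_eps = 0.1, eta = 0.01,
                  levels = c(-1, 0, 1))
  v <- viterbi(rep(0, 5), p)
  expect_equal(v$levels, rep(0, 5))

  # one downward shift: path (0, 0, -1, -1, -1), checked against the
  # enumeration oracle as well
  p2 <- slm_params(mu = -0.5, sigma2_mu = 1, sigma2_eps = 0.04, eta = 0.1,
                   levels = c(-1, 0))
  x <- c(0.0, 0.1, -1.1, -0.9, -1.0)
  v2 <- viterbi(x, p2)
  expect_equal(v2$levels, c(0, 0, -1, -1, -1))
  expect_equal(v2$logp, enumerate_best_path(x, p2)$logp, tolerance = 1e-9)
})

test_that("breakpoint count is non-decreasing in the jump probability", {
  set.seed(66)
  signals <- lapply(1:20, function(i) rnorm(200))
  mean_breaks <- sapply(c(1e-7, 1e-5, 1e-3, 1e-1), function(eta) {
    mean(sapply(signals, function(x) {
      p <- estimate_params(x, eta = eta)
      length(rle(viterbi(x, p)$path)$lengths) - 1L
    }))
  })
  expect_true(all(diff(mean_breaks) >= 0))
})

test_that("segmentation is shift-equivariant and reversal-symmetric", {
  set.seed(67)
  x <- c(rnorm(300, 0, 0.3), rnorm(100, -1, 0.3), rnorm(300, 0, 0.3))
  win <- flat_grid(length(x), 100)
  mk <- function(v) structure(
    list(windows = win, log2_values = v, usable = rep(TRUE, length(v))),
    class = "normalized_profile")
  seg <- slm_segment(mk(x))
  shifted <- slm_segment(mk(x + 0.8))
  expect_equal(shifted$start, seg$start)
  expect_equal(shifted$mean_log2, seg$mean_log2 + 0.8)

  rev_seg <- slm_segment(mk(rev(x)))
  n <- length(x) * 100
  expect_equal(sort(n - rev_seg$end), sort(seg$start))
})

test_that("a strong single shift is located to within one window", {
  set.seed(68)
  hits <- sapply(1:100, function(i) {
    x <- rnorm(1000)
    x[501:1000] <- x[501:1000] + 6
    p <- estimate_params(x)
    path <- viterbi(x, p)$path
    bk <- which(diff(path) != 0)
    length(bk) >= 1 && min(abs(bk - 500)) <= 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("segments partition usable windows and span masked ones", {
  set.seed(69)
  x <- c(rnorm(200, 0, 0.2), rnorm(50, 1, 0.2), rnorm(200, 0, 0.2))
  usable <- rep(TRUE, 450)
  usable[c(100:110, 220:225)] <- FALSE
  win <- flat_grid(450, 100)
  prof <- structure(list(windows = win, log2_values = x, usable = usable),
                    class = "normalized_profile")
  seg <- slm_segment(prof)
  expect_equal(sum(seg$n_windows), sum(usable))
  # consecutive segments carry different levels
  expect_true(all(diff(seg$mean_log2) != 0))
  # the event is found despite interior masked windows
  expect_true(any(seg$mean_log2 > 0.5 & seg$n_windows >= 40))

  # short chromosomes collapse to a single segment
  short <- structure(list(windows = flat_grid(5, 100),
                          log2_values = rnorm(5),
                          usable = rep(TRUE, 5)),
                     class = "normalized_profile")
  expect_equal(nrow(slm_segment(short)), 1L)
})
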