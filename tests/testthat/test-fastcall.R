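mk_segments <- function(means, n_windows = 50L) {
  data.frame(chrom = "chr1",
             start = seq_along(means) * 10000,
             end = seq_along(means) * 10000 + 5000,
             start_window = seq_along(means),
             end_window = seq_along(means),
             n_windows = rep(n_windows, length(means)),
             mean_log2 = means,
             emp_mean = means,
             stringsAsFactors = FALSE)
}

test_that("state means follow the cellularity-adjusted CN expectations", {
  m1 <- state_means(1)
  expect_equal(m1[3], 0)                    # neutral
  expect_equal(m1[2], -1)                   # loss
  expect_equal(m1[4], log2(3 / 2))          # gain ~ 0.585
  expect_equal(m1[1], log2(0.1 / 2))        # double loss with 0.1 floor
  expect_equal(m1[5], 1)

  m05 <- state_means(0.5)
  expect_equal(m05[2], log2(1.5 / 2))       # loss shrunk toward 0, ~ -0.415
  expect_true(all(abs(m05[-3]) < abs(m1[-3])))
  expect_true(all(diff(state_means(0.8)) > 0))
})

test_that("the mixture fit recovers weights, sd and cellularity", {
  set.seed(71)
  truth_w <- rep(0.2, 5)
  x <- as.vector(sapply(state_means(1), function(m) rnorm(100, m, 0.1)))
  segs <- mk_segments(x)
  model <- fit_call_model(segs)
  expect_false(model$fallback)
  expect_equal(model$cellularity, 1)
  expect_true(all(abs(model$weights - truth_w) < 0.05))
  expect_lt(abs(model$state_sd - 0.1), 0.05)
})

test_that("segments are classified by maximum posterior with CN mapping", {
  model <- fit_call_model(mk_segments(c(rnorm(40, 0, 0.05),
                                        rnorm(10, -1, 0.05),
                                        rnorm(10, 0.585, 0.05))),
                          cellularity = 1)
  calls <- call_segments(mk_segments(c(0, -1.05, 1.32, 0.59, -2.5)), model)
  expect_equal(calls$state,
               c("neutral", "loss", "multi_gain", "gain", "double_loss"))
  expect_equal(calls$cn, c(2L, 1L, 5L, 3L, 0L))   # 2 * 2^1.32 ~ 4.99 -> 5
  expect_true(all(calls$prob >= 0 & calls$prob <= 1))
})

test_that("posterior rows sum to one and calling is monotone in the mean", {
  set.seed(72)
  model <- fit_call_model(mk_segments(rnorm(100, rep(state_means(1), 20),
                                            0.08)))
  x <- sort(runif(50, -3, 1.8))
  post <- state_posterior(x, model)
  expect_equal(rowSums(post), rep(1, 50))
  calls <- call_segments(mk_segments(x), model)
  idx <- match(calls$state, c("double_loss", "loss", "neutral", "gain",
                              "multi_gain"))
  expect_true(all(diff(idx) >= 0))
})

test_that("well-separated states are called correctly at high rate", {
  set.seed(73)
  true_state <- sample(1:5, 500, replace = TRUE)
  x <- rnorm(500, state_means(1)[true_state], 0.1)
  segs <- mk_segments(x)
  model <- fit_call_model(segs, cellularity = 1)
  calls <- call_segments(segs, model)
  idx <- match(calls$state, c("double_loss", "loss", "neutral", "gain",
                              "multi_gain"))
  expect_gte(mean(idx == true_state), 0.98)
})

test_that("raw-scale medians at the loss threshold are never neutral", {
  model <- fit_call_model(mk_segments(rnorm(50, rep(state_means(1), 10),
                                            0.05)), cellularity = 1)
  # two-copy medians 1.5 and below -> log2 <= log2(1.5/2): always a loss
  for (median_cn in c(1.5, 1.49, 1.2)) {
    calls <- call_segments(mk_segments(log2(median_cn / 2)), model)
    expect_true(calls$state %in% c("loss", "double_loss"))
  }
  # and medians >= 2.5 are never neutral either
  for (median_cn in c(2.5, 2.6, 3)) {
    calls <- call_segments(mk_segments(log2(median_cn / 2)), model)
    expect_true(calls$state %in% c("gain", "multi_gain"))
  }
})

test_that("fewer than five segments fall back to fixed thresholds", {
  segs <- mk_segments(c(-0.8, 0.02, 0.5))
  model <- fit_call_model(segs)
  expect_true(model$fallback)
  expect_equal(model$truncation_bounds, c(-1.5, -0.42, 0.32, 1.0))
  calls <- call_segments(segs, model)
  expect_equal(calls$state, c("loss", "neutral", "gain"))
})

test_that("absolute genotyping rounds the regional median copy number", {
  win <- flat_grid(30, 100)
  norm_vals <- c(rep(2.0, 10), rep(0.9, 10), rep(4.2, 10))
  prof <- structure(list(windows = win, norm_values = norm_vals,
                         log2_values = log2(norm_vals / 2),
                         usable = rep(TRUE, 30)),
                    class = "normalized_profile")
  calls <- data.frame(chrom = "chr1",
                      start = c(0, 1000, 2000), end = c(1000, 2000, 3000),
                      n_windows = 10L, mean_log2 = log2(norm_vals[c(1, 11, 21)] / 2),
                      state = c("neutral", "neutral", "gain"),
                      cn = c(2L, 2L, 3L), prob = 1,
                      stringsAsFactors = FALSE)
  out <- genotype_absolute(prof, calls)
  expect_equal(out$cn, c(2L, 1L, 4L))
  # state labels re-derived where the genotype disagrees
  expect_equal(out$state, c("neutral", "loss", "multi_gain"))

  # fully masked region -> missing CN
  prof$usable[1:10] <- FALSE
  out <- genotype_absolute(prof, calls[1, ])
  expect_true(is.na(out$cn))
})

test_that("simulated CN 0..6 regions are genotyped on the identity line", {
  reg <- simulate_region_medians(rep(0:6, each = 10), 50,
                                 coverage_x = 30, window_size = 100,
                                 seed = 74)
  pred <- round(reg$median_norm)
  cc <- cn_concordance(pred, reg$cn)
  expect_gte(cc$ccr, 0.95)
  expect_lt(abs(cc$slope - 1), 0.05)
})
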