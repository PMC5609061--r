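test_that("median normalization equalizes per-bin medians", {
  # single bin: correction is the identity
  win <- flat_grid(5, 100)
  prof <- coverage_profile(c(10, 20, 30, 40, 50), win)
  out <- median_normalize(prof, "gc", min_bin_count = 1)
  expect_equal(out$values, prof$values)

  # two bins, hand-computed: A = [10,20,30] (median 20), B = [10,10,20]
  # (median 10), overall median 15
  win <- flat_grid(6, 100)
  win$gc <- c(30L, 30L, 30L, 60L, 60L, 60L)
  prof <- coverage_profile(c(10, 20, 30, 10, 10, 20), win)
  out <- median_normalize(prof, "gc", min_bin_count = 1)
  expect_equal(out$values, c(7.5, 15, 22.5, 15, 15, 30))

  # per-bin medians now all equal the original overall median
  for (b in c(30, 60))
    expect_equal(median(out$values[win$gc == b]), 15)
})

test_that("zero-median bins are masked, not divided", {
  win <- flat_grid(4, 100)
  win$gc <- c(40L, 40L, 40L, 80L)
  prof <- coverage_profile(c(10, 20, 30, 0), win)
  out <- median_normalize(prof, "gc", min_bin_count = 1)
  expect_false(out$usable[4])
  expect_true(all(is.finite(out$values)))
})

test_that("sparse bins borrow the nearest well-populated bin median", {
  set.seed(5)
  win <- flat_grid(100, 100)
  win$gc <- c(rep(45L, 98), 90L, 91L)
  v <- c(rpois(98, 100), 1000, 1000)   # outlier bins with 1 window each
  prof <- coverage_profile(v, win)
  out <- median_normalize(prof, "gc", min_bin_count = 30)
  # the two sparse windows are scaled by the 45%-bin median, not their own
  expect_equal(out$values[99] / v[99], out$values[1] / v[1])
})

test_that("two-copy normalization matches an independent re-computation", {
  set.seed(17)
  win <- flat_grid(200, 100)
  win$gc <- sample(c(35L, 45L, 55L), 200, replace = TRUE)
  win$map <- sample(c(0.9, 1.0), 200, replace = TRUE)
  v <- rnbinom(200, mu = 50, size = 25)
  v[v == 0] <- 1
  prof <- coverage_profile(v, win)
  norm <- normalize_two_copy(prof, min_bin_count = 1)

  # brute-force oracle: the three steps written out independently
  x <- v
  m <- median(x)
  for (b in unique(win$gc)) {
    sel <- win$gc == b
    x[sel] <- x[sel] * m / median(x[sel])
  }
  m2 <- median(x)
  for (b in unique(win$map)) {
    sel <- win$map == b
    x[sel] <- x[sel] * m2 / median(x[sel])
  }
  x <- x * 2 / median(x)
  expect_equal(norm$norm_values, x, tolerance = 1e-12)
  expect_equal(norm$log2_values, log2(x / 2), tolerance = 1e-12)
  expect_equal(median(norm$norm_values[norm$usable]), 2)
})

test_that("normalization is scale-equivariant", {
  set.seed(31)
  win <- flat_grid(300, 100)
  win$gc <- sample(c(40L, 50L), 300, replace = TRUE)
  v <- rpois(300, 80) + 1
  a <- median_normalize(coverage_profile(v, win), "gc", min_bin_count = 1)
  b <- median_normalize(coverage_profile(v * 3, win), "gc",
                        min_bin_count = 1)
  expect_equal(b$values, a$values * 3)
})

test_that("injected GC bias is removed by normalization", {
  set.seed(41)
  n <- 20000
  win <- flat_grid(n, 1000)
  win$gc <- pmin(pmax(as.integer(round(rnorm(n, 32, 11))), 2L), 58L)
  truth <- sim_truth(data.frame(), coverage_x = 30, window_size = 1000)
  prof <- simulate_rc(win, truth, gc_bias = default_gc_bias)
  pre_r <- cor(prof$values, win$gc)
  expect_gt(abs(pre_r), 0.3)
  norm <- normalize_two_copy(prof)
  post_r <- cor(norm$norm_values[norm$usable], win$gc[norm$usable])
  expect_lt(abs(post_r), 0.05)
})

test_that("bias-free data are not spuriously corrected", {
  set.seed(43)
  n <- 20000
  win <- flat_grid(n, 100)
  win$gc <- sample(c(35L, 40L, 45L, 50L, 55L), n, replace = TRUE)
  truth <- sim_truth(data.frame(), coverage_x = 30, window_size = 100)
  prof <- simulate_rc(win, truth)
  out <- median_normalize(prof, "gc")
  rel <- abs(out$values[out$usable] / prof$values[out$usable] - 1)
  expect_lt(max(rel), 0.05)
})

test_that("paired log2 ratios behave at the identities and guards", {
  win <- flat_grid(50, 100)
  set.seed(3)
  v <- rpois(50, 100) + 1
  test_p <- coverage_profile(v, win)
  ctrl_p <- coverage_profile(v, win)
  ratio <- paired_log2(test_p, ctrl_p, min_bin_count = 1)
  expect_equal(ratio$log2_values, rep(0, 50))

  # doubling a region gives log2 ratio 1 there (bias-corrected inputs)
  mk_norm <- function(values) structure(
    list(sample_id = "m", windows = win, norm_values = values,
         log2_values = log2(values / 2), usable = rep(TRUE, length(values))),
    class = "normalized_profile")
  v2 <- v
  v2[10:20] <- v[10:20] * 2
  ratio <- paired_log2(mk_norm(v2), mk_norm(v))
  expect_equal(ratio$log2_values[10:20], rep(1, 11))
  expect_equal(ratio$log2_values[-(10:20)], rep(0, 39))

  # control zero is masked, never +-Inf
  v3 <- v
  v3[5] <- 0
  ratio <- paired_log2(test_p, coverage_profile(v3, win), min_bin_count = 1)
  expect_false(ratio$usable[5])
  expect_true(all(is.finite(ratio$log2_values[ratio$usable])))

  other <- flat_grid(50, 100, chrom = "chrX")
  expect_error(paired_log2(test_p, coverage_profile(v, other),
                           min_bin_count = 1), "grid")
})

test_that("control pooling sums window-wise", {
  win <- flat_grid(3, 100)
  a <- coverage_profile(c(1, 2, 3), win)
  b <- coverage_profile(c(3, 2, 1), win)
  expect_equal(pool_controls(list(a))$values, a$values)
  expect_equal(pool_controls(list(a, b))$values, c(4, 4, 4))
  expect_error(pool_controls(list()), "at least one")
})
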