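test_that("estimate_abd solves the zero-bin and total matching conditions", {
  lib <- make_lib(c(0, 0, 4, 4))
  p <- estimate_abd(lib)
  # the two defining conditions, checked independently of the closed form
  expect_equal(4 * (1 - 1 / 4)^p$n0, 2, tolerance = 1e-10)   # B(1-1/B)^n0 = Z0
  expect_equal(p$amp * p$n0, 8, tolerance = 1e-10)           # a n0 = N
  expect_equal(p$n0, 2.409421, tolerance = 1e-6)
  expect_equal(p$amp, 3.320300, tolerance = 1e-6)

  # B = 1000, Z0 = 368, N = 1000: (1 - 1/1000)^1000 ~ e^-1 so n0 ~ 999
  counts <- c(rep(0, 368), rep(1, 631), 369)
  p2 <- estimate_abd(make_lib(counts))
  expect_equal(p2$n0, 999, tolerance = 1e-3)
  expect_equal(p2$amp, 1.0, tolerance = 1e-2)
})

test_that("estimate_abd rejects degenerate libraries", {
  expect_error(estimate_abd(make_lib(c(1, 2, 3, 4))), "no empty bins")
  expect_error(estimate_abd(make_lib(c(0, 0, 0))), "empty library")
})

test_that("abd_survival matches the brute-force binomial tail for integer n0", {
  params <- structure(list(n0 = 20, amp = 2, bins = 10), class = "abd_params")
  for (c in 0:45) {
    k <- ceiling(c / 2)
    oracle <- if (k <= 0) 1 else sum(dbinom(k:20, 20, 0.1))
    expect_equal(abd_survival(params, c), oracle, tolerance = 1e-12)
  }
})

test_that("abd_survival is a proper survival function", {
  p <- estimate_abd(make_lib(c(0, 0, 4, 4)))
  expect_equal(abd_survival(p, 0), 1)
  expect_equal(abd_survival(p, 1e9), 0)
  s <- abd_survival(p, 0:50)
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("fdr_threshold equals a brute-force scan over all thresholds", {
  brute <- function(lib, params, target) {
    counts <- lib$counts
    B <- n_bins(lib$layout)
    for (c in 1:(max(counts) + 1)) {
      obs <- sum(counts >= c)
      if (obs == 0) next
      if (min(1, B * abd_survival(params, c) / obs) <= target) return(c)
    }
    Inf
  }
  set.seed(21)
  for (i in 1:10) {
    counts <- rnbinom(2000, mu = runif(1, 0.5, 4), size = 0.7)
    if (all(counts == 0) || all(counts > 0)) next
    lib <- make_lib(counts)
    params <- estimate_abd(lib)
    target <- sample(c(0.01, 0.05, 0.2), 1)
    call <- suppressWarnings(fdr_threshold(lib, params, target))
    expect_equal(call$count_threshold, brute(lib, params, target))
    if (is.finite(call$count_threshold))
      expect_equal(call$mask, counts >= call$count_threshold)
  }
})

test_that("a library drawn from its own null yields a near-empty mask", {
  set.seed(31)
  B <- 10000
  counts <- 2 * tabulate(sample.int(B, 20000, replace = TRUE), nbins = B)
  lib <- make_lib(counts)
  call <- suppressWarnings(fdr_threshold(lib, estimate_abd(lib), 0.05))
  # every flagged bin is a false discovery; the empirical-FDR construction
  # keeps the flagged set to at most ~5% of the observed tail
  expect_lt(sum(call$mask), 0.01 * B)
  if (is.finite(call$count_threshold))
    expect_lte(call$fdr_at_threshold, 0.05)
})

test_that("planted 100x-mean spikes are all recovered", {
  set.seed(32)
  B <- 10000
  counts <- tabulate(sample.int(B, 30000, replace = TRUE), nbins = B)
  spiked <- sample.int(B, 50)
  counts[spiked] <- round(100 * mean(counts))
  lib <- make_lib(counts)
  call <- fdr_threshold(lib, estimate_abd(lib), 0.05)
  expect_true(all(call$mask[spiked]))
})

test_that("the call threshold is monotone in the FDR target", {
  set.seed(33)
  counts <- rnbinom(5000, mu = 2, size = 0.5)
  lib <- make_lib(counts)
  params <- estimate_abd(lib)
  t_strict <- fdr_threshold(lib, params, 0.05)$count_threshold
  t_loose <- fdr_threshold(lib, params, 0.999)$count_threshold
  expect_lte(t_loose, t_strict)
})

test_that("parameter recovery from simulated amplified libraries", {
  layout <- genome_layout("chr1", 1e8, 1000)   # B = 1e5
  truth <- sim_truth(layout, 0, 0, 0)
  for (a in c(2, 8)) {
    cfg <- sim_config(layout, truth, n_fragments = 5e5, amp = a)
    lib <- simulate_library(cfg, 1, seed = 40 + a)$data
    est <- estimate_abd(lib)
    expect_lt(abs(est$n0 - 5e5) / 5e5, 0.02)
    expect_lt(abs(est$amp - a) / a, 0.02)
  }
})

test_that("abd_survival matches empirical null tail frequencies", {
  set.seed(44)
  B <- 1e5
  n0 <- 5e5
  counts <- 2 * tabulate(sample.int(B, n0, replace = TRUE), nbins = B)
  # evaluate the survival function at the true generating parameters
  params <- structure(list(n0 = n0, amp = 2, bins = B),
                      class = "abd_params")
  m <- mean(counts)
  for (c in round(c(m, 2 * m, 4 * m))) {
    p_emp <- mean(counts >= c)
    p_mod <- abd_survival(params, c)
    se <- sqrt(max(p_mod * (1 - p_mod) / B, 1e-12))
    expect_lt(abs(p_emp - p_mod), 3 * se + 1e-6)
  }
})
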