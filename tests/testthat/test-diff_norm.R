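test_that("the fitted inverse CDF reproduces empirical quantiles", {
  qf <- fit_quantile_function(1:100)
  expect_equal(qf_eval(qf, 0.5), 50.5, tolerance = 0.01)
  expect_equal(qf_eval(qf, 0), 1, tolerance = 0.5)
  expect_equal(qf_eval(qf, 1), 100, tolerance = 0.5)
  # monotone over the whole domain
  v <- qf_eval(qf, seq(0, 1, length.out = 500))
  expect_true(all(diff(v) >= -1e-9))
  # percentile inversion is consistent with evaluation
  expect_equal(qf_percentile(qf, qf_eval(qf, c(0.2, 0.5, 0.8))),
               c(0.2, 0.5, 0.8), tolerance = 0.01)
})

test_that("degenerate quantile-function inputs are refused or flagged", {
  expect_error(fit_quantile_function(1:5), "at least 10")
  expect_warning(qf <- fit_quantile_function(rep(7, 20)), "constant")
  expect_equal(qf_eval(qf, c(0, 0.3, 1)), c(7, 7, 7))
})

test_that("quantile_transform is a rank-preserving map onto the target", {
  x1 <- seq(10, 100, by = 10)
  x2 <- 10 * x1
  qf1 <- fit_quantile_function(x1)
  qf2 <- fit_quantile_function(x2)
  expect_equal(quantile_transform(x1, qf1, qf2), x2, tolerance = 1e-6)
  # identity when both quantile functions coincide
  expect_equal(quantile_transform(x1, qf1, qf1), x1, tolerance = 1e-6)
  # out-of-range values clamp to the target range
  expect_equal(quantile_transform(c(-5, 1e6), qf1, qf2), c(100, 1000),
               tolerance = 1e-6)
})

test_that("transformed values follow the target distribution (KS)", {
  set.seed(7)
  a <- rexp(10000)
  b <- rexp(10000, 5)
  y <- quantile_transform(a, fit_quantile_function(a),
                          fit_quantile_function(b))
  ks <- suppressWarnings(stats::ks.test(y, b)$statistic)
  expect_lt(ks, 0.02)
})

test_that("DHE/CHE labels follow the fold and percentile rules", {
  qf <- fit_quantile_function(1:100)   # identity-scale reference
  x1 <- c(80, 60, 30, 90, 10, 55)
  x2 <- c(20, 55, 95, 88, 10, 54)
  lab <- call_dhe_che(x1, x2, qf, qf, t = 3, percentile_cutoff = 0.5)
  expect_equal(as.character(lab),
               c("DHE_LIB1",   # fold 4, above median in lib1
                 "CHE",        # fold ~1.1, both above median
                 "DHE_LIB2",   # fold < 1/3, x2 above its median
                 "CHE",        # fold ~1
                 "NONE",       # both below median
                 "CHE"))
  # percentile gate: a large fold below the median is not called
  lab2 <- call_dhe_che(c(30), c(5), qf, qf, t = 3)
  expect_equal(as.character(lab2), "NONE")
  # zero denominator: infinite fold is DHE if the gate passes
  lab3 <- call_dhe_che(c(80, 0), c(0, 0), qf, qf, t = 3)
  expect_equal(as.character(lab3), c("DHE_LIB1", "NONE"))
})

test_that("labels are mutually exclusive and symmetric under library swap", {
  set.seed(17)
  x1 <- rpois(500, 30)
  x2 <- rpois(500, 30) + sample(c(0, 60), 500, replace = TRUE)
  qf1 <- fit_quantile_function(x1)
  qf2 <- fit_quantile_function(x2)
  fwd <- call_dhe_che(x1, x2, qf1, qf2, t = 3)
  rev <- call_dhe_che(x2, x1, qf2, qf1, t = 3)
  swap <- c(NONE = "NONE", DHE_LIB1 = "DHE_LIB2", DHE_LIB2 = "DHE_LIB1",
            CHE = "CHE")
  expect_equal(as.character(rev), unname(swap[as.character(fwd)]))
})

test_that("DHE sets shrink as the fold threshold rises", {
  set.seed(18)
  x1 <- rnbinom(2000, mu = 40, size = 3)
  x2 <- rnbinom(2000, mu = 40, size = 3)
  qf1 <- fit_quantile_function(x1)
  qf2 <- fit_quantile_function(x2)
  prev <- NULL
  for (t in c(2, 3, 5, 8)) {
    dhe <- call_dhe_che(x1, x2, qf1, qf2, t = t) %in%
      c("DHE_LIB1", "DHE_LIB2")
    if (!is.null(prev)) expect_true(all(dhe <= prev))
    prev <- dhe
  }
})

test_that("merge_regions groups maximal same-label runs", {
  layout <- genome_layout("chrT", 60, 10)
  lab <- factor(c("DHE_LIB1", "DHE_LIB1", "NONE", "DHE_LIB2", "DHE_LIB2",
                  "DHE_LIB2"),
                levels = c("NONE", "DHE_LIB1", "DHE_LIB2", "CHE"))
  bl <- bin_labels(layout, rep(TRUE, 6), lab)
  r <- merge_regions(bl)
  expect_equal(r$start, c(0, 30))
  expect_equal(r$end, c(20, 60))
  expect_equal(r$label, c("DHE_LIB1", "DHE_LIB2"))

  # all NONE -> empty; alternating labels stay separate
  bl0 <- labels_at(tiny_layout(5), list())
  expect_equal(nrow(merge_regions(bl0)), 0)
  alt <- bin_labels(layout, rep(TRUE, 6),
                    factor(c("DHE_LIB1", "DHE_LIB2", "DHE_LIB1", "NONE",
                             "NONE", "NONE"),
                           levels = levels(lab)))
  expect_equal(nrow(merge_regions(alt)), 3)
})

test_that("merge_regions equals a brute-force run enumeration", {
  oracle <- function(lab, layout) {
    rows <- list()
    for (ci in seq_along(layout$chrom)) {
      nb <- layout$nbins_chrom[ci]
      v <- lab[layout$offset[ci] + seq_len(nb)]
      i <- 1
      while (i <= nb) {
        j <- i
        while (j < nb && v[j + 1] == v[i]) j <- j + 1
        if (v[i] != "NONE")
          rows[[length(rows) + 1]] <- data.frame(
            chrom = layout$chrom[ci],
            start = (i - 1) * layout$bin_size,
            end = min(j * layout$bin_size, layout$length[ci]),
            label = v[i])
        i <- j + 1
      }
    }
    do.call(rbind, rows)
  }
  set.seed(19)
  layout <- genome_layout(c("c1", "c2"), c(25500, 14000), 1000)
  for (rep in 1:20) {
    lab <- sample(c("NONE", "DHE_LIB1", "DHE_LIB2", "CHE"), n_bins(layout),
                  replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1))
    bl <- bin_labels(layout, rep(TRUE, n_bins(layout)),
                     factor(lab, levels = c("NONE", "DHE_LIB1", "DHE_LIB2",
                                            "CHE")))
    got <- as.data.frame(merge_regions(bl))
    want <- oracle(lab, layout)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})
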