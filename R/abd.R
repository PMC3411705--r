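#' Estimate the amplified-binomial null of a library
#'
#' Background fragments captured without antibody specificity scatter
#' over the B bins binomially; PCR multiplies every captured fragment by
#' a constant amplification factor a.  The null ("amplified binomial
#' distribution", ABD) therefore has two parameters: the
#' pre-amplification fragment count n0 and a.  They are identified by
#' matching two observables that amplification leaves unchanged or fixes
#' directly: (i) the number of zero bins, since amplifying cannot
#' create or destroy an empty bin, giving `B (1 - 1/B)^n0 = Z0`, i.e.
#' `n0 = log(Z0/B) / log(1 - 1/B)`; and (ii) the library total,
#' `a = N / n0`.
#'
#' @param lib a [binned_library()] with at least one zero bin and at
#'   least one non-zero bin.
#' @return An object of class `abd_params`: list with `n0` (real > 0),
#'   `amp` (>= 1; estimates below 1, possible under sampling noise, are
#'   clamped with a warning since amplification cannot shrink a
#'   library) and `bins` (B).
#' @examples
#' lib <- binned_library(genome_layout("c", 4000, 1000), c(0, 0, 4, 4))
#' estimate_abd(lib)  # n0 = log(.5)/log(.75), amp = 8/n0
#' @export
estimate_abd <- function(lib) {
  stopifnot(inherits(lib, "binned_library"))
  B <- n_bins(lib$layout)
  if (B < 2) stop("need at least 2 bins")
  Z0 <- zero_bins(lib)
  N <- lib_total(lib)
  if (Z0 == B) stop("empty library")
  if (Z0 == 0)
    stop("null not estimable: no empty bins; use more bins or smaller bins")
  n0 <- log(Z0 / B) / log(1 - 1 / B)
  amp <- N / n0
  if (amp < 1) {
    warning("estimated amplification factor ", signif(amp, 4),
            " < 1; clamped to 1")
    amp <- 1
  }
  structure(list(n0 = n0, amp = amp, bins = B), class = "abd_params")
}

#' @export
print.abd_params <- function(x, ...) {
  cat("<abd_params> n0 = ", signif(x$n0, 6), ", amplification = ",
      signif(x$amp, 6), ", bins = ", x$bins, "\n", sep = "")
  invisible(x)
}

#' Upper-tail probability of the amplified-binomial null
#'
#' P(aX >= c) for X ~ Binomial(n0, 1/B) with real-valued n0: the count
#' threshold is rescaled to the pre-amplification scale, `k =
#' ceiling(c / a)`, and the binomial upper tail P(X >= k) is evaluated
#' through the regularized incomplete beta function
#' `pbeta(1/B, k, n0 - k + 1)`, which extends the integer binomial tail
#' continuously in n0.  Counts themselves are never rescaled, so
#' observed integers stay intact.
#'
#' @param params an [estimate_abd()] result.
#' @param c observed count threshold(s), >= 0 (vectorized).
#' @return survival probabilities in `[0, 1]`, non-increasing in `c`.
#' @export
abd_survival <- function(params, c) {
  stopifnot(inherits(params, "abd_params"), all(c >= 0))
  k <- ceiling(c / params$amp)
  p <- 1 / params$bins
  out <- numeric(length(k))
  out[k <= 0] <- 1
  hi <- k > params$n0         # more successes than trials: impossible
  out[hi] <- 0
  mid <- k > 0 & !hi
  if (any(mid))
    out[mid] <- stats::pbeta(p, k[mid], params$n0 - k[mid] + 1)
  out
}

#' Call significant bins by empirical FDR against the ABD null
#'
#' For an integer count threshold c the empirical false discovery rate
#' is the expected number of null bins at or above c divided by the
#' number observed there: `FDR(c) = B * P(null >= c) / #{i: n_i >= c}`,
#' capped at 1.  The call threshold is the smallest c with `FDR(c) <=
#' target_fdr` and a non-empty observed tail; bins at or above it are
#' flagged significant.
#'
#' @param lib a [binned_library()].
#' @param params its [estimate_abd()] null (estimated from `lib` if
#'   omitted).
#' @param target_fdr FDR bound in (0, 1); 0.05 is the field's standard
#'   cut.
#' @return An object of class `significance_call`: list with
#'   `count_threshold`, `fdr_at_threshold`, and a logical per-bin
#'   `mask`.  When no threshold satisfies the bound the mask is empty
#'   and a warning notes the library is indistinguishable from noise.
#' @export
fdr_threshold <- function(lib, params = estimate_abd(lib), target_fdr = 0.05) {
  stopifnot(inherits(lib, "binned_library"),
            target_fdr > 0, target_fdr < 1)
  counts <- lib$counts
  B <- n_bins(lib$layout)
  cmax <- max(counts)
  cand <- seq_len(cmax + 1)                      # c = 1 .. max + 1
  # observed tail sizes #{counts >= c} for integer c via reverse cumsum
  tab <- tabulate(pmin(floor(counts), cmax + 1) + 1L, nbins = cmax + 2L)
  ge <- rev(cumsum(rev(tab)))                    # ge[c+1] = #{counts >= c}
  obs <- ge[cand + 1L]
  fdr <- pmin(1, B * abd_survival(params, cand) / obs)
  ok <- which(is.finite(fdr) & fdr <= target_fdr & obs > 0)
  if (length(ok) == 0) {
    warning("no count threshold achieves FDR <= ", target_fdr,
            "; library indistinguishable from noise")
    return(structure(list(count_threshold = Inf, fdr_at_threshold = NA_real_,
                          mask = rep(FALSE, B)),
                     class = "significance_call"))
  }
  c0 <- cand[ok[1]]
  structure(list(count_threshold = c0, fdr_at_threshold = fdr[ok[1]],
                 mask = counts >= c0),
            class = "significance_call")
}

#' @export
print.significance_call <- function(x, ...) {
  cat("<significance_call> threshold = ", x$count_threshold,
      ", FDR at threshold = ", signif(x$fdr_at_threshold, 4), ", ",
      sum(x$mask), " significant bin(s)\n", sep = "")
  invisible(x)
}
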