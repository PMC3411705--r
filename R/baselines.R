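# fold-only labels shared by the baseline callers (no percentile gate)
fold_labels <- function(y1, x2, t) {
  fold <- ifelse(y1 == 0 & x2 == 0, NA_real_,
                 ifelse(x2 == 0, Inf, y1 / x2))
  lab <- rep("NONE", length(y1))
  lab[!is.na(fold) & fold >= t] <- "DHE_LIB1"
  lab[!is.na(fold) & fold <= 1 / t] <- "DHE_LIB2"
  factor(lab, levels = c("NONE", "DHE_LIB1", "DHE_LIB2", "CHE"))
}

#' Unit-mean baseline: trimmed-mean scaling plus fold change
#'
#' Each library is divided by its trimmed mean — the mean over its
#' non-zero bins, in the manner of the classic microarray scaling
#' method — and a bin is labeled differential toward the library whose
#' scaled value exceeds the other's by at least `t`.  No noise
#' filtering, no percentile gate.
#'
#' @param lib1,lib2 [binned_library()] objects on one layout.
#' @param t fold threshold (> 1).
#' @return a [bin_labels()] object over all bins.
#' @export
unit_mean_call <- function(lib1, lib2, t = 3) {
  stopifnot(t > 1)
  check_same_layout(lib1, lib2)
  tm <- function(x) {
    if (all(x == 0)) stop("all-zero library: trimmed mean undefined")
    mean(x[x > 0])
  }
  n1 <- lib1$counts / tm(lib1$counts)
  n2 <- lib2$counts / tm(lib2$counts)
  lab <- fold_labels(n1, n2, t)
  bin_labels(lib1$layout, rep(TRUE, length(lab)), lab, y1 = n1, x2 = n2)
}

#' Quantile-only baseline: full-genome quantile transform plus fold
#'
#' Library 1 is quantile-mapped onto library 2's scale over all bins
#' (no stage-1 filtering) and bins are labeled by fold change alone.
#'
#' @inheritParams unit_mean_call
#' @return a [bin_labels()] object over all bins.
#' @export
quantile_only_call <- function(lib1, lib2, t = 3) {
  stopifnot(t > 1)
  check_same_layout(lib1, lib2)
  qf1 <- fit_quantile_function(lib1$counts)
  qf2 <- fit_quantile_function(lib2$counts)
  y1 <- quantile_transform(lib1$counts, qf1, qf2)
  lab <- fold_labels(y1, lib2$counts, t)
  bin_labels(lib1$layout, rep(TRUE, length(lab)), lab,
             y1 = y1, x2 = lib2$counts)
}

#' Rank baseline: decile assignment plus decile-difference threshold
#'
#' Bin values of each library are replaced by their decile index (1-10
#' within that library, equal partitions of the sorted list, ties by
#' average rank); a bin is labeled differential toward the library
#' whose decile exceeds the other's by more than `d` decile units.
#'
#' @inheritParams unit_mean_call
#' @param d decile-difference threshold (> 0).
#' @return a [bin_labels()] object over all bins.
#' @export
rank_call <- function(lib1, lib2, d = 2) {
  stopifnot(d > 0)
  check_same_layout(lib1, lib2)
  decile <- function(x) ceiling(10 * rank(x, ties.method = "average") /
                                  length(x))
  d1 <- decile(lib1$counts)
  d2 <- decile(lib2$counts)
  lab <- rep("NONE", length(d1))
  lab[d1 - d2 > d] <- "DHE_LIB1"
  lab[d2 - d1 > d] <- "DHE_LIB2"
  lab <- factor(lab, levels = c("NONE", "DHE_LIB1", "DHE_LIB2", "CHE"))
  bin_labels(lib1$layout, rep(TRUE, length(lab)), lab, y1 = d1, x2 = d2)
}

#' Two-stage unit-mean baseline
#'
#' Unit-mean scaling and fold-change labeling restricted to the stage-2
#' bin set produced by the noise- and bias-removal stage; trimmed means
#' are computed over the non-zero stage-2 bins only.
#'
#' @inheritParams unit_mean_call
#' @param stage2 logical stage-2 membership from [stage2_bin_set()].
#' @return a [bin_labels()] object; bins outside the stage-2 set are
#'   `NONE`.
#' @export
two_stage_unit_mean_call <- function(lib1, lib2, stage2, t = 3) {
  stopifnot(t > 1, length(stage2) == n_bins(lib1$layout))
  check_same_layout(lib1, lib2)
  if (!any(stage2)) {
    return(bin_labels(lib1$layout, stage2,
                      factor(levels = c("NONE", "DHE_LIB1", "DHE_LIB2",
                                        "CHE"))))
  }
  x1 <- lib1$counts[stage2]
  x2 <- lib2$counts[stage2]
  tm <- function(x) if (all(x == 0)) 1 else mean(x[x > 0])
  n1 <- x1 / tm(x1)
  n2 <- x2 / tm(x2)
  bin_labels(lib1$layout, stage2, fold_labels(n1, n2, t), y1 = n1, x2 = n2)
}
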