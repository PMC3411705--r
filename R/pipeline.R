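#' Full two-stage differential enrichment call
#'
#' Runs the complete method on two ChIP libraries and their input-DNA
#' controls.  Stage one, per library: significant bins against the
#' amplified-binomial null ([fdr_threshold()]) and control-enriched
#' bins ([iterative_normalize_control()]); their conjunction is the
#' enriched-significant set, and the union over the two libraries is
#' the stage-2 working set, carried forward with original bincounts.
#' Stage two: quantile functions are fitted on the stage-2 values of
#' each library, library 1 is mapped onto library 2's scale, and bins
#' are labeled DHE/CHE by [call_dhe_che()], then merged into regions.
#'
#' @param lib1,lib2 the two ChIP [binned_library()] objects (same
#'   layout).
#' @param ctrl1,ctrl2 matching input-DNA controls.
#' @param target_fdr stage-1 FDR bound (default 0.05).
#' @param control_fold control-enrichment fold cut (default 2).
#' @param control_iters control-normalization iterations (default 2).
#' @param t stage-2 fold-change threshold (default 3).
#' @param percentile_cutoff stage-2 percentile gate (default 0.5).
#' @return An object of class `quantdiff_fit`: list with the per-library
#'   stage-1 results (`abd1`, `abd2`, `sig1`, `sig2`, `enr1`, `enr2`,
#'   `es1`, `es2`), the logical `stage2` set, the [bin_labels()]
#'   `labels`, the merged `regions`, and the parameters used.
#' @export
quantdiff <- function(lib1, ctrl1, lib2, ctrl2,
                      target_fdr = 0.05, control_fold = 2,
                      control_iters = 2, t = 3, percentile_cutoff = 0.5) {
  check_same_layout(lib1, lib2)
  check_same_layout(lib1, ctrl1)
  check_same_layout(lib2, ctrl2)
  layout <- lib1$layout

  abd1 <- estimate_abd(lib1)
  abd2 <- estimate_abd(lib2)
  sig1 <- fdr_threshold(lib1, abd1, target_fdr)
  sig2 <- fdr_threshold(lib2, abd2, target_fdr)
  enr1 <- iterative_normalize_control(lib1, ctrl1, control_fold, control_iters)
  enr2 <- iterative_normalize_control(lib2, ctrl2, control_fold, control_iters)
  es1 <- enriched_significant(sig1, enr1)
  es2 <- enriched_significant(sig2, enr2)
  stage2 <- stage2_bin_set(es1, es2)

  if (sum(stage2) < 10) {
    if (sum(stage2) > 0)
      warning("fewer than 10 stage-2 bins; no differential calls made")
    labels <- bin_labels(layout, rep(FALSE, n_bins(layout)), factor(levels =
      c("NONE", "DHE_LIB1", "DHE_LIB2", "CHE")))
  } else {
    x1 <- lib1$counts[stage2]
    x2 <- lib2$counts[stage2]
    qf1 <- fit_quantile_function(x1)
    qf2 <- fit_quantile_function(x2)
    lab2 <- call_dhe_che(x1, x2, qf1, qf2, t, percentile_cutoff)
    y1 <- quantile_transform(x1, qf1, qf2)
    labels <- bin_labels(layout, stage2, lab2, y1 = y1, x2 = x2)
  }
  structure(list(abd1 = abd1, abd2 = abd2, sig1 = sig1, sig2 = sig2,
                 enr1 = enr1, enr2 = enr2, es1 = es1, es2 = es2,
                 stage2 = stage2, labels = labels,
                 regions = merge_regions(labels),
                 params = list(target_fdr = target_fdr,
                               control_fold = control_fold,
                               control_iters = control_iters, t = t,
                               percentile_cutoff = percentile_cutoff)),
            class = "quantdiff_fit")
}

#' @export
print.quantdiff_fit <- function(x, ...) {
  tb <- table(x$labels$labels)
  cat("<quantdiff_fit>\n",
      "  stage 1: ", sum(x$es1), " / ", sum(x$es2),
      " enriched-significant bins (lib1 / lib2)\n",
      "  stage 2: ", sum(x$stage2), " bins; DHE_LIB1 ", tb[["DHE_LIB1"]],
      ", DHE_LIB2 ", tb[["DHE_LIB2"]], ", CHE ", tb[["CHE"]], "\n",
      "  regions: ", nrow(x$regions), "\n", sep = "")
  invisible(x)
}
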