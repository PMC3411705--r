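# Rank-match quantile map fitted on a subset, applied everywhere.
# Fitted pairs are (sorted control, sorted data) over the fitting bins;
# between fitted quantiles we interpolate linearly, beyond the fitted
# range we extrapolate flat (rule = 2), and tied control values share
# the mean of their rank range (ties = mean).  A constant control has
# no rank structure, so every bin maps to the mean fitted data value.
fit_rank_map <- function(ctrl_fit, data_fit) {
  xs <- sort(ctrl_fit)
  ys <- sort(data_fit)
  if (length(unique(xs)) < 2) {
    warning("constant control values: quantile map degenerates to the mean")
    m <- mean(ys)
    return(function(v) rep(m, length(v)))
  }
  function(v) stats::approx(xs, ys, xout = v, ties = mean, rule = 2)$y
}

#' Normalize an input-DNA control by iterative quantile mapping
#'
#' Local genomic bias (open chromatin, mappability, amplified repeats)
#' affects a ChIP library and its input-DNA control alike, so bins truly
#' carrying signal are those enriched relative to the normalized
#' control.  A single quantile normalization is distorted when the
#' fraction of enriched bins is large (it can exceed half the genome),
#' which is why the fit is iterated: each round (1) fits the quantile
#' map of control onto data using only bins not currently flagged as
#' outliers, then applies the fitted map to all bins, and (2) flags
#' bins whose fold change data / mapped-control reaches
#' `fold_threshold` as outliers.  Outlier flags are recomputed from the
#' current folds each round, and the final flag set is the enrichment
#' mask.  Only the control is ever transformed; the data library is
#' left untouched.
#'
#' @param data the ChIP [binned_library()].
#' @param control the input-DNA control on the same layout.
#' @param fold_threshold enrichment fold cut (> 1; default 2, the
#'   conventional enrichment cut).
#' @param iterations number of fit/flag rounds (>= 1; default 2).
#' @return An object of class `enrichment_call`: list with
#'   `normalized_control`, per-bin `fold` (data 0 gives 0; mapped
#'   control 0 with data > 0 gives `Inf`), logical `mask`, and
#'   `iterations_run`.
#' @export
iterative_normalize_control <- function(data, control, fold_threshold = 2,
                                        iterations = 2) {
  stopifnot(inherits(data, "binned_library"),
            inherits(control, "binned_library"),
            fold_threshold > 1, iterations >= 1)
  check_same_layout(data, control)
  x <- data$counts
  ctl <- control$counts
  flagged <- rep(FALSE, length(x))
  mapped <- ctl
  for (k in seq_len(iterations)) {
    if (all(flagged))
      stop("all bins flagged as control outliers: control unusable")
    map <- fit_rank_map(ctl[!flagged], x[!flagged])
    mapped <- map(ctl)
    fold <- ifelse(x == 0, 0, ifelse(mapped == 0, Inf, x / mapped))
    flagged <- fold >= fold_threshold
  }
  structure(list(normalized_control = mapped, fold = fold, mask = flagged,
                 iterations_run = iterations),
            class = "enrichment_call")
}

#' @export
print.enrichment_call <- function(x, ...) {
  cat("<enrichment_call> ", sum(x$mask), " enriched bin(s) after ",
      x$iterations_run, " iteration(s)\n", sep = "")
  invisible(x)
}

#' Enriched-significant bins: noise test AND control test
#'
#' A bin survives stage one only if it is both significant against the
#' amplified-binomial null ([fdr_threshold()]) and enriched relative to
#' the normalized control ([iterative_normalize_control()]).
#'
#' @param sig a `significance_call`.
#' @param enr an `enrichment_call` on the same layout.
#' @return logical per-bin vector.
#' @export
enriched_significant <- function(sig, enr) {
  stopifnot(length(sig$mask) == length(enr$mask))
  sig$mask & enr$mask
}

#' Stage-2 working set: union over the two libraries
#'
#' Bins enriched-significant in either library are passed to stage two
#' with their original bincount values.
#'
#' @param es1,es2 logical enriched-significant vectors of the two
#'   libraries.
#' @return logical per-bin vector.
#' @export
stage2_bin_set <- function(es1, es2) {
  stopifnot(length(es1) == length(es2))
  es1 | es2
}
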