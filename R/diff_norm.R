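#' Fit a smoothed empirical inverse CDF (quantile function)
#'
#' The percentile-to-value curve of a set of bin values, smoothed with a
#' monotone piecewise-cubic spline (`monoH.FC`) through
#' percentile-spaced knots of the empirical inverse CDF.  Monotone
#' Hermite interpolation is used because a generic smoothing spline can
#' oscillate and break the ordering a quantile function must preserve;
#' knots are placed every percentile (or at every data point when there
#' are fewer than 101 values) so that heavy-tailed count distributions
#' are reproduced faithfully.
#'
#' @param values numeric vector, at least 10 values (fewer is refused:
#'   a quantile curve through a handful of points is meaningless).
#' @return An object of class `quantile_function` supporting
#'   [qf_eval()] (percentile to value) and [qf_percentile()] (value to
#'   percentile).
#' @examples
#' qf <- fit_quantile_function(1:100)
#' qf_eval(qf, 0.5)  # ~ 50.5
#' @export
fit_quantile_function <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 10)
    stop("need at least 10 values to fit a quantile function; got ",
         length(values))
  if (anyNA(values)) stop("values must not contain NA")
  if (diff(range(values)) == 0) {
    warning("constant input: quantile function degenerates to a constant")
    v <- values[1]
    return(structure(list(constant = v,
                          grid_p = c(0, 1), grid_v = c(v, v)),
                     class = "quantile_function"))
  }
  probs <- if (length(values) <= 101) stats::ppoints(length(values), a = 0.5)
           else seq(0, 1, by = 0.01)
  probs <- sort(unique(c(0, probs, 1)))
  knots <- stats::quantile(values, probs = probs, names = FALSE, type = 7)
  fun <- stats::splinefun(probs, knots, method = "monoH.FC")
  grid_p <- seq(0, 1, length.out = 2001)
  grid_v <- cummax(fun(grid_p))   # guard vs. rounding-level dips
  structure(list(fun = fun, knots_p = probs, knots_v = knots,
                 grid_p = grid_p, grid_v = grid_v),
            class = "quantile_function")
}

#' Evaluate a quantile function
#' @param qf a [fit_quantile_function()] object.
#' @param p percentiles; values outside `[0, 1]` are clamped.
#' @return fitted bin values, non-decreasing in `p`.
#' @export
qf_eval <- function(qf, p) {
  stopifnot(inherits(qf, "quantile_function"))
  p <- pmin(1, pmax(0, p))
  if (!is.null(qf$constant)) return(rep(qf$constant, length(p)))
  qf$fun(p)
}

#' Percentile of a value under a fitted quantile function
#'
#' Numerical inverse of [qf_eval()] on a fine percentile grid; values
#' in a flat (tied) stretch of the curve receive the mean percentile of
#' the stretch, values outside the fitted range clamp to 0 or 1.
#' @inheritParams qf_eval
#' @param x bin values.
#' @return percentiles in `[0, 1]`.
#' @export
qf_percentile <- function(qf, x) {
  stopifnot(inherits(qf, "quantile_function"))
  if (!is.null(qf$constant)) return(rep(0.5, length(x)))
  stats::approx(qf$grid_v, qf$grid_p, xout = x, ties = mean, rule = 2)$y
}

#' @export
print.quantile_function <- function(x, ...) {
  if (!is.null(x$constant))
    cat("<quantile_function> constant at", x$constant, "\n")
  else
    cat("<quantile_function> ", length(x$knots_p), " knots, range [",
        signif(min(x$knots_v), 4), ", ", signif(max(x$knots_v), 4), "]\n",
        sep = "")
  invisible(x)
}

#' Map library-1 values onto library 2's scale
#'
#' The normalizing transform f with `f(F1^-1(p)) = F2^-1(p)`: each value
#' is carried to its percentile under `qf1` and re-expressed through
#' `qf2`, after which the transformed values follow library 2's
#' distribution.  Values outside `qf1`'s fitted range evaluate at the
#' clamped percentile 0 or 1.
#'
#' @param x values of library 1.
#' @param qf1,qf2 [fit_quantile_function()] fits of libraries 1 and 2
#'   (on the stage-2 bin values for the two-stage method).
#' @return transformed values on library 2's scale; non-decreasing in
#'   `x`.
#' @export
quantile_transform <- function(x, qf1, qf2) {
  qf_eval(qf2, qf_percentile(qf1, x))
}

#' Label stage-2 bins as DHE, CHE or neither
#'
#' A bin is differentially enriched toward library 1 (`DHE_LIB1`) if
#' (i) its library-1 value sits above the `percentile_cutoff` of
#' library 1's own inverse CDF and (ii) its library-1 value mapped to
#' library 2's scale, `y1`, exceeds the library-2 value at least
#' `t`-fold (`y1 / x2 >= t`).  `DHE_LIB2` is the mirror image: the
#' library-2 percentile clears the cutoff and `y2 / x1 >= t`, with
#' `y2` the library-2 value on library 1's scale.  Each direction's
#' fold is thus judged after mapping the candidate library onto the
#' other's scale, which makes the labeling exactly symmetric under
#' swapping the libraries.  A bin is constitutively highly enriched
#' (`CHE`) when both percentiles clear the cutoff and neither fold
#' reaches `t` (the fold change stays inside `(1/t, t)`).  The
#' percentile gate reflects the stage-2 union: were the two libraries
#' independent, about half the stage-2 bins would be
#' enriched-significant in a given library, so the gate sits at the
#' median by default.  Zero denominators follow the `Inf` fold
#' convention; no pseudocounts are added because stage-1 filtering
#' makes true zeros rare in the stage-2 set.
#'
#' @param x1,x2 stage-2 bin counts of libraries 1 and 2 (equal length).
#' @param qf1,qf2 quantile functions fitted on `x1` and `x2`.
#' @param t fold-change threshold (> 1; default 3).
#' @param percentile_cutoff gate in `[0, 1)` (default 0.5, the median).
#' @return factor with levels `NONE`, `DHE_LIB1`, `DHE_LIB2`, `CHE`;
#'   labels are mutually exclusive by construction.
#' @export
call_dhe_che <- function(x1, x2, qf1 = fit_quantile_function(x1),
                         qf2 = fit_quantile_function(x2),
                         t = 3, percentile_cutoff = 0.5) {
  stopifnot(length(x1) == length(x2), t > 1,
            percentile_cutoff >= 0, percentile_cutoff < 1)
  p1 <- qf_percentile(qf1, x1)
  p2 <- qf_percentile(qf2, x2)
  y1 <- qf_eval(qf2, p1)
  y2 <- qf_eval(qf1, p2)
  fold_to <- function(num, den)            # fold with Inf/NA conventions
    ifelse(num == 0 & den == 0, NA_real_,
           ifelse(den == 0, Inf, num / den))
  f1 <- fold_to(y1, x2)
  f2 <- fold_to(y2, x1)
  d1_raw <- !is.na(f1) & p1 > percentile_cutoff & f1 >= t
  d2_raw <- !is.na(f2) & p2 > percentile_cutoff & f2 >= t
  # a monotone pair of quantile functions cannot satisfy both fold rules
  # at once except in degenerate smoothing corner cases; drop such bins
  # symmetrically rather than pick a side
  d1 <- d1_raw & !d2_raw
  d2 <- d2_raw & !d1_raw
  che <- !d1 & !d2 & p1 > percentile_cutoff & p2 > percentile_cutoff &
    !(is.na(f1) & is.na(f2))
  lab <- rep("NONE", length(x1))
  lab[d1] <- "DHE_LIB1"
  lab[d2] <- "DHE_LIB2"
  lab[che] <- "CHE"
  factor(lab, levels = c("NONE", "DHE_LIB1", "DHE_LIB2", "CHE"))
}

#' Assemble genome-wide bin labels from a stage-2 call
#'
#' @param layout a [genome_layout()].
#' @param stage2 logical stage-2 membership per bin.
#' @param stage2_labels factor from [call_dhe_che()] over the stage-2
#'   bins (in bin order).
#' @param y1,x2 optional normalized values over the stage-2 bins,
#'   stored for inspection.
#' @return An object of class `bin_labels`: list with `layout`,
#'   per-bin factor `labels` (bins outside the stage-2 set are
#'   `NONE`), logical `stage2`, and full-length `y1`, `x2` (NA outside
#'   the stage-2 set).
#' @export
bin_labels <- function(layout, stage2, stage2_labels, y1 = NULL, x2 = NULL) {
  B <- n_bins(layout)
  stopifnot(length(stage2) == B, sum(stage2) == length(stage2_labels))
  lab <- factor(rep("NONE", B),
                levels = c("NONE", "DHE_LIB1", "DHE_LIB2", "CHE"))
  lab[stage2] <- stage2_labels
  full <- function(v) {
    if (is.null(v)) return(rep(NA_real_, B))
    out <- rep(NA_real_, B); out[stage2] <- v; out
  }
  structure(list(layout = layout, labels = lab, stage2 = stage2,
                 y1 = full(y1), x2 = full(x2)),
            class = "bin_labels")
}

#' @export
print.bin_labels <- function(x, ...) {
  tb <- table(x$labels)
  cat("<bin_labels> ", sum(x$stage2), "/", length(x$labels),
      " bins evaluated; DHE_LIB1 ", tb[["DHE_LIB1"]], ", DHE_LIB2 ",
      tb[["DHE_LIB2"]], ", CHE ", tb[["CHE"]], "\n", sep = "")
  invisible(x)
}

#' Merge adjacent same-label bins into regions
#'
#' Maximal runs of identical non-`NONE` labels within a chromosome
#' become one region; coordinates are multiples of the bin size except
#' at chromosome ends, where the last bin truncates.
#'
#' @param labels a [bin_labels()] object.
#' @return `data.table` with `chrom`, `start`, `end`, `label`, ordered
#'   by genome position.
#' @export
merge_regions <- function(labels) {
  stopifnot(inherits(labels, "bin_labels"))
  layout <- labels$layout
  lab <- as.character(labels$labels)
  out <- vector("list", length(layout$chrom))
  for (ci in seq_along(layout$chrom)) {
    nb <- layout$nbins_chrom[ci]
    v <- lab[layout$offset[ci] + seq_len(nb)]
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths
    keep <- r$values != "NONE"
    if (!any(keep)) next
    out[[ci]] <- data.table::data.table(
      chrom = layout$chrom[ci],
      start = starts_bin[keep] * layout$bin_size,
      end = pmin(ends_bin[keep] * layout$bin_size, layout$length[ci]),
      label = r$values[keep])
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0)
    res <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), label = character())
  res[]
}
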