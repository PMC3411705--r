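#' Construct a gene set (TSS records)
#'
#' @param gene_id character; a gene may appear on several rows, one per
#'   alternative promoter (all promoters of a gene are considered).
#' @param chrom,tss chromosome and 0-based transcription start site.
#' @param strand `+` or `-`.
#' @return `data.table` of class `gene_set`.
#' @export
gene_set <- function(gene_id, chrom, tss, strand = "+") {
  dt <- data.table::data.table(gene_id = as.character(gene_id),
                               chrom = as.character(chrom),
                               tss = as.numeric(tss),
                               strand = strand)
  data.table::setattr(dt, "class", c("gene_set", class(dt)))
  dt
}

#' Read genes from a BED-like file (chrom, tss, strand, gene id)
#' @param path TSV with columns chrom, tss, gene_id, strand (no header).
#' @return a [gene_set()].
#' @export
read_genes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  gene_set(dt[[3]], dt[[1]], dt[[2]],
           if (ncol(dt) >= 4) as.character(dt[[4]]) else "+")
}

#' Read a two-condition expression table
#' @param path TSV with columns gene_id, expr_cond1, expr_cond2 (no
#'   header).
#' @return `data.table` with those columns.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, header = FALSE,
                          col.names = c("gene_id", "expr_cond1",
                                        "expr_cond2"),
                          colClasses = list(character = 1))
  if (anyDuplicated(dt$gene_id)) stop("duplicate gene ids in expression table")
  dt
}

# which labels occur in any promoter window (TSS +/- halfwidth,
# half-open) of each gene; union over a gene's TSS records
promoter_states <- function(labels, genes, halfwidth = 1000) {
  stopifnot(inherits(labels, "bin_labels"))
  layout <- labels$layout
  bs <- layout$bin_size
  ci <- match(genes$chrom, layout$chrom)
  lab <- labels$labels
  n <- nrow(genes)
  d1 <- d2 <- che <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(ci[i])) next
    lo <- max(0, genes$tss[i] - halfwidth)
    hi <- min(layout$length[ci[i]], genes$tss[i] + halfwidth)
    if (hi <= lo) next
    bins <- layout$offset[ci[i]] + (floor(lo / bs):floor((hi - 1) / bs)) + 1
    s <- lab[bins]
    d1[i] <- any(s == "DHE_LIB1")
    d2[i] <- any(s == "DHE_LIB2")
    che[i] <- any(s == "CHE")
  }
  dt <- data.table::data.table(gene_id = genes$gene_id,
                               d1 = d1, d2 = d2, che = che)
  dt[, .(has_d1 = any(d1), has_d2 = any(d2), has_che = any(che)),
     by = gene_id]
}

# expression fold ratios with a pseudocount guarding zero expression
expr_fold <- function(expr, pseudocount = 1) {
  (expr$expr_cond2 + pseudocount) / (expr$expr_cond1 + pseudocount)
}

#' Mean enrichment per gene-density class
#'
#' Tiles the genome into `window`-sized regions, ranks them by how many
#' TSS they contain, splits the ranked list into `classes` groups of
#' near-equal occupancy (sizes differ by at most one window), and
#' reports the mean per-window total of `values` within each class.
#' With per-bin fragment counts this profiles raw coverage against gene
#' density; with a 0/1 differential-call indicator it profiles where a
#' caller places its calls.
#'
#' @param values per-bin numeric vector on `layout` (counts or label
#'   indicator).
#' @param layout a [genome_layout()].
#' @param genes a [gene_set()].
#' @param window region size in bp (default 1 Mbp: large enough to hold
#'   a meaningful number of genes, small enough to resolve the trend).
#' @param classes number of gene-density classes (default 10).
#' @return `data.table` with `class` (1 = gene-poorest), `n_windows`,
#'   `mean_genes`, `mean_value`.
#' @export
gene_density_profile <- function(values, layout, genes, window = 1e6,
                                 classes = 10) {
  stopifnot(classes >= 2, length(values) == n_bins(layout))
  wd <- window_density(values, layout, window)
  # count TSS per window
  widx <- wd$wstart_index[match(
    paste(genes$chrom, floor(genes$tss / window)),
    paste(wd$chrom, wd$window_index))]
  gcount <- tabulate(widx[!is.na(widx)], nbins = nrow(wd))
  nw <- nrow(wd)
  if (nw < classes)
    stop("fewer windows (", nw, ") than classes (", classes, ")")
  ord <- order(gcount, seq_len(nw))      # stable: ties by position
  sizes <- diff(round(seq(0, nw, length.out = classes + 1)))
  cls <- rep(seq_len(classes), sizes)
  data.table::data.table(
    class = seq_len(classes),
    n_windows = as.integer(sizes),
    mean_genes = as.numeric(tapply(gcount[ord], cls, mean)),
    mean_value = as.numeric(tapply(wd$value[ord], cls, mean)))
}

#' Per-window totals of a per-bin quantity
#'
#' Helper underlying [gene_density_profile()]; also convenient for
#' correlating call density with planted-signal density.
#'
#' @inheritParams gene_density_profile
#' @return `data.table` with `chrom`, `window_index` (within
#'   chromosome), `value` (sum of `values` over the window's bins) and
#'   `wstart_index` (genome-wide window number).
#' @export
window_density <- function(values, layout, window = 1e6) {
  stopifnot(length(values) == n_bins(layout))
  out <- vector("list", length(layout$chrom))
  wtot <- 0L
  for (ci in seq_along(layout$chrom)) {
    nb <- layout$nbins_chrom[ci]
    starts <- (seq_len(nb) - 1) * layout$bin_size
    wi <- floor(starts / window)
    v <- values[layout$offset[ci] + seq_len(nb)]
    agg <- tapply(v, wi, sum)
    out[[ci]] <- data.table::data.table(
      chrom = layout$chrom[ci],
      window_index = as.integer(names(agg)),
      value = as.numeric(agg),
      wstart_index = wtot + seq_along(agg))
    wtot <- wtot + length(agg)
  }
  data.table::rbindlist(out)[]
}

#' Promoter sensitivity and error against differential expression
#'
#' For a repressive mark carried by library 1 (condition 1), genes at
#' least `fold`-fold over-expressed in condition 2 should show
#' condition-1 differential enrichment at their promoters.
#' Sensitivity on that gene group is the percentage with at least one
#' `DHE_LIB1` bin overlapping any promoter window (TSS +/-
#' `halfwidth`); the error is the percentage instead showing a
#' `DHE_LIB2` bin.  The symmetric tallies are reported for genes
#' over-expressed in condition 1.  A gene with several TSS records
#' counts once if any promoter qualifies.
#'
#' @param labels a [bin_labels()] object.
#' @param genes a [gene_set()].
#' @param expr expression table (`gene_id`, `expr_cond1`,
#'   `expr_cond2`).
#' @param fold expression fold cut for selecting genes (default 4).
#' @param halfwidth promoter half-width in bp (default 1000).
#' @param pseudocount added to both expression values before the ratio.
#' @return `data.table` with one row per side (`cond2_over`,
#'   `cond1_over`): `n_genes`, `sensitivity_pct`, `error_pct`.
#' @export
promoter_sensitivity <- function(labels, genes, expr, fold = 4,
                                 halfwidth = 1000, pseudocount = 1) {
  stopifnot(fold > 1)
  st <- promoter_states(labels, genes, halfwidth)
  dt <- merge(expr, st, by = "gene_id")
  r <- expr_fold(dt, pseudocount)
  sel2 <- r >= fold          # over-expressed in condition 2
  sel1 <- r <= 1 / fold      # over-expressed in condition 1
  if (!any(sel2) && !any(sel1))
    stop("no gene passes the ", fold, "-fold expression filter (",
         nrow(dt), " genes tested)")
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  data.table::data.table(
    side = c("cond2_over", "cond1_over"),
    n_genes = c(sum(sel2), sum(sel1)),
    sensitivity_pct = c(pct(dt$has_d1[sel2]), pct(dt$has_d2[sel1])),
    error_pct = c(pct(dt$has_d2[sel2]), pct(dt$has_d1[sel1])))
}

#' ROC points over a sweep of call thresholds
#'
#' The three-way decision (enriched toward 1, toward 2, neither) is
#' folded into two one-sided problems.  First side: class 1 is the
#' genes at least `fold`-fold over-expressed in condition 2, class 0
#' the rest; a gene tests positive when a `DHE_LIB1` bin overlaps its
#' promoter (repressive-mark convention).  Second side: class 1 is the
#' condition-1 over-expressed genes, positives are `DHE_LIB2`
#' promoters.  One (FPR, TPR) point is produced per supplied label set,
#' in the order given (typically a decreasing-threshold sweep).
#'
#' @param labels_list list of [bin_labels()] objects, one per
#'   threshold.
#' @inheritParams promoter_sensitivity
#' @return `data.table` with `side`, `threshold_index`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels_list, genes, expr, fold = 4,
                       halfwidth = 1000, pseudocount = 1) {
  stopifnot(length(labels_list) >= 1)
  res <- vector("list", length(labels_list))
  for (k in seq_along(labels_list)) {
    st <- promoter_states(labels_list[[k]], genes, halfwidth)
    dt <- merge(expr, st, by = "gene_id")
    r <- expr_fold(dt, pseudocount)
    one_side <- function(class1, pos) {
      if (!any(class1)) stop("empty class 1: no gene passes the filter")
      data.table::data.table(
        tpr = sum(class1 & pos) / sum(class1),
        fpr = sum(!class1 & pos) / sum(!class1))
    }
    s1 <- one_side(r >= fold, dt$has_d1)
    s2 <- one_side(r <= 1 / fold, dt$has_d2)
    res[[k]] <- data.table::data.table(
      side = c(1L, 2L), threshold_index = k,
      fpr = c(s1$fpr, s2$fpr), tpr = c(s1$tpr, s2$tpr))
  }
  data.table::rbindlist(res)[]
}

#' Replicate false-positive rate
#'
#' When the two libraries are replicates of one sample no bin should be
#' differential, so every DHE call is a false positive.  Returns the
#' percentage of evaluated bins (the stage-2 set for the two-stage
#' method, all bins for the baselines) carrying a DHE label.
#'
#' @param labels a [bin_labels()] object from a replicate-pair run.
#' @return percentage in `[0, 100]`.
#' @export
replicate_fpr <- function(labels) {
  stopifnot(inherits(labels, "bin_labels"))
  n_eval <- sum(labels$stage2)
  if (n_eval == 0) return(0)
  100 * sum(labels$labels %in% c("DHE_LIB1", "DHE_LIB2")) / n_eval
}

#' Classify genes into promoter types 1-4 for one mark
#'
#' Type 1: no DHE or CHE bin in any promoter window.  Type 2: at least
#' one `DHE_LIB1` bin but no CHE and no `DHE_LIB2`.  Type 4: the
#' mirror image.  Type 3: at least one CHE bin, or DHE bins of both
#' directions.  The four types are exhaustive and mutually exclusive.
#'
#' @inheritParams promoter_sensitivity
#' @return `data.table` with `gene_id`, `type` (integer 1-4).
#' @export
classify_gene_types <- function(labels, genes, halfwidth = 1000) {
  st <- promoter_states(labels, genes, halfwidth)
  type <- ifelse(!st$has_d1 & !st$has_d2 & !st$has_che, 1L,
          ifelse(st$has_che | (st$has_d1 & st$has_d2), 3L,
          ifelse(st$has_d1, 2L, 4L)))
  data.table::data.table(gene_id = st$gene_id, type = type)
}

#' Sixteen-class bivalent promoter states across two cell types
#'
#' Given differential calls for the repressive (K27) and activating
#' (K4) marks between the same two cell types, each promoter gets a
#' per-cell state in \{none, K4, K27, K4+K27\} and the combined label
#' "state1-state2".  A mark is present in cell 1 when a `DHE_LIB1` or
#' `CHE` bin of that mark overlaps a promoter window, and in cell 2
#' when a `DHE_LIB2` or `CHE` bin does; detected but depleted marks
#' count as absent.  The marks may be binned at different resolutions
#' (their layouts need not match).
#'
#' @param k27,k4 [bin_labels()] objects for the two marks (library 1 =
#'   cell 1, library 2 = cell 2 in both).
#' @inheritParams promoter_sensitivity
#' @return `data.table` with `gene_id`, `state1`, `state2`, `class`
#'   (factor over the 16 combined labels; `K4+K27-*` labels are the
#'   bivalent-in-cell-1 classes).
#' @export
bivalent_classes <- function(k27, k4, genes, halfwidth = 1000) {
  s27 <- promoter_states(k27, genes, halfwidth)
  s4 <- promoter_states(k4, genes, halfwidth)
  dt <- merge(s27, s4, by = "gene_id", suffixes = c("_k27", "_k4"))
  state <- function(k4p, k27p)
    ifelse(k4p & k27p, "K4+K27", ifelse(k4p, "K4", ifelse(k27p, "K27",
                                                          "none")))
  p1 <- function(s) s$has_d1 | s$has_che
  p2 <- function(s) s$has_d2 | s$has_che
  st1 <- state(p1(dt[, .(has_d1 = has_d1_k4, has_che = has_che_k4)]),
               p1(dt[, .(has_d1 = has_d1_k27, has_che = has_che_k27)]))
  st2 <- state(p2(dt[, .(has_d2 = has_d2_k4, has_che = has_che_k4)]),
               p2(dt[, .(has_d2 = has_d2_k27, has_che = has_che_k27)]))
  states <- c("none", "K4", "K27", "K4+K27")
  lv <- as.vector(outer(states, states, function(a, b) paste0(a, "-", b)))
  data.table::data.table(
    gene_id = dt$gene_id, state1 = st1, state2 = st2,
    class = factor(paste0(st1, "-", st2), levels = lv))
}
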