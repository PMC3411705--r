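#' Genome layout: ordered chromosomes tiled by fixed-width bins
#'
#' A layout fixes the bin index space used by every other object in the
#' package: chromosomes are tiled left to right by half-open bins of
#' `bin_size` base pairs (`[i*bin_size, (i+1)*bin_size)` in 0-based
#' coordinates), the last bin of each chromosome truncated at the
#' chromosome end, and per-chromosome bins are concatenated in the order
#' the chromosomes are given.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @param bin_size bin width in bp (> 0).  1000 bp suits broad marks such
#'   as H3K27me3; 200 bp suits sharp marks such as H3K4me3.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout("chr1", 1e6, bin_size = 1000)
#' @export
genome_layout <- function(chrom, length, bin_size = 1000) {
  stopifnot(is.character(chrom), length(chrom) == length(length),
            !anyDuplicated(chrom))
  length <- as.numeric(length)
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a single positive number")
  nb <- as.integer(ceiling(length / bin_size))
  structure(
    list(chrom = chrom, length = length, bin_size = as.numeric(bin_size),
         nbins_chrom = nb, offset = c(0L, cumsum(nb))[seq_along(chrom)]),
    class = "genome_layout")
}

#' Total number of bins in a layout
#' @param layout a `genome_layout`.
#' @return integer bin count B.
#' @export
n_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$nbins_chrom)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom), " chromosome(s), bin size ",
      x$bin_size, " bp, ", n_bins(x), " bins\n", sep = "")
  invisible(x)
}

#' Per-bin genomic intervals of a layout
#'
#' @param layout a `genome_layout`.
#' @return `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per bin in layout order.
#' @export
bin_table <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  dt <- data.table::data.table(
    chrom = rep(layout$chrom, layout$nbins_chrom),
    idx = unlist(lapply(layout$nbins_chrom, function(n) seq_len(n) - 1L)))
  dt[, `:=`(start = idx * layout$bin_size)]
  dt[, `:=`(end = pmin(start + layout$bin_size,
                       rep(layout$length, layout$nbins_chrom)))]
  dt[, idx := NULL]
  dt[]
}

#' Construct a binned library from per-bin counts
#'
#' The central container of both stages: one non-negative count per bin
#' of a [genome_layout()].
#'
#' @param layout a `genome_layout`.
#' @param counts numeric vector of non-negative counts, one per bin.
#' @return An object of class `binned_library` with elements `layout`
#'   and `counts`; the library total N and the number of zero bins Z0
#'   are available through [lib_total()] and [zero_bins()].
#' @export
binned_library <- function(layout, counts) {
  stopifnot(inherits(layout, "genome_layout"))
  counts <- as.numeric(counts)
  if (length(counts) != n_bins(layout))
    stop("counts length (", length(counts), ") != number of bins (",
         n_bins(layout), ")")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  structure(list(layout = layout, counts = counts),
            class = "binned_library")
}

#' @rdname binned_library
#' @param lib a `binned_library`.
#' @export
lib_total <- function(lib) sum(lib$counts)

#' @rdname binned_library
#' @export
zero_bins <- function(lib) sum(lib$counts == 0)

#' @export
print.binned_library <- function(x, ...) {
  cat("<binned_library> ", n_bins(x$layout), " bins, total ",
      format(lib_total(x), big.mark = ","), ", zero bins ",
      zero_bins(x), "\n", sep = "")
  invisible(x)
}

# shared sanity check used by all two-library operations
check_same_layout <- function(a, b) {
  la <- a$layout; lb <- b$layout
  if (!identical(la$chrom, lb$chrom) || !identical(la$length, lb$length) ||
      !identical(la$bin_size, lb$bin_size)) {
    bad <- which(la$chrom != lb$chrom | la$length != lb$length)[1]
    stop("libraries do not share a genome layout",
         if (!is.na(bad)) paste0(" (first mismatch: ", la$chrom[bad], ")"))
  }
  invisible(TRUE)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path file with columns name, length (no header).
#' @param bin_size bin width for the resulting layout.
#' @return a [genome_layout()].
#' @export
read_chrom_sizes <- function(path, bin_size = 1000) {
  dt <- data.table::fread(path, header = FALSE, col.names = c("chrom", "length"))
  genome_layout(as.character(dt$chrom), dt$length, bin_size)
}
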