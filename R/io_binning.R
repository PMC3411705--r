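#' Read mapped sequence tags from a BED6 file
#'
#' Tags are single-end reads mapped to the genome; the strand column is
#' required because downstream fragment-center shifting depends on read
#' orientation.  Malformed records (bad coordinates, start >= end,
#' strand not `+`/`-`) are skipped, counted, and reported in a warning;
#' they never abort the whole file.
#'
#' @param path BED file with at least 6 columns (chrom, start, end,
#'   name, score, strand).  CRLF line endings are tolerated.
#' @return A `data.table` of class `tag_set` with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `strand`.
#' @export
read_tags <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- if (file.size(path) == 0) data.table::data.table()
        else data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                               colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    out <- data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric(), strand = character())
    data.table::setattr(out, "class", c("tag_set", class(out)))
    return(out)
  }
  if (ncol(dt) < 6)
    stop("BED input must have 6 columns (strand in column 6 is required ",
         "for fragment-center shifting); got ", ncol(dt))
  out <- data.table::data.table(
    chrom = as.character(dt[[1]]),
    start = suppressWarnings(as.numeric(dt[[2]])),
    end = suppressWarnings(as.numeric(dt[[3]])),
    strand = as.character(dt[[6]]))
  bad <- is.na(out$start) | is.na(out$end) | out$start < 0 |
    out$start >= out$end | !(out$strand %in% c("+", "-"))
  if (any(bad))
    warning(sum(bad), " malformed BED record(s) skipped")
  out <- out[!bad]
  data.table::setattr(out, "class", c("tag_set", class(out)))
  out
}

#' Shift tag 5' ends to approximate fragment centers
#'
#' Sequencing reads one end of each immunoprecipitated fragment; with a
#' median fragment length around 200 bp the fragment center is
#' approximated by moving the tag 100 bp towards the fragment interior:
#' `start + shift` on the plus strand, `end - 1 - shift` on the minus
#' strand.  Positions are clamped into the chromosome.
#'
#' @param tags a `tag_set` from [read_tags()].
#' @param layout a [genome_layout()]; used for clamping.
#' @param shift bp to move towards the center (default 100, half the
#'   typical fragment length).
#' @return `data.table` with columns `chrom`, `pos`.
#' @export
shift_to_centers <- function(tags, layout, shift = 100) {
  stopifnot(shift >= 0)
  pos <- ifelse(tags$strand == "+", tags$start + shift, tags$end - 1 - shift)
  len <- layout$length[match(tags$chrom, layout$chrom)]
  pos <- pmax(0, pos)
  pos <- ifelse(is.na(len), pos, pmin(pos, len - 1))
  data.table::data.table(chrom = tags$chrom, pos = pos)
}

#' Bin fragment-center positions into a library
#'
#' @param positions `data.table` with `chrom`, `pos` (0-based bp), as
#'   produced by [shift_to_centers()].
#' @param layout a [genome_layout()].
#' @param on_unknown what to do with positions on chromosomes absent
#'   from the layout: `"drop"` (default; dropped with a warning giving
#'   the count — real libraries carry unplaced contigs) or `"error"`.
#' @return a [binned_library()] whose total equals the number of kept
#'   positions.
#' @export
bin_positions <- function(positions, layout, on_unknown = c("drop", "error")) {
  on_unknown <- match.arg(on_unknown)
  ci <- match(positions$chrom, layout$chrom)
  if (anyNA(ci)) {
    if (on_unknown == "error")
      stop(sum(is.na(ci)), " position(s) on chromosomes absent from layout")
    warning(sum(is.na(ci)), " position(s) on unknown chromosomes dropped")
  }
  keep <- !is.na(ci)
  ci <- ci[keep]
  pos <- positions$pos[keep]
  idx <- layout$offset[ci] + floor(pos / layout$bin_size) + 1
  counts <- tabulate(idx, nbins = n_bins(layout))
  binned_library(layout, counts)
}

#' Tags straight to a binned library
#'
#' Convenience wrapper: [read_tags()], [shift_to_centers()],
#' [bin_positions()].
#' @inheritParams shift_to_centers
#' @inheritParams bin_positions
#' @param path BED6 file of mapped tags.
#' @return a [binned_library()].
#' @export
bin_tags <- function(path, layout, shift = 100,
                     on_unknown = c("drop", "error")) {
  bin_positions(shift_to_centers(read_tags(path), layout, shift),
                layout, on_unknown)
}

#' Read and write binned counts as bedGraph
#'
#' `read_bedgraph` requires the intervals to tile the layout exactly at
#' its bin size (in layout order); any interval of the wrong width or
#' position aborts with the offending line number.  `write_bedgraph`
#' emits one line per bin, so the pair is a round-trip identity on
#' [binned_library()] objects.
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value).
#' @param layout a [genome_layout()] the intervals must tile.
#' @return `read_bedgraph`: a [binned_library()]; `write_bedgraph`:
#'   invisibly, the path.
#' @export
read_bedgraph <- function(path, layout) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1))
  bt <- bin_table(layout)
  if (nrow(dt) != nrow(bt))
    stop("bedGraph has ", nrow(dt), " intervals; layout has ", nrow(bt),
         " bins")
  bad <- which(dt$chrom != bt$chrom | dt$start != bt$start | dt$end != bt$end)
  if (length(bad))
    stop("bedGraph interval does not tile the layout at bin size ",
         layout$bin_size, " (line ", bad[1], ": ", dt$chrom[bad[1]], ":",
         dt$start[bad[1]], "-", dt$end[bad[1]], ")")
  binned_library(layout, dt$value)
}

#' @rdname read_bedgraph
#' @param lib a [binned_library()] to write.
#' @export
write_bedgraph <- function(lib, path) {
  bt <- bin_table(lib$layout)
  bt[, value := lib$counts]
  data.table::fwrite(bt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Write labeled regions as BED
#'
#' 0-based half-open BED with the region label (`DHE_LIB1`, `DHE_LIB2`
#' or `CHE`) in the name field.
#'
#' @param regions a region table from [merge_regions()] (columns
#'   `chrom`, `start`, `end`, `label`).
#' @param path output BED path.
#' @return invisibly, the path.
#' @export
write_regions <- function(regions, path) {
  dt <- data.table::data.table(chrom = regions$chrom,
                               start = regions$start,
                               end = regions$end,
                               name = as.character(regions$label))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Read a generic BED file of labeled regions
#'
#' Accepts output of [write_regions()] or of external differential
#' callers (label taken from the name column when present, otherwise a
#' constant supplied label).
#'
#' @param path BED file (>= 3 columns).
#' @param default_label label to assign when the file has no name column.
#' @return `data.table` with `chrom`, `start`, `end`, `label`.
#' @export
read_regions <- function(path, default_label = "DHE_LIB1") {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  out <- data.table::data.table(
    chrom = as.character(dt[[1]]),
    start = as.numeric(dt[[2]]),
    end = as.numeric(dt[[3]]),
    label = if (ncol(dt) >= 4) as.character(dt[[4]]) else default_label)
  out
}
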