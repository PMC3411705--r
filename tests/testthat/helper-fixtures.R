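# tiny layouts and libraries used across tests
tiny_layout <- function(nbins, bin_size = 1000, chrom = "chrT") {
  genome_layout(chrom, nbins * bin_size, bin_size)
}

make_lib <- function(counts, bin_size = 1000) {
  binned_library(tiny_layout(length(counts), bin_size), counts)
}

# write a BED6 file of tags; records as list of c(chrom,start,end,strand)
write_bed6 <- function(records, path, eol = "\n") {
  lines <- vapply(records, function(r)
    paste(r[1], r[2], r[3], "tag", "0", r[4], sep = "\t"), character(1))
  con <- file(path, "wb")
  writeLines(lines, con, sep = eol)
  close(con)
  path
}

# labels object with given label at given bins, NONE elsewhere
labels_at <- function(layout, lab_bins) {
  lab <- rep("NONE", n_bins(layout))
  for (nm in names(lab_bins)) lab[lab_bins[[nm]]] <- nm
  bin_labels(layout, rep(TRUE, n_bins(layout)),
             factor(lab, levels = c("NONE", "DHE_LIB1", "DHE_LIB2", "CHE")))
}
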