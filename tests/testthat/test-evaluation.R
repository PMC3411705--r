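# a layout of 20 x 1 Mbp windows (1 kb bins) shared by the profile tests
profile_layout <- function() genome_layout("chrT", 2e7, 1000)

test_that("gene-density classes are balanced and track planted structure", {
  layout <- profile_layout()
  # gene count and call density both rise with window number
  genes_dense <- gene_set(
    sprintf("g%03d", seq_len(sum(1:20))), "chrT",
    unlist(lapply(1:20, function(w) (w - 1) * 1e6 + seq_len(w) * 1e3)))
  values <- as.numeric(seq_len(n_bins(layout)))
  prof <- gene_density_profile(values, layout, genes_dense, classes = 10)
  expect_equal(sum(prof$n_windows), 20)
  expect_lte(diff(range(prof$n_windows)), 1)
  expect_equal(cor(prof$class, prof$mean_value, method = "spearman"), 1)
  expect_true(all(diff(prof$mean_genes) > 0))

  # no structure: flat profile
  uni <- gene_density_profile(rep(1, n_bins(layout)), layout, genes_dense)
  expect_true(all(abs(uni$mean_value - uni$mean_value[1]) < 1e-9))
  # empty labels: all-zero profile
  zero <- gene_density_profile(rep(0, n_bins(layout)), layout, genes_dense)
  expect_true(all(zero$mean_value == 0))
  expect_error(gene_density_profile(values, layout, genes_dense,
                                    classes = 30), "fewer windows")
})

test_that("promoter sensitivity and error follow the label definitions", {
  layout <- tiny_layout(50)
  genes <- gene_set(c("up2", "up1", "flat"), "chrT",
                    c(10500, 20500, 30500))
  expr <- data.table::data.table(gene_id = c("up2", "up1", "flat"),
                                 expr_cond1 = c(2, 80, 30),
                                 expr_cond2 = c(80, 2, 30))
  # repressive mark: DHE_LIB1 at the promoter of the cond2-overexpressed gene
  lab <- labels_at(layout, list(DHE_LIB1 = 11, DHE_LIB2 = 21))
  res <- promoter_sensitivity(lab, genes, expr, fold = 4)
  expect_equal(res$sensitivity_pct, c(100, 100))
  expect_equal(res$error_pct, c(0, 0))
  expect_equal(res$n_genes, c(1, 1))

  # all-NONE labels: zero everywhere
  res0 <- promoter_sensitivity(labels_at(layout, list()), genes, expr)
  expect_equal(res0$sensitivity_pct, c(0, 0))
  expect_equal(res0$error_pct, c(0, 0))

  # no gene passing the filter is an error
  flat_expr <- data.table::data.table(gene_id = genes$gene_id,
                                      expr_cond1 = 10, expr_cond2 = 10)
  expect_error(promoter_sensitivity(lab, genes, flat_expr), "filter")
})

test_that("a multi-TSS gene counts once if any promoter qualifies", {
  layout <- tiny_layout(50)
  genes <- gene_set(c("g", "g"), "chrT", c(5500, 40500))  # two promoters
  expr <- data.table::data.table(gene_id = "g", expr_cond1 = 1,
                                 expr_cond2 = 50)
  lab <- labels_at(layout, list(DHE_LIB1 = 41))   # only the second promoter
  res <- promoter_sensitivity(lab, genes, expr, fold = 4)
  expect_equal(res[res$side == "cond2_over"]$n_genes, 1)
  expect_equal(res[res$side == "cond2_over"]$sensitivity_pct, 100)
})

test_that("roc_points spans perfect, random and single-threshold cases", {
  layout <- tiny_layout(200)
  set.seed(52)
  n <- 60
  tss <- seq(1500, by = 3000, length.out = n)
  genes <- gene_set(sprintf("g%02d", 1:n), "chrT", tss)
  up2 <- seq_len(n) <= 20                     # class 1 of side 1
  up1 <- seq_len(n) > 40                      # class 1 of side 2
  expr <- data.table::data.table(
    gene_id = genes$gene_id,
    expr_cond1 = ifelse(up2, 2, ifelse(up1, 80, 40)),
    expr_cond2 = ifelse(up2, 80, ifelse(up1, 2, 40)))
  promoter_bin <- floor(tss / 1000) + 1
  # perfect labeling: DHE_LIB1 exactly at class-1 promoters
  perfect <- labels_at(layout, list(DHE_LIB1 = promoter_bin[up2]))
  r <- roc_points(list(perfect), genes, expr)
  expect_equal(nrow(r), 2)                    # single threshold, two sides
  expect_equal(r[r$side == 1]$tpr, 1)
  expect_equal(r[r$side == 1]$fpr, 0)

  # random labels: point near the diagonal
  rand_bins <- sample(promoter_bin, 30)
  rand <- labels_at(layout, list(DHE_LIB1 = rand_bins))
  rr <- roc_points(list(rand), genes, expr)
  expect_lt(abs(rr[rr$side == 1]$tpr - rr[rr$side == 1]$fpr), 0.35)

  # class 1 empty is an error
  no_expr <- data.table::data.table(gene_id = genes$gene_id,
                                    expr_cond1 = 10, expr_cond2 = 10)
  expect_error(roc_points(list(perfect), genes, no_expr), "class 1")
})

test_that("replicate FPR is the DHE percentage of evaluated bins", {
  layout <- tiny_layout(10000)
  expect_equal(replicate_fpr(labels_at(layout, list())), 0)
  one <- labels_at(layout, list(DHE_LIB1 = 77))
  expect_equal(replicate_fpr(one), 0.01)
  che <- labels_at(layout, list(CHE = 1:50))   # CHE is not a false positive
  expect_equal(replicate_fpr(che), 0)
})

test_that("gene types 1-4 match the exhaustive promoter-state truth table", {
  layout <- tiny_layout(30)
  combos <- expand.grid(d1 = c(FALSE, TRUE), d2 = c(FALSE, TRUE),
                        che = c(FALSE, TRUE))
  want_type <- function(d1, d2, che) {
    if (!d1 && !d2 && !che) 1L
    else if (che || (d1 && d2)) 3L
    else if (d1) 2L else 4L
  }
  for (i in seq_len(nrow(combos))) {
    with_bins <- list()
    if (combos$d1[i]) with_bins$DHE_LIB1 <- 11
    if (combos$d2[i]) with_bins$DHE_LIB2 <- 12
    if (combos$che[i]) with_bins$CHE <- 13
    lab <- labels_at(layout, with_bins)
    genes <- gene_set("g", "chrT", 11500)  # promoter covers bins 11-13
    got <- classify_gene_types(lab, genes, halfwidth = 1500)
    expect_equal(got$type,
                 want_type(combos$d1[i], combos$d2[i], combos$che[i]),
                 info = paste(combos[i, ], collapse = "/"))
  }
})

test_that("bivalent classification enumerates all 16 promoter states", {
  layout <- tiny_layout(30)
  # presence pattern of one mark across the two cells -> a label placement
  placement <- function(state) switch(state,
    none = list(),
    cell1 = list(DHE_LIB1 = 11),
    cell2 = list(DHE_LIB2 = 11),
    both = list(CHE = 11))
  state_name <- function(k4, k27, cell) {
    has_k4 <- k4 %in% c(cell, "both")
    has_k27 <- k27 %in% c(cell, "both")
    if (has_k4 && has_k27) "K4+K27" else if (has_k4) "K4"
    else if (has_k27) "K27" else "none"
  }
  genes <- gene_set("g", "chrT", 11500)
  seen <- character()
  for (k4 in c("none", "cell1", "cell2", "both"))
    for (k27 in c("none", "cell1", "cell2", "both")) {
      got <- bivalent_classes(labels_at(layout, placement(k27)),
                              labels_at(layout, placement(k4)), genes)
      want <- paste0(state_name(k4, k27, "cell1"), "-",
                     state_name(k4, k27, "cell2"))
      expect_equal(as.character(got$class), want)
      seen <- union(seen, want)
    }
  expect_equal(length(seen), 16)  # all 16 classes reachable
})

test_that("the worked bivalent example maps to the expected class", {
  layout <- tiny_layout(30)
  genes <- gene_set("g", "chrT", 11500)
  # K4 present in cell 1 only, K27 present in both cells
  k4 <- labels_at(layout, list(DHE_LIB1 = 11))
  k27 <- labels_at(layout, list(CHE = 11))
  got <- bivalent_classes(k27, k4, genes)
  expect_equal(as.character(got$class), "K4+K27-K27")
})
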