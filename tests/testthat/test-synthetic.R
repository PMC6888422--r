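test_that("planted single-domain proteins round-trip through the annotator", {
  rec <- gen_wrky_protein("p1", list(list(hepta = "WRKYGQK",
                                          fingers = list(list(a = 5, b = 23,
                                                              z = "H")))),
                          length_aa = 150, seed = 1)
  expect_equal(nchar(rec$seq), 150L)
  ann <- annotate_protein(rec$id, rec$seq)
  expect_length(ann$hits, 1L)
  expect_equal(format_zinc_label(ann$hits[[1]]$fingers[[1]]),
               "C-X5-C-X23-HXH")
  expect_equal(ann$zinc_type, "C-C-H-H")

  two <- gen_wrky_protein("p2", list(list(hepta = "WRKYGQK",
                                          fingers = list(list(a = 4, b = 22,
                                                              z = "H"))),
                                     list(hepta = "WRKYGKK",
                                          fingers = list(list(a = 4, b = 23,
                                                              z = "H")))),
                          length_aa = 400, seed = 2)
  ann2 <- annotate_protein(two$id, two$seq)
  expect_length(ann2$hits, 2L)
  expect_equal(ann2$hits[[2]]$hepta_seq, "WRKYGKK")

  none <- gen_wrky_protein("p0", list(), length_aa = 90, seed = 3)
  expect_length(annotate_protein(none$id, none$seq)$hits, 0L)
  expect_error(gen_wrky_protein("bad",
                                list(list(hepta = "WRKYGQK",
                                          fingers = list(list(a = 10, b = 23,
                                                              z = "H")))),
                                length_aa = 150, seed = 4),
               "outside the grammar")
  expect_error(gen_wrky_protein("short",
                                list(list(hepta = "WRKYGQK",
                                          fingers = list(list(a = 5, b = 23,
                                                              z = "H")))),
                                length_aa = 30, seed = 5), "too short")
})

test_that("the synthetic family FASTA matches the fixture row for row", {
  fx <- load_family_fixture()
  fam <- gen_family_fasta(fx, seed = 101)
  expect_equal(nrow(fam), 64L)
  expect_equal(fam$id, fx$gene)
  expect_equal(nchar(fam$seq), fx$orf_aa)
  anns <- annotate_proteins(fam)
  tab <- annotation_table(anns)
  # domain counts and heptapeptide strings match the fixture exactly
  expect_equal(tab$motif_string, fx$motif_string)
  # formatted zinc labels match the fixture exactly (normalized)
  fx_labels <- vapply(strsplit(fx$zinc_labels, "/", fixed = TRUE),
                      function(l) paste(vapply(l, normalize_zinc_label,
                                               character(1)),
                                        collapse = "/"), character(1))
  expect_equal(tab$zinc_labels, unname(fx_labels))
  expect_equal(sum(tab$n_domains == 2L), 13L)

  # byte-identical regeneration under the same seed
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam, f1)
  write_fasta(gen_family_fasta(fx, seed = 101), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the padding
  expect_false(identical(gen_family_fasta(fx, seed = 102)$seq, fam$seq))
})

test_that("planted W-box counts are recovered exactly, strand-symmetrically", {
  cfg <- promoter_config()
  plan <- data.frame(gene = c("g1", "g2", "gm"),
                     strand = c("+", "+", "-"),
                     n_boxes = c(0L, 5L, 5L))
  gg <- gen_genome(plan, cfg, seed = 71)
  sc <- scan_promoters(gg$genes, gg$genome, cfg)
  cf <- count_and_filter(sc$hits, sc$scanned, cfg)
  got <- setNames(cf$counts$n_wbox, cf$counts$gene)
  expect_equal(got[plan$gene], setNames(plan$n_boxes, plan$gene))
  expect_setequal(cf$targets, c("g2", "gm"))  # threshold 5, inclusive
})

test_that("an 80-gene planted genome reproduces its histogram exactly", {
  cfg <- promoter_config()
  plan <- data.frame(gene = sprintf("g%02d", 1:80),
                     strand = rep(c("+", "-"), 40),
                     n_boxes = rep(0:7, each = 10))
  gg <- gen_genome(plan, cfg, seed = 72)
  sc <- scan_promoters(gg$genes, gg$genome, cfg)
  cf <- count_and_filter(sc$hits, sc$scanned, cfg)
  want <- c("0" = 10L, "1" = 10L, "2" = 10L, "3" = 10L, "4" = 10L,
            ">=5" = 30L)
  expect_equal(setNames(cf$histogram$n_genes, cf$histogram$bin), want)
  expect_equal(sum(cf$histogram$n_genes), length(sc$scanned))
})

test_that("the synthetic GFF3 round-trips through the GFF parser", {
  plan <- data.frame(gene = c("ga", "gb"), strand = c("+", "-"),
                     n_boxes = c(1L, 2L), n_exons = c(1L, 4L))
  gg <- gen_genome(plan, seed = 73)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gg$gff, gff)
  parsed <- read_gff3_genes(gff, gg$genome)
  for (g in plan$gene) {
    expect_equal(parsed[[g]]$cds_start, gg$genes[[g]]$cds_start)
    expect_equal(parsed[[g]]$strand, gg$genes[[g]]$strand)
    expect_equal(parsed[[g]]$exons[, "start"],
                 unname(gg$genes[[g]]$exons[, "start"]),
                 ignore_attr = TRUE)
  }
  expect_equal(gene_structure(parsed$gb)$n_introns, 3L)
  # the extracted promoter equals the planted oriented string: scanning it
  # yields exactly the planted counts
  cfg <- promoter_config()
  for (g in plan$gene) {
    prom <- extract_promoter(parsed[[g]], gg$genome, cfg)
    expect_equal(nrow(scan_wbox(prom$seq, cfg)),
                 plan$n_boxes[plan$gene == g])
  }
})

test_that("qPCR generation is seeded and recovers degenerate folds exactly", {
  plan <- data.frame(gene = "g", hormone = "SA", fold_3h = 2, fold_6h = 0.5)
  c1 <- gen_qpcr(plan, seed = 11)
  c2 <- gen_qpcr(plan, seed = 11)
  expect_identical(c1, c2)
  expect_false(identical(gen_qpcr(plan, seed = 12), c1))
  noise0 <- gen_qpcr(plan, noise_sd = 0, ref_sd = 0, seed = 11)
  r <- relative_expression(noise0, "g", "SA")
  expect_equal(r$rel_expr[r$timepoint == 3], 2)
  expect_equal(r$rel_expr[r$timepoint == 6], 0.5)
})

test_that("Poisson count matrices give near-unbiased RPKM estimates", {
  genes <- sprintf("g%02d", 1:20)
  expr <- matrix(c(rep(0, 5), seq(10, 160, length.out = 15)), 20, 1,
                 dimnames = list(genes, "s1"))
  lens <- rep(2000L, 20)

  zero <- gen_count_matrix(expr * 0, lens, 1e7, seed = 1)
  expect_true(all(zero == 0))

  big <- gen_count_matrix(expr, lens, 1e8, seed = 2)
  r <- rpkm_matrix(big, lens, 1e8)
  nonzero <- expr[, 1] >= 10
  expect_true(all(abs(r[nonzero, 1] - expr[nonzero, 1]) /
                    expr[nonzero, 1] < 0.05))

  # averaging over 100 seeds: estimator within 1% of truth
  acc <- matrix(0, 20, 1)
  for (s in 1:100)
    acc <- acc + rpkm_matrix(gen_count_matrix(expr, lens, 1e8, seed = s),
                             lens, 1e8)
  est <- acc / 100
  expect_true(all(abs(est[nonzero, 1] - expr[nonzero, 1]) /
                    expr[nonzero, 1] < 0.01))
})
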