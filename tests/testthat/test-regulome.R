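test_that("promoter extraction follows the strand and truncation rules", {
  cfg <- promoter_config(promoter_len = 2000)
  contig <- random_dna(5000)
  genome <- data.frame(id = "c1", desc = "", seq = contig)
  gplus <- list(gene_id = "gp", contig = "c1", strand = "+",
                cds_start = 3000L, exons = cbind(start = 3000L, end = 3500L))
  p <- extract_promoter(gplus, genome, cfg)
  expect_equal(p$seq, substring(contig, 1000, 2999))
  expect_equal(p$span, c(1000, 2999))
  expect_false(p$truncated)

  gminus <- list(gene_id = "gm", contig = "c1", strand = "-",
                 cds_start = 2000L, exons = cbind(start = 1500L, end = 2000L))
  m <- extract_promoter(gminus, genome, cfg)
  expect_equal(m$seq, revcomp(substring(contig, 2001, 4000)))

  # truncation at the contig edge
  gshort <- list(gene_id = "gs", contig = "c1", strand = "+",
                 cds_start = 500L, exons = cbind(start = 500L, end = 900L))
  t <- extract_promoter(gshort, genome, cfg)
  expect_true(t$truncated)
  expect_equal(nchar(t$seq), 499L)

  gedge <- list(gene_id = "ge", contig = "c1", strand = "+",
                cds_start = 1L, exons = cbind(start = 1L, end = 300L))
  expect_warning(e <- extract_promoter(gedge, genome, cfg), "empty promoter")
  expect_equal(e$seq, "")
})

test_that("W-box scan finds canonical, overlapping and minus-strand hits", {
  expect_equal(nrow(scan_wbox("TTGACC")), 1L)
  h <- scan_wbox("TTGACTTGACC")
  expect_equal(h$offset[h$strand == "+"], c(1L, 6L))  # overlap allowed
  g <- scan_wbox("GGTCAA")
  expect_equal(g$strand, "-")
  expect_equal(nrow(scan_wbox("GGTCAA",
                              promoter_config(scan_both_strands = FALSE))),
               0L)
  expect_warning(scan_wbox("TTGACCXX"), "non-ACGTN")
})

test_that("W-box scan equals naive window enumeration on random sequences", {
  cfg <- promoter_config()
  set.seed(55)
  lens <- c(50, 200, 1000, 10000)
  for (L in lens) {
    seq <- random_dna(L)
    got <- scan_wbox(seq, cfg)
    want <- oracle_scan_wbox(seq)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
  }
})

test_that("counting bins the histogram and applies the inclusive threshold", {
  cfg <- promoter_config()
  hits <- data.frame(gene_id = c(rep("g5", 5), rep("g4", 4), rep("g7", 7)))
  cf <- count_and_filter(hits, scanned = c("g0", "g4", "g5", "g7"), cfg)
  expect_setequal(cf$targets, c("g5", "g7"))   # "at least five" is inclusive
  expect_equal(cf$counts$n_wbox[cf$counts$gene == "g0"], 0L)
  expect_equal(cf$histogram$n_genes[cf$histogram$bin == ">=5"], 2L)
  expect_equal(cf$histogram$n_genes[cf$histogram$bin == "4"], 1L)
  expect_equal(sum(cf$histogram$n_genes), 4L)  # all scanned genes binned
})

test_that("strand-specific counts survive reverse-complementing the genome", {
  plan <- data.frame(gene = c("g1", "g2", "g3"), strand = c("+", "-", "+"),
                     n_boxes = c(2L, 4L, 6L))
  gg <- gen_genome(plan, seed = 13)
  cfg <- promoter_config()
  sc <- scan_promoters(gg$genes, gg$genome, cfg)
  counts <- count_and_filter(sc$hits, sc$scanned, cfg)$counts
  # flip the entire genome and all gene strands: counts must not change
  flipped_genome <- gg$genome
  flips <- vapply(gg$genome$seq, revcomp, character(1))
  clens <- nchar(gg$genome$seq)
  flipped_genome$seq <- unname(flips)
  flipped_genes <- lapply(gg$genes, function(g) {
    clen <- clens[match(g$contig, gg$genome$id)]
    g2 <- g
    g2$strand <- if (g$strand == "+") "-" else "+"
    g2$cds_start <- clen - g$cds_start + 1L
    g2$exons <- cbind(start = clen - g$exons[, "end"] + 1L,
                      end = clen - g$exons[, "start"] + 1L)
    g2
  })
  sc2 <- scan_promoters(flipped_genes, flipped_genome, cfg)
  counts2 <- count_and_filter(sc2$hits, sc2$scanned, cfg)$counts
  expect_equal(counts2[order(counts2$gene), c("gene", "n_wbox")],
               counts[order(counts$gene), c("gene", "n_wbox")])
})

test_that("genomic hit coordinates are consistent with the contig sequence", {
  plan <- data.frame(gene = c("g1", "g2"), strand = c("+", "-"),
                     n_boxes = c(3L, 3L))
  gg <- gen_genome(plan, seed = 17)
  sc <- scan_promoters(gg$genes, gg$genome, promoter_config())
  for (i in seq_len(nrow(sc$hits))) {
    h <- sc$hits[i, ]
    contig <- gg$genome$seq[gg$genome$id == h$contig]
    piece <- substring(contig, h$start, h$end)
    if (h$strand == "-") piece <- revcomp(piece)
    expect_match(piece, "^[CT]TGAC[CT]$")
  }
})

test_that("gene structure counts introns as exons minus one", {
  mk <- function(n) list(gene_id = "g", contig = "c", strand = "+",
                         cds_start = 1L,
                         exons = cbind(start = seq(1, by = 200,
                                                   length.out = n),
                                       end = seq(100, by = 200,
                                                 length.out = n)))
  expect_equal(gene_structure(mk(1))$n_introns, 0L)
  expect_equal(gene_structure(mk(3))$n_introns, 2L)
  expect_equal(gene_structure(mk(14))$n_introns, 13L)
})

test_that("hypergeometric enrichment matches exhaustive combinatorics", {
  # N=10, K=5, n=4, k=4: p = C(5,4) C(5,0) / C(10,4) = 5/210
  background <- paste0("g", 1:10)
  pm <- data.frame(gene = background[1:5], pathway_id = "P1",
                   pathway_name = "pathway one")
  res <- enrich(background[1:4], background, pm)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$k, 4L)

  # random configurations against the explicit-combinatorics oracle
  set.seed(99)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    bg <- paste0("g", 1:N)
    tg <- sample(bg, n)
    pmr <- data.frame(gene = bg[1:K], pathway_id = "P", pathway_name = "p")
    k <- sum(tg %in% bg[1:K])
    expect_equal(enrich(tg, bg, pmr)$p, oracle_hyper_upper(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("enrichment degenerates and corrects as expected", {
  bg <- paste0("g", 1:20)
  pm <- rbind(data.frame(gene = bg[1:5], pathway_id = "P1",
                         pathway_name = "one"),
              data.frame(gene = bg[6:10], pathway_id = "P2",
                         pathway_name = "two"))
  # targets = background: nothing can be enriched
  res <- enrich(bg, bg, pm)
  expect_true(all(res$p == 1))
  expect_error(enrich(character(0), bg, pm), "empty target set")
  expect_error(enrich("zz", bg, pm), "subset")

  # BH q-values are monotone in p-rank and >= p
  set.seed(3)
  pm3 <- do.call(rbind, lapply(1:6, function(i)
    data.frame(gene = sample(bg, 8), pathway_id = paste0("Q", i),
               pathway_name = "x")))
  r3 <- enrich(sample(bg, 7), bg, pm3)
  expect_true(all(diff(r3$q) >= -1e-12))
  expect_true(all(r3$q >= r3$p - 1e-12))
  expect_equal(r3$q, p.adjust(r3$p, "BH"))
})

test_that("null enrichment p-values are calibrated", {
  # draws from the null: random target sets, one pathway of 100 genes in a
  # background of 500; the rejection rate at 0.05 stays near nominal
  N <- 500; K <- 100; n <- 100
  bg <- paste0("g", 1:N)
  pm <- data.frame(gene = bg[1:K], pathway_id = "P", pathway_name = "p")
  set.seed(31)
  ps <- replicate(1000, enrich(sample(bg, n), bg, pm)$p)
  expect_true(abs(mean(ps < 0.05) - 0.05) <= 0.02)
})
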