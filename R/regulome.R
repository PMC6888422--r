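#' Promoter / W-box scan configuration
#'
#' @param promoter_len Promoter length in bp upstream of the ATG start
#'   codon (default 2000).
#' @param consensus W-box consensus as an IUPAC DNA string; the default
#'   `"YTGACY"` is (C/T)TGAC(C/T).
#' @param min_boxes_for_target Minimum W-box count for a gene to be called
#'   a potential target (default 5; the threshold is inclusive).
#' @param scan_both_strands Scan the reverse complement as well (default
#'   TRUE).
#' @return Object of class `promoter_config`.
#' @export
promoter_config <- function(promoter_len = 2000L, consensus = "YTGACY",
                            min_boxes_for_target = 5L,
                            scan_both_strands = TRUE) {
  stopifnot(promoter_len > 0, min_boxes_for_target >= 1)
  consensus <- toupper(consensus)
  if (grepl("[^ACGTRYSWKMBDHVN]", consensus))
    stop("consensus must be an IUPAC DNA string")
  structure(list(promoter_len = as.integer(promoter_len),
                 consensus = consensus,
                 min_boxes_for_target = as.integer(min_boxes_for_target),
                 scan_both_strands = isTRUE(scan_both_strands)),
            class = "promoter_config")
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
            S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
            H = "ACT", V = "ACG", N = "ACGT")

.iupac_regex <- function(consensus) {
  parts <- vapply(strsplit(consensus, "")[[1]], function(ch) {
    opts <- .IUPAC[[ch]]
    if (nchar(opts) == 1) opts else paste0("[", opts, "]")
  }, character(1))
  paste(parts, collapse = "")
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param x DNA string.
#' @return Reverse complement string.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Extract the promoter of a gene
#'
#' The promoter is the `promoter_len` bases immediately upstream of the ATG
#' translation start: on the + strand, positions
#' `[cds_start - L, cds_start - 1]`; on the - strand, positions
#' `[cds_start + 1, cds_start + L]` reverse-complemented. The window is
#' truncated at the contig edge; a truncated or empty promoter is flagged.
#'
#' @param gene Gene model from [read_gff3_genes()].
#' @param genome Data frame from [read_fasta()] (nucleotide records).
#' @param cfg [promoter_config()].
#' @return List with `seq` (promoter on the gene's coding orientation),
#'   `truncated` flag, and genomic `span` (`c(start, end)`, 1-based
#'   inclusive; `NULL` when empty).
#' @export
extract_promoter <- function(gene, genome, cfg = promoter_config()) {
  idx <- match(gene$contig, genome$id)
  if (is.na(idx)) stop("contig not in genome: ", gene$contig)
  contig <- genome$seq[idx]
  clen <- nchar(contig)
  L <- cfg$promoter_len
  if (gene$strand == "+") {
    from <- max(1L, gene$cds_start - L)
    to <- gene$cds_start - 1L
    if (to < from) {
      warning("empty promoter for gene ", gene$gene_id)
      return(list(seq = "", truncated = TRUE, span = NULL))
    }
    list(seq = substring(contig, from, to), truncated = (to - from + 1L) < L,
         span = c(from, to))
  } else {
    from <- gene$cds_start + 1L
    to <- min(clen, gene$cds_start + L)
    if (to < from) {
      warning("empty promoter for gene ", gene$gene_id)
      return(list(seq = "", truncated = TRUE, span = NULL))
    }
    list(seq = revcomp(substring(contig, from, to)),
         truncated = (to - from + 1L) < L, span = c(from, to))
  }
}

#' Scan a sequence for W-box elements
#'
#' Forward scan for the consensus; when both strands are scanned, the
#' reverse-complement pattern is additionally matched on the forward
#' coordinates and reported as minus-strand hits. Overlapping matches are
#' all counted. Hits are sorted by offset, then strand.
#'
#' @param seq Uppercase DNA string.
#' @param cfg [promoter_config()].
#' @return Data frame with `offset` (1-based), `strand`, `match`.
#' @export
scan_wbox <- function(seq, cfg = promoter_config()) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq))
    warning("non-ACGTN characters in sequence; they never match")
  w <- nchar(cfg$consensus)
  find <- function(pattern) {
    m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m)
  }
  cut <- function(pos) {
    if (length(pos) == 0L) character(0)
    else substring(seq, pos, pos + w - 1L)
  }
  fwd <- find(.iupac_regex(cfg$consensus))
  hits <- data.frame(offset = fwd,
                     strand = rep("+", length(fwd)),
                     match = cut(fwd),
                     stringsAsFactors = FALSE)
  if (cfg$scan_both_strands) {
    rev <- find(.iupac_regex(revcomp(cfg$consensus)))
    hits <- rbind(hits, data.frame(offset = rev,
                                   strand = rep("-", length(rev)),
                                   match = cut(rev),
                                   stringsAsFactors = FALSE))
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

#' Scan every gene promoter of a genome for W-boxes
#'
#' Convenience composition of [extract_promoter()] and [scan_wbox()].
#' Genes with an empty promoter are dropped (with a warning from the
#' extraction step). Hits are reported both in promoter coordinates and as
#' genomic coordinates suitable for [write_bed()].
#'
#' @param genes List of gene models from [read_gff3_genes()].
#' @param genome Data frame from [read_fasta()].
#' @param cfg [promoter_config()].
#' @return List with `hits` (data frame: `gene_id`, `contig`, `offset`,
#'   `start`, `end`, `strand` (genomic), `match`) and `scanned` (character
#'   vector of genes with a non-empty promoter).
#' @export
scan_promoters <- function(genes, genome, cfg = promoter_config()) {
  out <- list()
  scanned <- character(0)
  for (g in genes) {
    prom <- extract_promoter(g, genome, cfg)
    if (!nzchar(prom$seq)) next
    scanned <- c(scanned, g$gene_id)
    h <- scan_wbox(prom$seq, cfg)
    if (nrow(h) == 0L) next
    w <- nchar(cfg$consensus)
    if (g$strand == "+") {
      gstart <- prom$span[1] + h$offset - 1L
      gstrand <- h$strand
    } else {
      gstart <- prom$span[2] - h$offset - w + 2L
      gstrand <- ifelse(h$strand == "+", "-", "+")
    }
    out[[g$gene_id]] <- data.frame(gene_id = g$gene_id, contig = g$contig,
                                   offset = h$offset, start = gstart,
                                   end = gstart + w - 1L, strand = gstrand,
                                   match = h$match, stringsAsFactors = FALSE)
  }
  hits <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
          else data.frame(gene_id = character(), contig = character(),
                          offset = integer(), start = integer(),
                          end = integer(), strand = character(),
                          match = character(), stringsAsFactors = FALSE)
  list(hits = hits, scanned = scanned)
}

#' Count W-boxes per gene, bin the histogram and call target genes
#'
#' @param hits Data frame of hits with a `gene_id` column (e.g. from
#'   [scan_promoters()]).
#' @param scanned Character vector of all genes with a scanned (non-empty)
#'   promoter; genes without hits count as zero.
#' @param cfg [promoter_config()].
#' @return List with `counts` (data frame `gene`, `n_wbox`, `target`),
#'   `histogram` (data frame `bin` in 0,1,2,3,4,">=5" and `n_genes`) and
#'   `targets` (character vector).
#' @export
count_and_filter <- function(hits, scanned, cfg = promoter_config()) {
  n <- table(factor(hits$gene_id, levels = scanned))
  counts <- data.frame(gene = scanned, n_wbox = as.integer(n),
                       stringsAsFactors = FALSE)
  counts$target <- counts$n_wbox >= cfg$min_boxes_for_target
  bin <- ifelse(counts$n_wbox >= 5L, ">=5", as.character(counts$n_wbox))
  bins <- c("0", "1", "2", "3", "4", ">=5")
  histogram <- data.frame(bin = bins,
                          n_genes = as.integer(table(factor(bin, bins))),
                          stringsAsFactors = FALSE)
  list(counts = counts, histogram = histogram,
       targets = counts$gene[counts$target])
}

#' Exon/intron counts of a gene model
#'
#' @param gene Gene model from [read_gff3_genes()].
#' @return List with `n_exons` and `n_introns` (`n_exons - 1`).
#' @export
gene_structure <- function(gene) {
  n <- nrow(gene$exons)
  stopifnot(n >= 1)
  list(n_exons = n, n_introns = n - 1L)
}

#' Hypergeometric pathway enrichment of a target gene set
#'
#' For each pathway with K background genes, of which k are targets, the
#' enrichment p-value is the hypergeometric upper tail
#' P(X >= k | N, K, n) with N background genes and n targets, followed by
#' Benjamini-Hochberg correction across the tested pathways.
#'
#' @param targets Character vector of target genes (subset of background).
#' @param background Character vector of background genes.
#' @param pathway_map Data frame with columns `gene`, `pathway_id`,
#'   `pathway_name`; genes outside the background are ignored.
#' @param top_n Keep the `top_n` most significant pathways (default 20;
#'   `Inf` keeps all).
#' @return Data frame sorted by p-value: `pathway_id`, `pathway_name`, `k`,
#'   `K`, `n`, `N`, `p`, `q`.
#' @export
enrich <- function(targets, background, pathway_map, top_n = 20L) {
  if (length(targets) == 0L) stop("empty target set")
  if (!all(targets %in% background))
    stop("targets must be a subset of the background")
  pathway_map <- pathway_map[pathway_map$gene %in% background, , drop = FALSE]
  N <- length(unique(background))
  n <- length(unique(targets))
  sp <- split(pathway_map, pathway_map$pathway_id)
  rows <- lapply(sp, function(pm) {
    genes <- unique(pm$gene)
    K <- length(genes)
    k <- length(intersect(genes, targets))
    data.frame(pathway_id = pm$pathway_id[1], pathway_name = pm$pathway_name[1],
               k = k, K = K, n = n, N = N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$pathway_id), , drop = FALSE]
  utils::head(res, top_n)
}
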