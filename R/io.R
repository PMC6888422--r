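#' Read a FASTA file
#'
#' Wrapped sequence lines are concatenated, record order is preserved, and
#' sequences are uppercase-normalized. The record id is the first
#' whitespace-delimited token of the header; the rest is kept as the
#' description.
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(id = character(), desc = character(),
                      seq = character(), stringsAsFactors = FALSE))
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">"))
    stop("FASTA format error: sequence data before the first header")
  x <- Biostrings::readBStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(x))
  if (any(ids == "")) stop("FASTA record with empty id")
  if (any(nchar(seqs) == 0L)) stop("FASTA record with empty sequence")
  data.frame(id = unname(ids), desc = unname(desc), seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param records Data frame with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$desc) && nzchar(records$desc[i]))
      hdr <- paste(hdr, records$desc[i])
    writeLines(paste0(">", hdr), con)
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Builds one gene model per `gene` feature. When a gene has several mRNAs
#' the first one (file order) provides the exon structure. The translation
#' start is the minimum CDS start on the + strand and the maximum CDS end
#' on the - strand. GFF3 coordinates are 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional data frame from [read_fasta()]; when given, exon
#'   coordinates are validated against contig lengths.
#' @return Named list of gene models: each a list with `gene_id`, `contig`,
#'   `strand`, `cds_start` and `exons` (two-column matrix of 1-based
#'   inclusive start/end, sorted by start).
#' @export
read_gff3_genes <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  get_id <- function(i) as.character(md$ID[i])
  get_parent <- function(i) {
    p <- md$Parent[i]
    if (is.null(p)) return(NA_character_)
    p <- unlist(p)
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }
  parents <- vapply(seq_along(gr), get_parent, character(1))
  genes <- which(typ == "gene")
  out <- list()
  for (g in genes) {
    gid <- get_id(g)
    mrnas <- which(typ %in% c("mRNA", "transcript") & parents == gid)
    if (length(mrnas) > 0) {
      mid <- get_id(mrnas[1])
      kids <- which(parents == mid)
    } else {
      kids <- which(parents == gid)
    }
    ex <- kids[typ[kids] == "exon"]
    cds <- kids[typ[kids] == "CDS"]
    if (length(ex) == 0) ex <- cds  # single-feature fallback
    if (length(cds) == 0) cds <- ex
    exm <- cbind(start = GenomicRanges::start(gr)[ex],
                 end = GenomicRanges::end(gr)[ex])
    exm <- exm[order(exm[, "start"]), , drop = FALSE]
    if (any(exm[-1, "start"] <= exm[-nrow(exm), "end"]))
      stop("overlapping exons in gene ", gid)
    strand <- as.character(GenomicRanges::strand(gr)[g])
    if (!strand %in% c("+", "-")) stop("gene ", gid, " lacks a strand")
    cds_start <- if (strand == "+") min(GenomicRanges::start(gr)[cds])
                 else max(GenomicRanges::end(gr)[cds])
    contig <- as.character(GenomicRanges::seqnames(gr)[g])
    if (!is.null(genome)) {
      clen <- nchar(genome$seq[match(contig, genome$id)])
      if (is.na(clen)) stop("contig ", contig, " absent from genome FASTA")
      if (max(exm[, "end"]) > clen || min(exm[, "start"]) < 1L)
        stop("exon outside contig bounds for gene ", gid)
    }
    out[[gid]] <- list(gene_id = gid, contig = contig, strand = strand,
                       cds_start = as.integer(cds_start), exons = exm)
  }
  out
}

#' Write motif hits as BED6
#'
#' Input coordinates are 1-based inclusive (the package's genomic
#' convention); BED output is 0-based half-open. An empty hit set writes an
#' empty file.
#'
#' @param hits Data frame with columns `contig`, `start`, `end`, `name`,
#'   `strand` and optionally `score`.
#' @param path Output path.
#' @export
write_bed <- function(hits, path) {
  if (nrow(hits) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  stopifnot(all(hits$start >= 1L), all(hits$end >= hits$start))
  score <- if (is.null(hits$score)) 0L else hits$score
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", hits$contig,
                   as.integer(hits$start) - 1L, as.integer(hits$end),
                   hits$name, as.character(score), hits$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write a phylogenetic tree as Newick
#'
#' Branch lengths are kept; integer bootstrap supports, when present as
#' node labels, are written as internal labels.
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a table as TSV with a header row
#'
#' @param rows Data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
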