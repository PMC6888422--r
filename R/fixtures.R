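#' Load the packaged SaWRKY family table
#'
#' The packaged transcription of the published SaWRKY family table: one row
#' per gene with ORF length (amino acids), the heptapeptide motif string
#' (two-domain proteins have two 7-mers joined by "/"), the zinc-finger
#' labels, the predicted subcellular location, and the phylogenetic
#' group/subgroup. Zinc labels are stored in normalized canonical form.
#'
#' @return Data frame with columns `gene`, `orf_aa`, `motif_string`,
#'   `zinc_labels`, `subcellular`, `group` (values I, IIa-IIe, III), plus a
#'   derived `major_group` column (I, II, III).
#' @export
load_family_fixture <- function() {
  path <- system.file("extdata", "sawrky_family_table.tsv",
                      package = "wrkyfam", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(x) != 64L || anyDuplicated(x$gene) ||
      !setequal(x$gene, paste0("SaWRKY", 1:64)))
    stop("packaged family fixture is corrupt")
  if (any(x$orf_aa < 1L))
    stop("packaged family fixture has non-positive ORF lengths")
  for (labels in strsplit(x$zinc_labels, "/", fixed = TRUE))
    lapply(labels, parse_zinc_label)  # errors loudly on malformed labels
  if (!all(x$group %in% c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")))
    stop("packaged family fixture has invalid group labels")
  x$major_group <- ifelse(startsWith(x$group, "II") & x$group != "III",
                          "II", x$group)
  x
}

#' Load the packaged hormone-regulation gene lists
#'
#' The published direction calls for the 42 RT-qPCR-assayed genes: 13 genes
#' up- and 12 down-regulated by salicylic acid (SA), 18 up- and 6
#' down-regulated by methyl jasmonate (MeJA).
#'
#' @return Named list (`SA`, `MeJA`), each with character vectors `up` and
#'   `down`.
#' @export
load_regulation_fixture <- function() {
  path <- system.file("extdata", "sawrky_regulation.tsv",
                      package = "wrkyfam", mustWork = TRUE)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(x, x$hormone), function(h)
    list(up = h$gene[h$direction == "up"],
         down = h$gene[h$direction == "down"]))
  for (h in out)
    if (length(intersect(h$up, h$down)) > 0)
      stop("packaged regulation fixture has contradictory calls")
  out[c("SA", "MeJA")]
}

#' Load the packaged BLOSUM62 substitution matrix
#'
#' @return Numeric matrix with amino-acid dimnames.
#' @export
load_blosum62 <- function() {
  path <- system.file("extdata", "blosum62.tsv",
                      package = "wrkyfam", mustWork = TRUE)
  x <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(x[, -1])
  rownames(m) <- x$aa
  storage.mode(m) <- "double"
  m
}
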