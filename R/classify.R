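#' Rule-based group assignment
#'
#' Family members with two or more WRKY domains belong to group I; single-
#' domain members with the canonical C-C-H-H finger to group II and with
#' the C-C-H-C finger to group III. Single-domain proteins with a variant
#' or undetected finger are `"unresolved"` and deferred to phylogenetic
#' placement. A protein without any heptapeptide hit is not a family member
#' and raises an error.
#'
#' @param annotation A `wrky_annotation` from [annotate_protein()].
#' @return One of `"I"`, `"II"`, `"III"`, `"unresolved"`.
#' @export
assign_group <- function(annotation) {
  n <- length(annotation$hits)
  if (n == 0L)
    stop(annotation$protein_id, " has no WRKY domain; not a family member")
  if (n >= 2L) return("I")
  switch(annotation$zinc_type,
         "C-C-H-H" = "II",
         "C-C-H-C" = "III",
         "unresolved")
}

#' Phylogenetic subgroup assignment
#'
#' Places a query on a tree containing labeled reference sequences. The
#' unrooted tree is midpoint-rooted, then the walk proceeds from the query
#' leaf outward through its ancestors: the first enclosing clade that
#' contains at least one reference, all of whose references share one
#' label, gives that label (`basis = "clade"`). If no such clade exists,
#' the label of the reference at minimum patristic distance is used
#' (`basis = "nearest"`). The same mechanism resolves group placement for
#' proteins whose rule-based group is `"unresolved"` or exceptional
#' (e.g. single-domain members grouping with two-domain relatives).
#'
#' @param query_id Tip label of the query.
#' @param tree Unrooted `ape::phylo` containing the query and references.
#' @param reference_labels Named character vector: reference tip label ->
#'   subgroup label.
#' @return List with `subgroup` and `basis` (`"clade"` or `"nearest"`).
#' @export
assign_subgroup <- function(query_id, tree, reference_labels) {
  refs <- intersect(names(reference_labels), tree$tip.label)
  if (length(refs) == 0L) stop("no labeled references present in the tree")
  if (!query_id %in% tree$tip.label) stop("query not in tree: ", query_id)
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  tip <- match(query_id, rooted$tip.label)
  parent_of <- function(node) {
    e <- rooted$edge[rooted$edge[, 2] == node, 1]
    if (length(e) == 0) NA_integer_ else e[1]
  }
  node <- parent_of(tip)
  while (!is.na(node)) {
    clade_tips <- rooted$tip.label[
      unlist(phangorn::Descendants(rooted, node, type = "tips"))]
    in_refs <- intersect(clade_tips, refs)
    if (length(in_refs) > 0) {
      labs <- unique(reference_labels[in_refs])
      if (length(labs) == 1L)
        return(list(subgroup = unname(labs), basis = "clade"))
    }
    node <- parent_of(node)
  }
  pd <- ape::cophenetic.phylo(tree)[query_id, refs]
  nearest <- refs[order(pd, refs)][1]
  list(subgroup = unname(reference_labels[nearest]), basis = "nearest")
}

#' Summary statistics of a WRKY family table
#'
#' Works on the packaged family fixture (columns `gene`, `orf_aa`,
#' `motif_string`, `zinc_labels`, `group`) or on an [annotation_table()]
#' augmented with a `group` column (`length_aa` is then used for ORF
#' lengths).
#'
#' @param table Data frame, one row per gene.
#' @return List with `n_total`, `n_two_domain`, `zinc_type_counts` (named
#'   integer vector), `group_counts` (major groups), `subgroup_counts`,
#'   `orf_min`, `orf_max`, `orf_mean` (rounded to the nearest integer) and
#'   `pct_group_II` (rounded percent).
#' @export
summarize_family <- function(table) {
  stopifnot(nrow(table) >= 1)
  orf <- if (!is.null(table$orf_aa)) table$orf_aa else table$length_aa
  if (is.null(orf)) stop("table lacks an ORF/protein length column")
  n_dom <- lengths(strsplit(table$motif_string, "/", fixed = TRUE))
  ztype <- vapply(strsplit(table$zinc_labels, "/", fixed = TRUE),
                  function(labs) {
                    labs <- labs[nzchar(labs)]
                    if (length(labs) == 0) return("undetected")
                    classify_zinc_type(lapply(labs, parse_zinc_label))
                  }, character(1))
  out <- list(
    n_total = nrow(table),
    n_two_domain = sum(n_dom == 2L),
    zinc_type_counts = table(ztype),
    orf_min = min(orf),
    orf_max = max(orf),
    orf_mean = round(mean(orf))
  )
  if (!is.null(table$group)) {
    major <- ifelse(startsWith(table$group, "II") & table$group != "III",
                    "II", table$group)
    out$group_counts <- table(factor(major, levels = c("I", "II", "III")))
    out$subgroup_counts <- table(table$group)
    out$pct_group_II <- round(100 * mean(major == "II"))
  }
  out
}
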