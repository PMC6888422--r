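#' Alignment parameters
#'
#' @param submat Substitution matrix (defaults to the packaged BLOSUM62).
#' @param gap_open Score for the first residue of a gap run (negative).
#' @param gap_extend Score for each further gapped residue (negative).
#' @return Object of class `align_params`.
#' @export
align_params <- function(submat = load_blosum62(), gap_open = -10,
                         gap_extend = -1) {
  stopifnot(gap_open < 0, gap_extend < 0)
  structure(list(submat = submat, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap costs (Gotoh
#' three-state recursion). A gap run of length L costs
#' `gap_open + (L-1) * gap_extend`. Identity is the number of identical
#' aligned residues divided by the number of alignment columns.
#'
#' @param a,b Protein sequences.
#' @param params [align_params()].
#' @return List with `a`, `b` (gapped strings), `score`, `identity`.
#' @export
global_align <- function(a, b, params = align_params()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  nw_align_cpp(toupper(a), toupper(b), params$submat,
               params$gap_open, params$gap_extend)
}

# Insert gap columns (positions in the *current* row coordinate) into a
# gapped string.
.insert_gaps <- function(row, positions) {
  if (length(positions) == 0) return(row)
  chars <- strsplit(row, "")[[1]]
  for (p in sort(positions)) {
    chars <- append(chars, "-", after = p - 1L)
  }
  paste(chars, collapse = "")
}

#' Center-star multiple sequence alignment
#'
#' The center is the sequence minimizing the sum of pairwise alignment
#' distances (1 - identity) to all others. Every other sequence is aligned
#' pairwise to the center and the pairwise gaps are merged under the
#' "once a gap, always a gap" rule.
#'
#' @param seqs Named character vector of >= 2 sequences.
#' @param params [align_params()].
#' @return Object of class `wrky_msa`: list with `ids`, `rows` (equal-length
#'   gapped strings) and `ncol`.
#' @export
center_star_msa <- function(seqs, params = align_params()) {
  n <- length(seqs)
  if (n < 2) stop("center_star_msa needs at least 2 sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  ids <- names(seqs)
  dist_sum <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- 1 - global_align(seqs[i], seqs[j], params)$identity
    dist_sum[i] <- dist_sum[i] + d
    dist_sum[j] <- dist_sum[j] + d
  }
  center <- which(dist_sum == min(dist_sum))[1]

  master <- seqs[[center]]          # center row, accumulating gaps
  rows <- list()                    # finished non-center rows (gapped)
  for (k in seq_len(n)[-center]) {
    aln <- global_align(seqs[[center]], seqs[[k]], params)
    # merge aln (center without master gaps) into the running master
    mc <- strsplit(master, "")[[1]]
    ac <- strsplit(aln$a, "")[[1]]
    sc <- strsplit(aln$b, "")[[1]]
    new_master <- character(0)
    new_row <- character(0)
    add_master <- integer(0)   # columns to add to existing rows
    i <- 1L; j <- 1L
    while (i <= length(mc) || j <= length(ac)) {
      if (i <= length(mc) && mc[i] == "-") {
        # gap column from an earlier merge: new sequence gets a gap
        new_master <- c(new_master, "-"); new_row <- c(new_row, "-")
        i <- i + 1L
      } else if (j <= length(ac) && ac[j] == "-") {
        # gap column new in this pairwise alignment: existing rows get a gap
        new_master <- c(new_master, "-"); new_row <- c(new_row, sc[j])
        add_master <- c(add_master, length(new_master))
        j <- j + 1L
      } else {
        # residue column of the center in both coordinates
        new_master <- c(new_master, mc[i]); new_row <- c(new_row, sc[j])
        i <- i + 1L; j <- j + 1L
      }
    }
    rows <- lapply(rows, .insert_gaps, positions = add_master)
    rows[[length(rows) + 1L]] <- paste(new_row, collapse = "")
    master <- paste(new_master, collapse = "")
  }
  all_rows <- character(n)
  all_rows[center] <- master
  all_rows[seq_len(n)[-center]] <- unlist(rows)
  structure(list(ids = ids, rows = all_rows,
                 ncol = nchar(all_rows[1])), class = "wrky_msa")
}

#' @export
print.wrky_msa <- function(x, ...) {
  cat(sprintf("<wrky_msa> %d sequences x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

#' Pairwise distances from a multiple alignment
#'
#' Columns containing any gap are dropped first (complete deletion), then
#' the proportion of mismatching retained columns gives the p-distance; the
#' Poisson correction is d = -ln(1 - p).
#'
#' @param msa A `wrky_msa`.
#' @param model `"poisson"` (default) or `"p_distance"`.
#' @return Symmetric distance matrix with sequence ids as dimnames.
#' @export
msa_distance_matrix <- function(msa, model = c("poisson", "p_distance")) {
  model <- match.arg(model)
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  keep <- colSums(mat == "-") == 0L
  if (!any(keep)) stop("no gap-free columns after complete deletion")
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- mean(mat[i, ] != mat[j, ])
    if (model == "poisson") {
      if (p >= 1) stop("saturated pair (p = 1) under the Poisson model")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}
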