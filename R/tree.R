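#' Neighbor-joining tree reconstruction
#'
#' Saitou-Nei neighbor joining: at each step the pair minimizing
#' Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k) is joined, with
#' branch lengths from the standard NJ formulas. Ties on Q are broken
#' lexicographically by the smallest leaf label contained in each cluster,
#' so the result is deterministic. Negative branch-length estimates are
#' clamped to zero with the deficit moved to the sibling edge so that the
#' joined pair's path length is preserved. NJ is exact (topology and branch
#' lengths) on additive distance matrices.
#'
#' @param D Symmetric distance matrix with unique dimnames, n >= 3.
#' @return Unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  ids <- rownames(D)
  if (is.null(ids) || anyDuplicated(ids)) stop("D needs unique row names")
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")

  nwk <- ids                   # newick fragment per active cluster
  lab <- ids                   # lexicographic tie-break label per cluster
  d <- D
  fmt <- function(x) sprintf("%.12g", x)

  while (nrow(d) > 3) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij) {
      ll <- sort(c(lab[ij[1]], lab[ij[2]]))
      paste(ll, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    dij <- d[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- max(0, lj + li); li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_lab <- min(lab[i], lab[j])
    dk <- (d[i, -c(i, j)] + d[j, -c(i, j)] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- d[keep, keep, drop = FALSE]
    d <- rbind(cbind(d, dk), c(dk, 0))
    nwk <- c(nwk[keep], new_nwk)
    lab <- c(lab[keep], new_lab)
  }
  # final three-way join: closed-form edge lengths
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  l1 <- max(0, l1); l2 <- max(0, l2); l3 <- max(0, l3)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(l1), nwk[2], fmt(l2),
                 nwk[3], fmt(l3))
  ape::read.tree(text = txt)
}

# run code with a local, restorable RNG stream
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `reps` times; each
#' replicate alignment is taken through the same distance model and NJ
#' reconstruction, and the support of an internal edge of the full-data
#' tree is the percentage of replicate trees containing the same
#' bipartition. Deterministic given `seed`.
#'
#' @param msa A `wrky_msa`.
#' @param model Distance model, see [msa_distance_matrix()].
#' @param reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return The full-data NJ tree with integer percentage supports in
#'   `node.label` (the root entry is `NA`).
#' @export
bootstrap_support <- function(msa, model = "poisson", reps = 1000L,
                              seed = 1L) {
  ref <- neighbor_joining(msa_distance_matrix(msa, model))
  mat <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(mat) <- msa$ids
  boot <- .with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      bm <- structure(list(ids = msa$ids,
                           rows = apply(mat[, cols, drop = FALSE], 1, paste,
                                        collapse = ""),
                           ncol = length(cols)), class = "wrky_msa")
      neighbor_joining(msa_distance_matrix(bm, model))
    })
  })
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  support <- round(100 * counts / reps)
  support[1] <- NA  # root of the unrooted representation is not an edge
  ref$node.label <- support
  ref
}
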