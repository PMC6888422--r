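# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most naive route available so that the package
# implementations are checked against a second, unrelated computation.

# every 7-residue window checked against the literal consensus set
oracle_scan_7mers <- function(seq, consensi) {
  n <- nchar(seq)
  hits <- data.frame(start = integer(), hepta = character())
  if (n < 7) return(hits)
  for (i in 1:(n - 6)) {
    w <- substr(seq, i, i + 6)
    if (w %in% consensi)
      hits <- rbind(hits, data.frame(start = i, hepta = w))
  }
  hits
}

# every 6-bp window checked against both strand patterns
oracle_scan_wbox <- function(seq, both = TRUE) {
  fw <- c(outer(c("C", "T"), c("C", "T"),
                function(a, b) paste0(a, "TGAC", b)))
  rv <- vapply(fw, wrkyfam::revcomp, character(1))
  n <- nchar(seq)
  out <- data.frame(offset = integer(), strand = character())
  if (n < 6) return(out)
  for (i in 1:(n - 5)) {
    w <- substr(seq, i, i + 5)
    if (w %in% fw) out <- rbind(out, data.frame(offset = i, strand = "+"))
    if (both && w %in% rv)
      out <- rbind(out, data.frame(offset = i, strand = "-"))
  }
  out[order(out$offset, out$strand), , drop = FALSE]
}

# exhaustive enumeration of all global alignments (affine gaps: a run of
# length L costs open + (L-1) * extend); returns the optimal score
oracle_align_score <- function(a, b, submat, open, extend) {
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > nchar(a) && j > nchar(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= nchar(a) && j <= nchar(b)) {
      s <- submat[substr(a, i, i), substr(b, j, j)]
      rec(i + 1, j + 1, score + s, "M")
    }
    if (i <= nchar(a))
      rec(i + 1, j, score + if (last == "X") extend else open, "X")
    if (j <= nchar(b))
      rec(i, j + 1, score + if (last == "Y") extend else open, "Y")
  }
  rec(1, 1, 0, "start")
  best
}

# upper-tail hypergeometric probability by explicit combinatorics
oracle_hyper_upper <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# greedy identity clustering recomputed from a full pairwise identity matrix
oracle_greedy_dedupe <- function(ids, seqs, idmat, threshold) {
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]
  reps <- character(0)
  for (id in ids) {
    hit <- FALSE
    for (r in reps) {
      if (idmat[id, r] >= threshold) { hit <- TRUE; break }
    }
    if (!hit) reps <- c(reps, id)
  }
  reps
}

# random additive distance matrix from a random tree, plus the tree
oracle_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

random_protein <- function(n) {
  paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
               replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
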