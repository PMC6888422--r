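#' Scan a protein for WRKY heptapeptide matches
#'
#' Slides over every 7-residue window and reports each match against the
#' grammar's consensus set, left to right; overlapping matches are all
#' reported. Positions are 1-based. Non-standard characters draw a warning
#' and never match.
#'
#' @param seq Uppercase amino-acid string.
#' @param grammar A [wrky_grammar()].
#' @return Data frame with columns `start` (1-based) and `hepta`.
#' @export
scan_heptapeptide <- function(seq, grammar = wrky_grammar()) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("[^A-Z]", seq))
    warning("non-standard characters in protein sequence; they never match")
  n <- nchar(seq)
  if (n < 7L)
    return(data.frame(start = integer(), hepta = character()))
  pat <- paste0("(?=(", paste(grammar$heptapeptides, collapse = "|"), "))")
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(), hepta = character()))
  starts <- as.integer(m)
  data.frame(start = starts,
             hepta = substring(seq, starts, starts + 6L),
             stringsAsFactors = FALSE)
}

# Search [from, cap] for the first C-Xa-C-Xb-H-X-Z arrangement, preferring
# the smallest c1 position, then the smallest a, then the smallest b.
.find_finger <- function(seq, from, cap, grammar) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cap <- min(cap, n)
  a_rng <- grammar$c1_c2_spacing
  b_rng <- grammar$c2_h_spacing
  hi <- min(from + grammar$finger_window - 1L, cap)
  c1 <- from
  while (c1 <= hi) {
    if (chars[c1] == "C") {
      for (a in a_rng[1]:a_rng[2]) {
        c2 <- c1 + a + 1L
        if (c2 > cap || chars[c2] != "C") next
        for (b in b_rng[1]:b_rng[2]) {
          h <- c2 + b + 1L
          z <- h + 2L
          if (z > cap) next
          if (chars[h] == "H") {
            return(list(c1_pos = c1, c2_pos = c2, h1_pos = h, z_pos = z,
                        a = a, b = b, z_residue = chars[z]))
          }
        }
      }
    }
    c1 <- c1 + 1L
  }
  NULL
}

#' Extract the zinc-finger pattern downstream of a heptapeptide
#'
#' Searches the window after the heptapeptide for the first
#' C-Xa-C-Xb-H-X-Z arrangement satisfying both spacing ranges, preferring
#' the smallest first-cysteine position, then the smallest `a`, then the
#' smallest `b`. Absence is a value, not an error.
#'
#' @param seq Protein sequence.
#' @param hepta_start 1-based start of the heptapeptide hit.
#' @param grammar A [wrky_grammar()].
#' @param cap Last position allowed for the arrangement (defaults to the
#'   sequence end; set to just before the next heptapeptide when scanning
#'   multi-domain proteins).
#' @return A pattern list (`c1_pos`, `c2_pos`, `h1_pos`, `z_pos`, `a`, `b`,
#'   `z_residue`; 1-based) or `NULL` when no arrangement exists.
#' @export
extract_zinc_finger <- function(seq, hepta_start, grammar = wrky_grammar(),
                                cap = nchar(seq)) {
  seq <- toupper(seq)
  .find_finger(seq, from = hepta_start + 7L, cap = cap, grammar = grammar)
}

#' Scan for successive zinc-finger arrangements after a heptapeptide
#'
#' Some annotated family members carry more than one finger arrangement
#' behind a single heptapeptide. After the first arrangement (found as in
#' [extract_zinc_finger()]), the search continues for further arrangements,
#' each starting within the grammar window after the previous arrangement's
#' end, up to `cap`.
#'
#' @inheritParams extract_zinc_finger
#' @return List of pattern lists (possibly empty).
#' @export
scan_zinc_fingers <- function(seq, hepta_start, grammar = wrky_grammar(),
                              cap = nchar(seq)) {
  seq <- toupper(seq)
  out <- list()
  from <- hepta_start + 7L
  repeat {
    p <- .find_finger(seq, from = from, cap = cap, grammar = grammar)
    if (is.null(p)) break
    out[[length(out) + 1L]] <- p
    from <- p$z_pos + 1L
  }
  out
}

#' Classify the zinc-finger type of a protein
#'
#' A protein with no detected finger is `"undetected"`. A protein with at
#' least one finger whose fourth coordinating residue is histidine is the
#' canonical `"C-C-H-H"` type; otherwise the type follows the last (most
#' C-terminal) finger's residue, e.g. `"C-C-H-C"` for the group III motif
#' or variant labels such as `"C-C-H-T"`.
#'
#' @param patterns List of zinc-finger patterns (possibly empty).
#' @return Type label string.
#' @export
classify_zinc_type <- function(patterns) {
  if (length(patterns) == 0L) return("undetected")
  z <- vapply(patterns, function(p) p$z_residue, character(1))
  if (any(z == "H")) return("C-C-H-H")
  paste0("C-C-H-", z[length(z)])
}

#' Annotate a protein with WRKY domains and zinc-finger type
#'
#' Composes the heptapeptide scan, the per-domain zinc-finger scan (capped
#' at the next heptapeptide for multi-domain proteins) and zinc-finger
#' typing. Proteins with zero heptapeptide hits are annotated but are not
#' family members.
#'
#' @param id Protein identifier.
#' @param seq Protein sequence.
#' @param grammar A [wrky_grammar()].
#' @return Object of class `wrky_annotation`: list with `protein_id`,
#'   `length_aa`, `hits` (each with `hepta_start`, `hepta_seq`, `fingers`)
#'   and `zinc_type`.
#' @export
annotate_protein <- function(id, seq, grammar = wrky_grammar()) {
  seq <- toupper(seq)
  hep <- scan_heptapeptide(seq, grammar)
  hits <- list()
  if (nrow(hep) > 0L) {
    caps <- c(hep$start[-1L] - 1L, nchar(seq))
    for (i in seq_len(nrow(hep))) {
      fingers <- scan_zinc_fingers(seq, hep$start[i], grammar, cap = caps[i])
      hits[[i]] <- list(hepta_start = hep$start[i],
                        hepta_seq = hep$hepta[i],
                        fingers = fingers)
    }
  }
  patterns <- unlist(lapply(hits, `[[`, "fingers"), recursive = FALSE)
  structure(list(protein_id = id, length_aa = nchar(seq), hits = hits,
                 zinc_type = classify_zinc_type(patterns)),
            class = "wrky_annotation")
}

#' @export
print.wrky_annotation <- function(x, ...) {
  cat(sprintf("<wrky_annotation> %s (%d aa): %d domain(s), zinc type %s\n",
              x$protein_id, x$length_aa, length(x$hits), x$zinc_type))
  invisible(x)
}

#' Annotate every record of a protein set
#'
#' @param records Data frame as returned by [read_fasta()] (columns `id`,
#'   `seq`).
#' @param grammar A [wrky_grammar()].
#' @return Named list of [annotate_protein()] results.
#' @export
annotate_proteins <- function(records, grammar = wrky_grammar()) {
  anns <- Map(annotate_protein, records$id, records$seq,
              MoreArgs = list(grammar = grammar))
  names(anns) <- records$id
  anns
}

#' Tabulate annotations
#'
#' @param annotations List of `wrky_annotation` objects.
#' @return Data frame with one row per protein: `protein`, `length_aa`,
#'   `n_domains`, `motif_string` (heptapeptides joined by "/"),
#'   `zinc_labels` (formatted finger labels joined by "/"), `zinc_type`.
#' @export
annotation_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    labs <- unlist(lapply(a$hits, function(h)
      vapply(h$fingers, format_zinc_label, character(1))))
    data.frame(protein = a$protein_id, length_aa = a$length_aa,
               n_domains = length(a$hits),
               motif_string = paste(vapply(a$hits, `[[`, character(1),
                                           "hepta_seq"), collapse = "/"),
               zinc_labels = paste(labs, collapse = "/"),
               zinc_type = a$zinc_type,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Remove redundant family members by greedy identity clustering
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted by
#' length (longest first, ties by identifier), and each sequence joins the
#' first retained representative to which its global-alignment identity is
#' at least `identity_threshold`; otherwise it becomes a new
#' representative.
#'
#' @param records Data frame with columns `id`, `seq`.
#' @param identity_threshold Identity fraction (default 0.95).
#' @param params Alignment parameters from [align_params()].
#' @return List with `representatives` (character vector of ids, in
#'   retention order) and `clusters` (named list mapping representative to
#'   member ids, representative included).
#' @export
dedupe_members <- function(records, identity_threshold = 0.95,
                           params = align_params()) {
  stopifnot(nrow(records) >= 1)
  ord <- order(-nchar(records$seq), records$id)
  ids <- records$id[ord]
  seqs <- records$seq[ord]
  reps <- character(0)
  rep_seqs <- character(0)
  clusters <- list()
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (j in seq_along(reps)) {
      aln <- global_align(seqs[i], rep_seqs[j], params)
      if (aln$identity >= identity_threshold) {
        clusters[[reps[j]]] <- c(clusters[[reps[j]]], ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, ids[i])
      rep_seqs <- c(rep_seqs, seqs[i])
      clusters[[ids[i]]] <- ids[i]
    }
  }
  list(representatives = reps, clusters = clusters)
}
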