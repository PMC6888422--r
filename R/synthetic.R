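# Flank/spacer alphabet for synthetic proteins: the 20 standard residues
# minus W, C and H, so the only tryptophans (hence heptapeptides) and the
# only zinc-coordinating C/H residues in a synthetic protein are planted
# ones. This makes planted-truth recovery exact rather than probabilistic.
.AA_NEUTRAL <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N", "P", "Q",
                 "R", "S", "T", "V", "Y")

.rand_flank <- function(n) {
  if (n <= 0) return("")
  paste(sample(.AA_NEUTRAL, n, replace = TRUE), collapse = "")
}

.finger_seq <- function(a, b, z) {
  paste0("C", .rand_flank(a), "C", .rand_flank(b), "H",
         sample(.AA_NEUTRAL, 1), z)
}

#' Generate a synthetic WRKY protein with planted domains
#'
#' Builds a protein of exactly `length_aa` residues containing the planted
#' heptapeptide(s), each followed by the planted zinc-finger
#' arrangement(s) (a domain may chain several finger arrangements, as some
#' annotated family members do). Flanks and spacers are drawn from an
#' alphabet without W, C or H, so the annotator recovers exactly the
#' planted truth. Deterministic given `seed` (flanks are drawn left to
#' right, one domain at a time).
#'
#' @param id Sequence identifier.
#' @param domains List of domains; each a list with `hepta` (7-mer) and
#'   `fingers` (possibly empty list of lists with `a`, `b`, `z`).
#' @param length_aa Total protein length; `NA` for minimal padding.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param grammar Grammar the planted spacings must respect (checked unless
#'   `negative_control` allows out-of-range plans).
#' @param negative_control Allow spacings outside the grammar ranges.
#' @return One-row data frame (`id`, `desc`, `seq`).
#' @export
gen_wrky_protein <- function(id, domains, length_aa = NA, seed = NULL,
                             grammar = wrky_grammar(),
                             negative_control = FALSE) {
  gen <- function() {
    pieces <- character(0)
    core_len <- 0L
    n_dom <- length(domains)
    for (d in domains) {
      stopifnot(nchar(d$hepta) == 7L)
      dom <- d$hepta
      for (f in d$fingers) {
        if (!negative_control) {
          ok <- f$a >= grammar$c1_c2_spacing[1] &&
            f$a <= grammar$c1_c2_spacing[2] &&
            f$b >= grammar$c2_h_spacing[1] && f$b <= grammar$c2_h_spacing[2]
          if (!ok) stop("planted spacing outside the grammar ranges")
        }
        gap <- sample(0:5, 1)
        dom <- paste0(dom, .rand_flank(gap), .finger_seq(f$a, f$b, f$z))
      }
      pieces <- c(pieces, dom)
      core_len <- core_len + nchar(dom)
    }
    if (is.na(length_aa)) {
      pad <- rep(2L, n_dom + 1L)
    } else {
      slack <- length_aa - core_len
      if (slack < n_dom)  # at least one residue between adjacent domains
        stop("protein too short for the planted domains: ", id)
      w <- if (n_dom > 0) rep(1, n_dom + 1L) else 1
      pad <- floor(slack * w / sum(w))
      pad[1] <- pad[1] + (slack - sum(pad))
    }
    out <- .rand_flank(pad[1])
    for (i in seq_along(pieces))
      out <- paste0(out, pieces[[i]], .rand_flank(pad[i + 1L]))
    out
  }
  seq <- if (is.null(seed)) gen() else .with_seed(seed, gen())
  if (!is.na(length_aa) && nchar(seq) != length_aa)
    stop("internal length accounting error")
  # planted-truth verification: the annotation must equal the plan
  ann <- annotate_protein(id, seq, grammar)
  if (length(ann$hits) != length(domains))
    stop("generated protein does not recover its planted domain count")
  for (i in seq_along(domains)) {
    if (ann$hits[[i]]$hepta_seq != domains[[i]]$hepta ||
        length(ann$hits[[i]]$fingers) != length(domains[[i]]$fingers))
      stop("generated protein does not recover its planted fingers")
  }
  data.frame(id = id, desc = "", seq = seq, stringsAsFactors = FALSE)
}

# translate a fixture row into a domain plan: heptapeptides get one finger
# each in label order; surplus labels are chained after the last domain
.fixture_domains <- function(motif_string, zinc_labels) {
  heptas <- strsplit(motif_string, "/", fixed = TRUE)[[1]]
  labels <- strsplit(zinc_labels, "/", fixed = TRUE)[[1]]
  labels <- labels[nzchar(labels)]
  if (length(labels) < length(heptas))
    stop("fewer zinc labels than heptapeptides")
  fingers <- lapply(labels, function(l) {
    p <- parse_zinc_label(l)
    list(a = p$a, b = p$b, z = p$z_residue)
  })
  doms <- list()
  for (i in seq_along(heptas)) {
    if (i < length(heptas)) doms[[i]] <- list(hepta = heptas[i],
                                              fingers = fingers[i])
    else doms[[i]] <- list(hepta = heptas[i],
                           fingers = fingers[i:length(fingers)])
  }
  doms
}

#' Generate the synthetic SaWRKY family FASTA from the packaged fixture
#'
#' One synthetic protein per fixture row, of exactly the row's ORF length,
#' embedding the row's heptapeptide(s) and zinc-finger label(s). Regenerating
#' with the same seed is byte-identical.
#'
#' @param fixture Family fixture data frame (default
#'   [load_family_fixture()]).
#' @param seed Integer seed.
#' @return Data frame of 64 records (`id`, `desc`, `seq`).
#' @export
gen_family_fasta <- function(fixture = load_family_fixture(), seed = 1L) {
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(fixture)), function(i) {
      gen_wrky_protein(fixture$gene[i],
                       .fixture_domains(fixture$motif_string[i],
                                        fixture$zinc_labels[i]),
                       length_aa = fixture$orf_aa[i], seed = NULL)
    })
    do.call(rbind, rows)
  })
}

# ---- genome generation -------------------------------------------------

# remove every W-box match (both strands) from a DNA string by redrawing
# matched bases until the sequence is clean
.scrub_wbox <- function(seq, cfg) {
  repeat {
    hits <- suppressWarnings(scan_wbox(seq, cfg))
    if (nrow(hits) == 0L) return(seq)
    chars <- strsplit(seq, "")[[1]]
    for (o in hits$offset) {
      w <- nchar(cfg$consensus)
      chars[o:(o + w - 1L)] <- sample(c("A", "C", "G", "T"), w,
                                      replace = TRUE)
    }
    seq <- paste(chars, collapse = "")
  }
}

.realize_wbox <- function(cfg) {
  paste(vapply(strsplit(cfg$consensus, "")[[1]], function(ch) {
    opts <- strsplit(.IUPAC[[ch]], "")[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

# an oriented promoter string with exactly n planted W-boxes
.planted_promoter <- function(n, cfg) {
  L <- cfg$promoter_len
  w <- nchar(cfg$consensus)
  for (try in 1:100) {
    bg <- .scrub_wbox(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                            collapse = ""), cfg)
    if (n == 0L) {
      if (nrow(scan_wbox(bg, cfg)) == 0L) return(bg)
      next
    }
    # non-overlapping offsets
    offs <- integer(0)
    avail <- seq_len(L - w + 1L)
    for (k in seq_len(n)) {
      if (length(avail) == 0L) break
      o <- if (length(avail) == 1L) avail else sample(avail, 1)
      offs <- c(offs, o)
      avail <- avail[abs(avail - o) >= w]
    }
    if (length(offs) < n) stop("promoter too crowded for ", n, " boxes")
    chars <- strsplit(bg, "")[[1]]
    for (o in offs) {
      box <- .realize_wbox(cfg)
      if (cfg$scan_both_strands && stats::runif(1) < 0.5) box <- revcomp(box)
      chars[o:(o + w - 1L)] <- strsplit(box, "")[[1]]
    }
    cand <- paste(chars, collapse = "")
    if (nrow(scan_wbox(cand, cfg)) == n) return(cand)
    # a planting junction created an extra match; redraw
  }
  stop("failed to plant exactly ", n, " W-boxes")
}

#' Generate a synthetic genome with planted per-gene W-box counts
#'
#' Each planned gene gets its own contig holding a gene body (exons
#' separated by introns) and a promoter of `cfg$promoter_len` bp upstream
#' of the translation start, into which exactly the planned number of
#' W-box consensus instances is planted at random non-overlapping offsets
#' (random strand each). Background sequence is rejection-sampled free of
#' accidental consensus matches on either strand, so planted counts are
#' exact truths. Deterministic given `seed`.
#'
#' @param plan Data frame with columns `gene`, `strand` (+/-), `n_boxes`
#'   and optionally `n_exons` (default 3).
#' @param cfg [promoter_config()].
#' @param seed Integer seed.
#' @param exon_len,intron_len Exon/intron sizes (bp) of the gene bodies.
#' @return List with `genome` (FASTA records data frame), `gff` (character
#'   vector of GFF3 lines), `genes` (gene-model list matching
#'   [read_gff3_genes()] output) and `truth` (the plan with a `contig`
#'   column).
#' @export
gen_genome <- function(plan, cfg = promoter_config(), seed = 1L,
                       exon_len = 300L, intron_len = 100L) {
  stopifnot(all(plan$strand %in% c("+", "-")), all(plan$n_boxes >= 0))
  if (is.null(plan$n_exons)) plan$n_exons <- 3L
  .with_seed(seed, {
    recs <- list()
    gff <- c("##gff-version 3")
    genes <- list()
    pad <- 50L
    L <- cfg$promoter_len
    for (i in seq_len(nrow(plan))) {
      g <- plan$gene[i]
      ne <- plan$n_exons[i]
      body_len <- ne * exon_len + (ne - 1L) * intron_len
      contig_id <- paste0("ctg_", g)
      st <- plan$strand[i]
      prom <- .planted_promoter(plan$n_boxes[i], cfg)
      body <- .scrub_wbox(paste(sample(c("A", "C", "G", "T"),
                                       body_len + pad, replace = TRUE),
                                collapse = ""), cfg)
      if (st == "+") {
        # promoter [1, L], gene body immediately downstream, pad tail
        contig <- paste0(prom, body)
        gstart <- L + 1L
      } else {
        # pad, gene body, then the promoter region [cds_start+1,
        # cds_start+L] holding the reverse complement of the oriented
        # promoter string
        contig <- paste0(substring(body, 1, pad),
                         substring(body, pad + 1L), revcomp(prom))
        gstart <- pad + 1L
      }
      exon_starts <- gstart + (seq_len(ne) - 1L) * (exon_len + intron_len)
      exon_ends <- exon_starts + exon_len - 1L
      gend <- exon_ends[ne]
      cds_start <- if (st == "+") exon_starts[1] else gend
      gff <- c(gff,
               sprintf("%s\twrkyfam_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       contig_id, exon_starts[1], gend, st, g),
               sprintf("%s\twrkyfam_sim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       contig_id, exon_starts[1], gend, st, g, g))
      for (e in seq_len(ne)) {
        gff <- c(gff,
                 sprintf("%s\twrkyfam_sim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                         contig_id, exon_starts[e], exon_ends[e], st, g, e, g),
                 sprintf("%s\twrkyfam_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s.t1",
                         contig_id, exon_starts[e], exon_ends[e], st, g, e, g))
      }
      recs[[i]] <- data.frame(id = contig_id, desc = "", seq = contig,
                              stringsAsFactors = FALSE)
      genes[[g]] <- list(gene_id = g, contig = contig_id, strand = st,
                         cds_start = as.integer(cds_start),
                         exons = cbind(start = exon_starts, end = exon_ends))
    }
    truth <- plan
    truth$contig <- paste0("ctg_", plan$gene)
    list(genome = do.call(rbind, recs), gff = gff, genes = genes,
         truth = truth)
  })
}

# ---- qPCR generation ---------------------------------------------------

#' Generate a synthetic triplicate Cq table with planted fold changes
#'
#' For each gene x hormone, target Cq at timepoint t is
#' `baseline - log2(fold_t) + Normal(0, noise_sd)` per replicate
#' (fold = 1 at the calibrator), and each reference-gene Cq is
#' `ref_baseline + Normal(0, ref_sd)` per well, so the expected recovered
#' relative expression equals the planted fold. Deterministic given `seed`
#' (wells are drawn row by row in plan order, timepoint-major).
#'
#' @param plan Data frame with columns `gene`, `hormone`, `fold_3h`,
#'   `fold_6h` (positive folds).
#' @param noise_sd Replicate noise SD on the target Cq (cycles).
#' @param ref_sd Reference-gene stability SD (cycles).
#' @param n_replicates Biological replicates per condition (default 3).
#' @param seed Integer seed.
#' @param timepoints Timepoints in hours (first is the calibrator).
#' @return Long-format data frame: `gene`, `hormone`, `timepoint`,
#'   `replicate`, `cq_target`, `cq_ref1`, `cq_ref2`.
#' @export
gen_qpcr <- function(plan, noise_sd = 0.1, ref_sd = 0.05, n_replicates = 3L,
                     seed = 1L, timepoints = c(0, 3, 6)) {
  stopifnot(all(c("gene", "hormone", "fold_3h", "fold_6h") %in% names(plan)),
            all(plan$fold_3h > 0), all(plan$fold_6h > 0),
            noise_sd >= 0, ref_sd >= 0)
  .with_seed(seed, {
    base_target <- 26
    base_ref <- 18
    rows <- list()
    for (i in seq_len(nrow(plan))) {
      folds <- c(1, plan$fold_3h[i], plan$fold_6h[i])[seq_along(timepoints)]
      for (t in seq_along(timepoints)) {
        for (r in seq_len(n_replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = plan$gene[i], hormone = plan$hormone[i],
            timepoint = timepoints[t], replicate = r,
            cq_target = base_target - log2(folds[t]) +
              stats::rnorm(1, 0, noise_sd),
            cq_ref1 = base_ref + stats::rnorm(1, 0, ref_sd),
            cq_ref2 = base_ref + stats::rnorm(1, 0, ref_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}

#' Build a qPCR generation plan from the packaged regulation fixture
#'
#' Genes in a hormone's up list get `up_fold` at both treated timepoints,
#' genes in its down list get `down_fold`, all other genes of the assayed
#' universe get 1. The universe defaults to SaWRKY1..SaWRKY42, the set
#' assayed by RT-qPCR.
#'
#' @param regulation Regulation fixture (default
#'   [load_regulation_fixture()]).
#' @param genes Gene universe.
#' @param up_fold,down_fold Planted fold changes (defaults 3.0 and 0.3).
#' @return Plan data frame for [gen_qpcr()].
#' @export
qpcr_plan_from_fixture <- function(regulation = load_regulation_fixture(),
                                   genes = paste0("SaWRKY", 1:42),
                                   up_fold = 3, down_fold = 0.3) {
  rows <- lapply(names(regulation), function(h) {
    fold <- ifelse(genes %in% regulation[[h]]$up, up_fold,
                   ifelse(genes %in% regulation[[h]]$down, down_fold, 1))
    data.frame(gene = genes, hormone = h, fold_3h = fold, fold_6h = fold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Generate a Poisson count matrix from true expression levels
#'
#' Counts are Poisson with mean
#' `true_expr * (length_bp/1000) * (mapped_total/1e6)`, so [rpkm()] applied
#' to the output is an unbiased estimator of `true_expr`.
#'
#' @param true_expr Genes x samples matrix of true expression levels.
#' @param length_bp Per-gene lengths (bp).
#' @param mapped_totals Per-sample library sizes.
#' @param seed Integer seed.
#' @return Integer matrix of counts with the input dimnames.
#' @export
gen_count_matrix <- function(true_expr, length_bp, mapped_totals, seed = 1L) {
  stopifnot(nrow(true_expr) == length(length_bp),
            ncol(true_expr) == length(mapped_totals))
  lambda <- sweep(sweep(true_expr, 1, length_bp / 1e3, "*"), 2,
                  mapped_totals / 1e6, "*")
  .with_seed(seed, {
    m <- matrix(stats::rpois(length(lambda), lambda), nrow = nrow(lambda))
    dimnames(m) <- dimnames(true_expr)
    m
  })
}

# ---- synthetic references for subgroup placement -----------------------

.mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  k <- max(0L, round(rate * length(chars)))
  if (k == 0L) return(seq)
  pos <- sample(seq_along(chars), k)
  for (p in pos)
    chars[p] <- sample(setdiff(.AA_NEUTRAL, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Generate a synthetic labeled reference set for subgroup placement
#'
#' A stand-in for a curated, subgroup-labeled WRKY reference panel (e.g.
#' the Arabidopsis WRKY domains): each subgroup descends from its own
#' ancestor sequence (strong between-subgroup divergence), and members
#' diverge mildly within the subgroup. Entirely synthetic; replace with a
#' curated panel for real analyses.
#'
#' @param subgroups Subgroup labels.
#' @param n_per References per subgroup.
#' @param domain_len Domain length (aa).
#' @param between_div,within_div Mutated fraction between/within subgroups.
#' @param seed Integer seed.
#' @return List with `records` (data frame `id`, `desc`, `seq`), `labels`
#'   (named character vector id -> subgroup) and `ancestors` (named
#'   character vector subgroup -> ancestral sequence).
#' @export
gen_subgroup_references <- function(subgroups = c("IIa", "IIb", "IIc",
                                                  "IId", "IIe"),
                                    n_per = 3L, domain_len = 60L,
                                    between_div = 0.5, within_div = 0.05,
                                    seed = 1L) {
  .with_seed(seed, {
    root <- .rand_flank(domain_len)
    anc <- vapply(subgroups, function(s) .mutate_seq(root, between_div),
                  character(1))
    ids <- character(0); seqs <- character(0); labs <- character(0)
    for (s in subgroups) {
      for (k in seq_len(n_per)) {
        ids <- c(ids, sprintf("ref_%s_%d", s, k))
        seqs <- c(seqs, .mutate_seq(anc[[s]], within_div))
        labs <- c(labs, s)
      }
    }
    labels <- stats::setNames(labs, ids)
    list(records = data.frame(id = ids, desc = "", seq = seqs,
                              stringsAsFactors = FALSE),
         labels = labels, ancestors = anc)
  })
}
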