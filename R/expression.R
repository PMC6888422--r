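#' Reads per kilobase per million mapped reads
#'
#' RPKM = count / (length_bp/1000) / (mapped_total/1e6). Vectorized over
#' genes; `mapped_total` is the library-wide mapped-read total, not the sum
#' of counted genes.
#'
#' @param count Read counts (>= 0).
#' @param length_bp Gene/exon-model lengths in bp (> 0).
#' @param mapped_total Mapped reads in the library (> 0).
#' @return RPKM values.
#' @export
rpkm <- function(count, length_bp, mapped_total) {
  if (any(length_bp <= 0)) stop("gene lengths must be positive")
  if (any(mapped_total <= 0)) stop("library totals must be positive")
  count / (length_bp / 1e3) / (mapped_total / 1e6)
}

#' RPKM matrix from a count matrix
#'
#' @param counts Genes x samples matrix of read counts.
#' @param length_bp Per-gene lengths (bp), in row order.
#' @param mapped_totals Per-sample mapped-read totals, in column order.
#' @return Matrix of RPKM values with the input dimnames.
#' @export
rpkm_matrix <- function(counts, length_bp, mapped_totals) {
  stopifnot(nrow(counts) == length(length_bp),
            ncol(counts) == length(mapped_totals))
  sweep(sweep(counts, 1, length_bp / 1e3, "/"), 2, mapped_totals / 1e6, "/")
}

#' log2(x + 1) heat-map transform
#'
#' @param x Non-negative expression values (vector or matrix).
#' @return Element-wise log2(x + 1).
#' @export
heat_matrix <- function(x) {
  if (any(x < 0)) stop("expression values must be non-negative")
  log2(x + 1)
}

#' Regulation-call configuration
#'
#' @param up_threshold Fold change above which (strictly) a gene can be
#'   called up-regulated (default 1.5).
#' @param down_threshold Fold change below which (strictly) a gene can be
#'   called down-regulated (default 0.5).
#' @param alpha Significance level for the fold-change gate (default 0.05).
#' @return Object of class `regulation_config`.
#' @export
regulation_config <- function(up_threshold = 1.5, down_threshold = 0.5,
                              alpha = 0.05) {
  stopifnot(down_threshold < 1, up_threshold > 1, alpha > 0, alpha < 1)
  structure(list(up_threshold = up_threshold,
                 down_threshold = down_threshold, alpha = alpha),
            class = "regulation_config")
}

# Welch two-sample t-test p-value that tolerates zero-variance groups
.welch_p <- function(x, y) {
  if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12) {
    return(if (abs(mean(x) - mean(y)) < 1e-12) 1 else 0)
  }
  stats::t.test(x, y)$p.value
}

#' Relative expression by the 2^-ddCq method
#'
#' Per replicate, dCq = Cq(target) - mean(Cq(reference genes)); per
#' treatment timepoint, ddCq = mean(dCq at t) - mean(dCq at the
#' calibrator), and the relative expression is 2^-ddCq. The p-value is a
#' Welch two-sample t-test on the replicate dCq values (timepoint vs
#' calibrator).
#'
#' @param cq Long-format data frame with columns `gene`, `hormone`,
#'   `timepoint`, `replicate`, `cq_target`, and one or more `cq_ref*`
#'   columns (two reference genes by default).
#' @param gene Gene to analyse.
#' @param hormone Hormone condition to analyse.
#' @param calibrator Calibrator timepoint (default 0).
#' @param n_replicates Required biological replicates per condition
#'   (default 3).
#' @return Data frame with one row per non-calibrator timepoint: `gene`,
#'   `hormone`, `timepoint`, `rel_expr`, `p_value`.
#' @export
relative_expression <- function(cq, gene, hormone, calibrator = 0,
                                n_replicates = 3L) {
  ref_cols <- grep("^cq_ref", names(cq), value = TRUE)
  if (length(ref_cols) == 0) stop("no reference-gene Cq columns (cq_ref*)")
  d <- cq[cq$gene == gene & cq$hormone == hormone, , drop = FALSE]
  if (nrow(d) == 0) stop("no measurements for ", gene, " under ", hormone)
  if (any(d$cq_target <= 0 | d$cq_target >= 45))
    stop("Cq values out of range (0, 45) for ", gene)
  d$dcq <- d$cq_target - rowMeans(d[, ref_cols, drop = FALSE])
  tps <- sort(unique(d$timepoint))
  if (!calibrator %in% tps) stop("calibrator timepoint missing for ", gene)
  for (tp in tps) {
    n <- sum(d$timepoint == tp)
    if (n != n_replicates)
      stop(sprintf("%s / %s / %s h: %d replicates, expected %d",
                   gene, hormone, format(tp), n, n_replicates))
  }
  d0 <- d$dcq[d$timepoint == calibrator]
  rows <- lapply(setdiff(tps, calibrator), function(tp) {
    dt <- d$dcq[d$timepoint == tp]
    ddcq <- mean(dt) - mean(d0)
    data.frame(gene = gene, hormone = hormone, timepoint = tp,
               rel_expr = 2^(-ddcq), p_value = .welch_p(dt, d0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Call a single timepoint up / down / unchanged
#'
#' Up-regulated means relative expression strictly above the up threshold
#' with p below alpha; down-regulated means strictly below the down
#' threshold with p below alpha; anything else (including a fold change of
#' exactly 1.5) is unchanged.
#'
#' @param rel_expr Relative expression (fold).
#' @param p P-value from [relative_expression()].
#' @param cfg [regulation_config()].
#' @return `"up"`, `"down"` or `"unchanged"`.
#' @export
call_regulation <- function(rel_expr, p, cfg = regulation_config()) {
  if (rel_expr > cfg$up_threshold && p < cfg$alpha) "up"
  else if (rel_expr < cfg$down_threshold && p < cfg$alpha) "down"
  else "unchanged"
}

#' Per-gene hormone regulation calls from a Cq table
#'
#' Runs [relative_expression()] for every gene under one hormone and
#' aggregates the timepoint calls: a gene is up (down) for the hormone if
#' it is called up (down) at one or more timepoints and never the
#' opposite; genes with contradictory timepoints are unchanged.
#'
#' @param cq Long-format Cq table (see [relative_expression()]).
#' @param hormone Hormone condition.
#' @param cfg [regulation_config()].
#' @param calibrator Calibrator timepoint (default 0).
#' @return List with `per_timepoint` (data frame incl. `call`) and `calls`
#'   (data frame `gene`, `hormone`, `call`).
#' @export
call_hormone_response <- function(cq, hormone, cfg = regulation_config(),
                                  calibrator = 0) {
  genes <- sort(unique(cq$gene[cq$hormone == hormone]))
  per_tp <- do.call(rbind, lapply(genes, relative_expression, cq = cq,
                                  hormone = hormone, calibrator = calibrator))
  per_tp$call <- mapply(call_regulation, per_tp$rel_expr, per_tp$p_value,
                        MoreArgs = list(cfg = cfg))
  agg <- vapply(genes, function(g) {
    cl <- per_tp$call[per_tp$gene == g]
    if (any(cl == "up") && !any(cl == "down")) "up"
    else if (any(cl == "down") && !any(cl == "up")) "down"
    else "unchanged"
  }, character(1))
  list(per_timepoint = per_tp,
       calls = data.frame(gene = genes, hormone = hormone, call = unname(agg),
                          stringsAsFactors = FALSE))
}

#' Summary of hormone responsiveness across two treatments
#'
#' @param calls_SA,calls_MeJA Call data frames (`gene`, `call`) from
#'   [call_hormone_response()] over the same gene universe.
#' @return List with `counts` (named integer vector: `SA_up`, `SA_down`,
#'   `MeJA_up`, `MeJA_down`, `both_up`, `SA_total`, `MeJA_total`) and
#'   `genes` (the corresponding gene sets).
#' @export
responsive_summary <- function(calls_SA, calls_MeJA) {
  stopifnot(setequal(calls_SA$gene, calls_MeJA$gene))
  sets <- list(
    SA_up = calls_SA$gene[calls_SA$call == "up"],
    SA_down = calls_SA$gene[calls_SA$call == "down"],
    MeJA_up = calls_MeJA$gene[calls_MeJA$call == "up"],
    MeJA_down = calls_MeJA$gene[calls_MeJA$call == "down"])
  sets$both_up <- intersect(sets$SA_up, sets$MeJA_up)
  counts <- c(vapply(sets, length, integer(1)),
              SA_total = length(sets$SA_up) + length(sets$SA_down),
              MeJA_total = length(sets$MeJA_up) + length(sets$MeJA_down))
  list(counts = counts, genes = sets)
}
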