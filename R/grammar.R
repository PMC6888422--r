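#' WRKY domain grammar
#'
#' The grammar that defines what counts as a WRKY domain: the conserved
#' heptapeptide (WRKYGQK and its natural variants WRKYGKK / WRKYGHK, i.e.
#' W-R-K-Y-G-\[QKH\]-K) and the geometry of the downstream zinc-finger-like
#' motif C-Xa-C-Xb-H-X-Z, where `a` residues separate the two cysteines,
#' `b` residues separate the second cysteine from the histidine, and Z is
#' the fourth metal-coordinating residue two positions after the histidine
#' (H for the C-C-H-H type, C for the group III C-C-H-C type, other residues
#' for rarer variants).
#'
#' @param heptapeptides Character vector of literal 7-mer consensi.
#' @param finger_window Residues downstream of a heptapeptide (or of the
#'   previous finger) searched for the zinc-finger arrangement.
#' @param c1_c2_spacing Length-2 integer range for `a` (residues between the
#'   two cysteines).
#' @param c2_h_spacing Length-2 integer range for `b` (residues between the
#'   second cysteine and the histidine).
#' @return An object of class `wrky_grammar`.
#' @export
wrky_grammar <- function(heptapeptides = c("WRKYGQK", "WRKYGKK", "WRKYGHK"),
                         finger_window = 100L,
                         c1_c2_spacing = c(3L, 7L),
                         c2_h_spacing = c(22L, 23L)) {
  stopifnot(length(heptapeptides) >= 1, all(nchar(heptapeptides) == 7L),
            length(c1_c2_spacing) == 2, length(c2_h_spacing) == 2,
            c1_c2_spacing[1] <= c1_c2_spacing[2],
            c2_h_spacing[1] <= c2_h_spacing[2])
  if (finger_window < c2_h_spacing[2] + c1_c2_spacing[2] + 4)
    stop("finger_window too small for the requested spacing ranges")
  structure(list(heptapeptides = toupper(heptapeptides),
                 finger_window = as.integer(finger_window),
                 c1_c2_spacing = as.integer(c1_c2_spacing),
                 c2_h_spacing = as.integer(c2_h_spacing)),
            class = "wrky_grammar")
}

#' Format a zinc-finger pattern as its conventional label
#'
#' @param pattern A zinc-finger pattern (list with fields `a`, `b`,
#'   `z_residue`), as returned by [extract_zinc_finger()].
#' @return A label string such as `"C-X5-C-X23-HXH"`.
#' @export
format_zinc_label <- function(pattern) {
  stopifnot(is.list(pattern), !is.null(pattern$a))
  sprintf("C-X%d-C-X%d-HX%s", pattern$a, pattern$b, pattern$z_residue)
}

#' Normalize a zinc-finger label
#'
#' Strips the typographic irregularities seen in printed tables
#' (underscores, stray spacing, a missing dash before `X`) so that labels
#' like `"C-X_5_-C-X_23_-HXH"` or `"C-X6-CX23-HXH"` become canonical
#' `"C-X6-C-X23-HXH"`.
#'
#' @param label Label string.
#' @return Canonical label string.
#' @export
normalize_zinc_label <- function(label) {
  x <- gsub("[_ *]", "", toupper(label))
  x <- gsub("CX", "C-X", x, fixed = TRUE)
  x <- gsub("-+", "-", x)
  x
}

#' Parse a zinc-finger label into its fields
#'
#' Inverse of [format_zinc_label()] on valid labels.
#'
#' @param label Label string (normalized first).
#' @return List with `a`, `b`, `z_residue`.
#' @export
parse_zinc_label <- function(label) {
  x <- normalize_zinc_label(label)
  m <- regmatches(x, regexec("^C-X([0-9]+)-C-X([0-9]+)-HX([A-Z])$", x))[[1]]
  if (length(m) != 4)
    stop("unparseable zinc-finger label: ", label)
  list(a = as.integer(m[2]), b = as.integer(m[3]), z_residue = m[4])
}
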