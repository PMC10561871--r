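# Shared helpers: amino-acid naming, plate-well geometry, seed handling.

AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

#' HGVS-style protein substitution label
#'
#' Builds labels such as `p.Ala99Val` from a 1-based residue index and
#' single-letter reference/alternate amino acids. These labels are the
#' canonical join key across score and annotation tables.
#'
#' @param residue_index 1-based residue position (initiator Met = 1).
#' @param ref_aa,alt_aa Single-letter amino-acid codes.
#' @return Character vector of labels.
#' @examples
#' hgvs_p(99, "A", "V")
#' @export
hgvs_p <- function(residue_index, ref_aa, alt_aa) {
  stopifnot(all(ref_aa %in% names(AA3)), all(alt_aa %in% names(AA3)))
  paste0("p.", AA3[ref_aa], residue_index, AA3[alt_aa])
}

# 96-well geometry: rows A-H, columns 1-12, row-major indexing
well_label <- function(row, col) paste0(LETTERS[row], col)

well_row <- function(well) match(substr(well, 1, 1), LETTERS)

well_col <- function(well) as.integer(substring(well, 2))

is_edge_well <- function(row, col, nrow = 8, ncol = 12) {
  row == 1 | row == nrow | col == 1 | col == ncol
}

# Deterministic per-stage seed derivation, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

genetic_code <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  gc <- genetic_code()
  aa <- unname(gc[codon])
  if (any(is.na(aa))) stop("invalid codon: ", paste(codon[is.na(aa)], collapse = ", "))
  aa
}
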