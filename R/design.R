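# Library design: enumerate the SNV-accessible substitution space of a CDS
# and lay out single-codon pools on 96-well plates.

NUCS <- c("A", "C", "G", "T")

#' Validate a coding sequence
#'
#' Checks that a CDS is a multiple of three, starts with ATG, ends with a stop
#' codon, contains no internal stop and only unambiguous nucleotides.
#'
#' @param cds Character scalar nucleotide sequence (case-insensitive).
#' @return The uppercased sequence, invisibly usable; errors on violation.
#' @export
validate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1)
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  chars <- strsplit(cds, "")[[1]]
  if (!all(chars %in% NUCS)) {
    stop("CDS contains invalid nucleotides: ",
         paste(unique(chars[!chars %in% NUCS]), collapse = ","))
  }
  codons <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
  aas <- translate_codon(codons)
  if (aas[1] != "M") stop("CDS does not begin with a start codon")
  if (aas[length(aas)] != "*") stop("CDS does not end with a stop codon")
  if (any(aas[-length(aas)] == "*")) {
    stop("CDS contains an internal stop codon at position ",
         which(aas[-length(aas)] == "*")[1])
  }
  cds
}

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
}

# All unique non-synonymous, non-stop amino acids reachable from one codon by
# a single nucleotide change.
snv_alt_aas <- function(codon) {
  ref <- translate_codon(codon)
  s <- strsplit(codon, "")[[1]]
  alts <- character(0)
  for (i in 1:3) {
    for (n in setdiff(NUCS, s[i])) {
      v <- s
      v[i] <- n
      aa <- translate_codon(paste(v, collapse = ""))
      if (aa != ref && aa != "*") alts <- c(alts, aa)
    }
  }
  sort(unique(alts))
}

#' Enumerate SNV-accessible amino-acid substitutions
#'
#' For every codon of a CDS except the initiation and termination codons, all
#' nine single-nucleotide changes are translated; synonymous and stop-gain
#' changes are discarded and the unique (position, alternate amino acid) pairs
#' are returned. This reproduces the design rule of a saturation
#' single-variant library: each internal codon contributes 4-7 unique
#' substitutions under the standard genetic code.
#'
#' @param cds Coding nucleotide sequence (character scalar).
#' @param cds_id Identifier recorded on the result.
#' @param validate If `TRUE` (default) the CDS is validated strictly first.
#' @return A `substitution_set`: data frame with columns `residue_index`
#'   (1-based, Met1 = 1), `ref_aa`, `alt_aa`, `ref_codon` and `label`
#'   (HGVS-style), with attributes `cds_id`, `n_codons` (mutated codons) and
#'   `per_codon_counts`.
#' @examples
#' cds <- paste0("ATG", "GCT", "TGG", "TAA")
#' enumerate_snv_substitutions(cds)
#' @export
enumerate_snv_substitutions <- function(cds, cds_id = "cds", validate = TRUE) {
  cds <- toupper(gsub("\\s", "", cds))
  if (validate) cds <- validate_cds(cds)
  codons <- split_codons(cds)
  n <- length(codons)
  if (n < 3) stop("CDS has no internal codons")
  internal <- 2:(n - 1)
  per_codon <- lapply(internal, function(i) {
    alts <- snv_alt_aas(codons[i])
    if (length(alts) == 0) return(NULL)
    data.frame(residue_index = i,
               ref_aa = translate_codon(codons[i]),
               alt_aa = alts,
               ref_codon = codons[i],
               stringsAsFactors = FALSE)
  })
  subs <- do.call(rbind, per_codon)
  rownames(subs) <- NULL
  subs$label <- hgvs_p(subs$residue_index, subs$ref_aa, subs$alt_aa)
  counts <- table(factor(subs$residue_index, levels = internal))
  structure(subs,
            class = c("substitution_set", "data.frame"),
            cds_id = cds_id,
            n_codons = length(internal),
            per_codon_counts = stats::setNames(as.integer(counts), internal))
}

#' @export
print.substitution_set <- function(x, ...) {
  cat(sprintf("SNV-accessible substitution set '%s': %d substitutions over %d codons (%d-%d per codon)\n",
              attr(x, "cds_id"), nrow(x), attr(x, "n_codons"),
              min(attr(x, "per_codon_counts")), max(attr(x, "per_codon_counts"))))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a codon-usage table
#'
#' Expects a tab-delimited file with columns `codon`, `aa` (single letter) and
#' `fraction` (any positive relative-usage measure; only within-amino-acid
#' ranks matter). A reference table of approximate relative codon usage for
#' *S. cerevisiae* ships with the package.
#'
#' @param path File path; defaults to the packaged yeast table.
#' @return Data frame with `codon`, `aa`, `fraction`.
#' @export
read_codon_usage <- function(path = system.file("extdata", "scer_codon_usage.tsv",
                                                package = "vemap")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("codon", "aa", "fraction")
  if (!all(need %in% names(tab))) {
    stop("codon usage table must have columns: ", paste(need, collapse = ", "))
  }
  tab$codon <- toupper(tab$codon)
  tab
}

#' Assign a single variant codon per substitution
#'
#' Each amino-acid substitution is encoded by exactly one codon: the codon
#' with the highest usage fraction for the target amino acid in the supplied
#' table, with ties broken alphabetically, so output is deterministic.
#'
#' @param subs A [substitution_set][enumerate_snv_substitutions].
#' @param usage Codon-usage table as from [read_codon_usage()].
#' @return The substitution set with a `variant_codon` column filled.
#' @export
assign_variant_codons <- function(subs, usage = read_codon_usage()) {
  aas <- unique(subs$alt_aa)
  missing <- setdiff(aas, usage$aa)
  if (length(missing)) stop("usage table missing amino acids: ", paste(missing, collapse = ","))
  pick <- vapply(aas, function(a) {
    cand <- usage[usage$aa == a, , drop = FALSE]
    cand <- cand[order(-cand$fraction, cand$codon), , drop = FALSE]
    cand$codon[1]
  }, character(1))
  subs$variant_codon <- unname(pick[subs$alt_aa])
  bad <- translate_codon(subs$variant_codon) != subs$alt_aa
  if (any(bad)) stop("usage table assigns codons that do not translate to the target amino acid")
  subs
}

#' Lay out single-codon pools on 96-well plates
#'
#' One pool per mutated codon (all substitutions at that amino-acid
#' position), assigned to wells row-major (A1..A12, B1..) across as many
#' 96-well plates as needed.
#'
#' @param subs A substitution set.
#' @param plate_rows,plate_cols Plate geometry (default 8 x 12).
#' @return Data frame with one row per pool: `pool_id`, `residue_index`,
#'   `n_members`, `plate`, `well`; the member substitutions keep their pool
#'   assignment in the returned attribute `members` (the input with `pool_id`
#'   added).
#' @export
build_single_codon_pools <- function(subs, plate_rows = 8, plate_cols = 12) {
  residues <- sort(unique(subs$residue_index))
  npool <- length(residues)
  per_plate <- plate_rows * plate_cols
  idx <- seq_len(npool) - 1L
  plate <- idx %/% per_plate + 1L
  within <- idx %% per_plate
  pools <- data.frame(
    pool_id = sprintf("pool_%04d", residues),
    residue_index = residues,
    n_members = as.integer(table(factor(subs$residue_index, levels = residues))),
    plate = plate,
    well = well_label(within %/% plate_cols + 1L, within %% plate_cols + 1L),
    stringsAsFactors = FALSE
  )
  members <- as.data.frame(subs)
  members$pool_id <- pools$pool_id[match(members$residue_index, pools$residue_index)]
  attr(pools, "members") <- members
  pools
}
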