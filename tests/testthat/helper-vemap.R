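# Shared fixtures, built in code at test time.

small_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_variants = 60L, ...)
}

synthetic_cds <- function() {
  read_fasta(system.file("extdata", "synthetic_psat1_like_cds.fa",
                         package = "vemap"))[[1]]
}

# independent brute-force enumeration of SNV-accessible substitutions for one
# codon: plain nested loops over positions and bases
brute_force_alts <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  ref <- code[[codon]]
  found <- character(0)
  s <- strsplit(codon, "")[[1]]
  for (i in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == s[i]) next
      mut <- s
      mut[i] <- b
      aa <- code[[paste(mut, collapse = "")]]
      if (aa != ref && aa != "*") found <- c(found, aa)
    }
  }
  sort(unique(found))
}

# anchor annotation table whose extremes reproduce the published assay bounds
# (pathogenic up to 0.82, benign from 0.91, primate homozygotes from 0.84)
anchor_tables <- function() {
  list(scores = data.frame(
         label = c("path1", "path2", "path3", "ben1", "ben2", "prim1", "prim2"),
         score = c(0.57, 0.30, 0.82, 0.91, 0.99, 0.84, 0.95)),
       annotations = data.frame(
         label = c("path1", "path2", "path3", "ben1", "ben2", "prim1", "prim2"),
         clinvar_pathogenic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
         clinvar_benign = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
         primad_homozygote = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)))
}

# exact pairwise model with the published coefficients, recovered from
# noiseless data so predictions carry (a, b, c) = (0.05, 0.28, 0.73) exactly
published_coef_fit <- function() {
  grid <- expand.grid(score1 = c(0, 0.3, 0.6, 1), score2 = c(0, 0.5, 1))
  grid$d <- 0.05 + 0.28 * pmin(grid$score1, grid$score2) +
    0.73 * pmax(grid$score1, grid$score2)
  fit_diploid_growth(grid)
}
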