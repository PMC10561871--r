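# Relating per-residue functional scores to structural annotations and
# evolutionary conservation: medians, site-set permutation test, rank
# correlation, enrichment, external-predictor comparison.

#' Median growth per residue
#'
#' Median of all tested substitutions at each residue (mean-of-middle-two
#' convention for even counts). Residues with no tested variant are absent
#' from the result, not zero.
#'
#' @param scores Data frame with `residue_index` and `score`.
#' @return Data frame `residue_index`, `median_growth`, `n_variants`.
#' @export
median_growth_per_residue <- function(scores) {
  stopifnot(all(c("residue_index", "score") %in% names(scores)))
  sp <- split(scores$score, scores$residue_index)
  data.frame(residue_index = as.integer(names(sp)),
             median_growth = vapply(sp, stats::median, numeric(1)),
             n_variants = vapply(sp, length, integer(1)),
             row.names = NULL)
}

#' One-sided permutation test for a site set's median growth
#'
#' Observed statistic: the median growth over all variants at the residues
#' of the site set (e.g. the cofactor-binding residues). Null distribution:
#' the same statistic for random residue sets of equal size drawn without
#' replacement from all tested residues, preserving the per-residue variant
#' structure. The one-sided p-value for a *low* observed median is
#' `(1 + #[null <= observed]) / (1 + n_perm)`, which is never below
#' `1/(n_perm + 1)`.
#'
#' @param site_residues Integer residue indices of the site set.
#' @param scores Data frame with `residue_index` and `score`.
#' @param n_perm Number of permutations (>= 1000 for reported p-values;
#'   smaller values allowed for exhaustive cross-checks).
#' @param seed Seed for the permutation draws.
#' @param exhaustive Enumerate all residue subsets instead of sampling
#'   (feasible only for small residue universes).
#' @return List `observed`, `global_median`, `p.value`, `n_perm`, `n_sites`.
#' @export
site_set_median_test <- function(site_residues, scores, n_perm = 1e4, seed = 1,
                                 exhaustive = FALSE) {
  stopifnot(length(site_residues) > 0)
  residues <- unique(scores$residue_index)
  site_residues <- unique(site_residues)
  if (!all(site_residues %in% residues)) {
    stop("site set contains residues with no tested variant")
  }
  sp <- split(scores$score, scores$residue_index)
  stat <- function(res_set) stats::median(unlist(sp[as.character(res_set)], use.names = FALSE))
  obs <- stat(site_residues)
  k <- length(site_residues)
  if (setequal(site_residues, residues)) {
    warning("site set covers all tested residues; degenerate test")
    return(list(observed = obs, global_median = stats::median(scores$score),
                p.value = 1, n_perm = 0L, n_sites = k))
  }
  if (exhaustive) {
    sets <- utils::combn(residues, k, simplify = FALSE)
    null <- vapply(sets, stat, numeric(1))
    p <- mean(null <= obs)  # exact enumeration: no pseudo-count needed
    n_used <- length(sets)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i) stat(sample(residues, k)), numeric(1))
    p <- (1 + sum(null <= obs)) / (1 + n_perm)
    n_used <- as.integer(n_perm)
  }
  list(observed = obs, global_median = stats::median(scores$score),
       p.value = p, n_perm = n_used, n_sites = k)
}

#' Spearman correlation between conservation and per-residue median growth
#'
#' Rank correlation (average ranks for ties) between the per-residue
#' conservation score (more negative = more conserved) and the per-residue
#' median growth; a positive correlation means conserved residues grow less
#' when substituted.
#'
#' @param profiles Data frame with `consurf_score` and `median_growth`.
#' @return List `rho`, `p.value`, `n`.
#' @export
spearman_conservation_correlation <- function(profiles) {
  d <- profiles[is.finite(profiles$consurf_score) & is.finite(profiles$median_growth), ]
  if (nrow(d) < 3) stop("need >= 3 residues with both scores")
  if (stats::sd(d$consurf_score) == 0 || stats::sd(d$median_growth) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- suppressWarnings(stats::cor.test(d$consurf_score, d$median_growth,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = nrow(d))
}

#' Enrichment of amorphic variants at conserved residues
#'
#' One-sided Fisher's exact test on the 2x2 table of (amorphic vs
#' non-amorphic) x (conserved: ConSurf < 0 vs not), testing enrichment of
#' amorphs at conserved residues.
#'
#' @param classified Data frame with `residue_index` and `functional_class`
#'   (as from [classify_functional()]).
#' @param profiles Data frame with `residue_index` and `consurf_score`.
#' @return List `table` (2x2), `p.value`, `amorphic_conserved_fraction`,
#'   `overall_conserved_fraction`.
#' @export
amorphic_conservation_enrichment <- function(classified, profiles) {
  d <- merge(classified, profiles[c("residue_index", "consurf_score")],
             by = "residue_index")
  d <- d[is.finite(d$consurf_score), ]
  amorph <- d$functional_class == "amorph"
  conserved <- d$consurf_score < 0
  tab <- table(factor(amorph, c(TRUE, FALSE), c("amorph", "other")),
               factor(conserved, c(TRUE, FALSE), c("conserved", "not_conserved")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("empty table margin")
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab, p.value = ft$p.value,
       amorphic_conserved_fraction = tab["amorph", "conserved"] / sum(tab["amorph", ]),
       overall_conserved_fraction = sum(tab[, "conserved"]) / sum(tab))
}

#' Correlation of growth scores with external variant-effect predictors
#'
#' Per-predictor Spearman correlation over variants shared with the score
#' table, and the mean absolute correlation (predictors are reported on
#' heterogeneous scales and orientations, so only |rho| is summarized).
#' Predictors with fewer than `min_n` joined variants are skipped with a
#' warning.
#'
#' @param scores Data frame with `label` and `score`.
#' @param predictors Data frame with `label` plus one numeric column per
#'   predictor.
#' @param min_n Minimum joined variants per predictor (default 10).
#' @return List `per_predictor` (data frame `predictor`, `rho`, `n`),
#'   `mean_abs_rho`.
#' @export
compare_external_predictors <- function(scores, predictors, min_n = 10L) {
  d <- merge(scores[c("label", "score")], predictors, by = "label")
  cols <- setdiff(names(predictors), "label")
  rows <- lapply(cols, function(cl) {
    ok <- is.finite(d$score) & is.finite(d[[cl]])
    if (sum(ok) < min_n) {
      warning("predictor ", cl, " skipped: only ", sum(ok), " joined variants")
      return(NULL)
    }
    rho <- suppressWarnings(stats::cor(d$score[ok], d[[cl]][ok], method = "spearman"))
    data.frame(predictor = cl, rho = rho, n = sum(ok), stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) == 0) stop("no predictor with enough joined variants")
  list(per_predictor = per, mean_abs_rho = mean(abs(per$rho)))
}
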