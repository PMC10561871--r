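# Pooled variant calling: identify which variant each pooled transformant
# carries from position-resolved codon counts, using a per-variant empirical
# sequencing-error model and four rejection filters.

#' Calling configuration
#'
#' Thresholds of the candidate-variant quality filters. Rejection uses strict
#' inequalities exactly as stated for the assay: a candidate is rejected when
#' its observed frequency is *less than* `min_enrichment` times its error
#' frequency, when the second most frequent variant is enriched at least
#' `second_enrichment`-fold over its error frequency *and* observed above
#' `second_relative_freq` of the candidate frequency, or when it is supported
#' by *fewer than* `min_reads` reads.
#'
#' @param min_enrichment Candidate enrichment floor over its error frequency
#'   (default 3.3).
#' @param second_enrichment Enrichment defining a suspicious second variant
#'   (default 10).
#' @param second_relative_freq Relative frequency (of the candidate) above
#'   which an enriched second variant is disqualifying (default 0.30).
#' @param min_reads Minimum supporting reads (default 15).
#' @param pseudocount Pseudocount of the error-model estimator (default 1).
#' @return List of class `calling_config`.
#' @export
calling_config <- function(min_enrichment = 3.3, second_enrichment = 10,
                           second_relative_freq = 0.30, min_reads = 15L,
                           pseudocount = 1) {
  vals <- c(min_enrichment, second_enrichment, second_relative_freq, min_reads)
  if (any(vals <= 0)) stop("all calling thresholds must be > 0")
  structure(list(min_enrichment = min_enrichment,
                 second_enrichment = second_enrichment,
                 second_relative_freq = second_relative_freq,
                 min_reads = as.integer(min_reads),
                 pseudocount = pseudocount),
            class = "calling_config")
}

#' Estimate the per-variant sequencing-error model
#'
#' From control sequencing of reference-only material, the frequency with
#' which each variant codon is generated by sequencing error at each position
#' is estimated with a pseudocount over the 64-codon alphabet:
#' `e_v = (count_v + pseudocount) / (total + pseudocount * 64)`. Codons never
#' observed in the controls receive the pseudocount floor, so every error
#' frequency is strictly positive.
#'
#' @param control_counts Data frame `position`, `codon`, `count` from
#'   wild-type-only sequencing (a `pool_id` column is ignored).
#' @param pseudocount Pseudocount (default 1).
#' @return Object of class `error_model`; query with [error_freq()].
#' @export
estimate_error_model <- function(control_counts, pseudocount = 1) {
  stopifnot(all(c("position", "codon", "count") %in% names(control_counts)))
  totals <- tapply(control_counts$count, control_counts$position, sum)
  if (any(totals == 0)) {
    stop("zero total reads at position(s): ",
         paste(names(totals)[totals == 0], collapse = ","))
  }
  counts <- control_counts[c("position", "codon", "count")]
  counts <- stats::aggregate(count ~ position + codon, counts, sum)
  structure(list(totals = totals, counts = counts,
                 pseudocount = pseudocount, alphabet = 64L),
            class = "error_model")
}

#' Error frequency of a codon at a position
#'
#' @param model An [estimate_error_model()] result.
#' @param position Integer position (codon index).
#' @param codon Codon (character).
#' @return Estimated error frequency in (0, 1).
#' @export
error_freq <- function(model, position, codon) {
  stopifnot(inherits(model, "error_model"))
  total <- model$totals[as.character(position)]
  if (is.na(total)) stop("position ", position, " absent from error model")
  hit <- model$counts$count[model$counts$position == position &
                            model$counts$codon == codon]
  cnt <- if (length(hit)) sum(hit) else 0
  unname((cnt + model$pseudocount) / (total + model$pseudocount * model$alphabet))
}

# counts at one position of one pool, as named vector
position_counts <- function(counts, pool, pos) {
  sub <- counts[counts$pool_id == pool & counts$position == pos, , drop = FALSE]
  stats::setNames(sub$count, sub$codon)
}

#' Call pooled variants with four-filter quality control
#'
#' For each transformant in the pool design, the counts at its target codon
#' are examined: the most frequent non-reference codon is the candidate
#' variant, and the second most frequent is screened as a potential
#' contaminant. A candidate becomes a high-confidence call only if it passes
#' all filters (see [calling_config()]); otherwise the transformant receives
#' a no-call with machine-readable rejection reasons. Pools in which a
#' nonsynonymous or nonsense secondary mutation is detected at a non-target
#' codon ([detect_secondary_mutations()]) have all their transformants
#' rejected, since pooled reads cannot attribute the secondary mutation to a
#' single transformant.
#'
#' @param counts Pool count table (`pool_id`, `position`, `codon`, `count`).
#' @param model Error model from [estimate_error_model()].
#' @param design Pool membership: `pool_id`, `transformant_id`, `position`.
#' @param reference Reference codons indexed by position.
#' @param config A [calling_config()].
#' @param screen_secondary Screen non-target positions present in `counts`
#'   for secondary mutations (default `TRUE`).
#' @return Data frame of calls: `transformant_id`, `pool_id`, `position`,
#'   `status` (`called`/`no_call`), `codon`, `substitution` (HGVS-style, NA
#'   for synonymous candidates), `supporting_reads`, `frequency`, `reasons`
#'   (comma-joined). Attribute `filter_tally` summarizes rejection reasons.
#' @export
call_pool_variants <- function(counts, model, design, reference,
                               config = calling_config(), screen_secondary = TRUE) {
  stopifnot(inherits(model, "error_model"), inherits(config, "calling_config"))
  if (nrow(design) == 0) stop("empty pool design")
  for (p in unique(design$pool_id)) {
    sub <- design[design$pool_id == p, ]
    if (nrow(sub) > 12) stop("pool ", p, " has more than 12 members")
    if (anyDuplicated(sub$position)) stop("pool ", p, " repeats a target codon")
  }
  sec_by_pool <- list()
  if (screen_secondary) {
    for (p in unique(design$pool_id)) {
      targets <- design$position[design$pool_id == p]
      sec_by_pool[[p]] <- detect_secondary_mutations(
        counts[counts$pool_id == p, , drop = FALSE], model, reference,
        target_positions = targets, config = config)
    }
  }
  out <- lapply(seq_len(nrow(design)), function(i) {
    pool <- design$pool_id[i]
    pos <- design$position[i]
    cnt <- position_counts(counts, pool, pos)
    if (length(cnt) == 0) stop("target codon ", pos, " absent from counts for pool ", pool)
    total <- sum(cnt)
    ref <- reference[pos]
    var_cnt <- sort(cnt[names(cnt) != ref & cnt > 0], decreasing = TRUE)
    reasons <- character(0)
    cand <- NA_character_; reads <- 0L; f1 <- NA_real_
    if (length(var_cnt) == 0) {
      reasons <- "no_variant_reads"
    } else {
      cand <- names(var_cnt)[1]
      reads <- as.integer(var_cnt[1])
      f1 <- var_cnt[1] / total
      e1 <- error_freq(model, pos, cand)
      if (f1 < config$min_enrichment * e1) reasons <- c(reasons, "low_enrichment")
      if (length(var_cnt) >= 2) {
        sec <- names(var_cnt)[2]
        f2 <- var_cnt[2] / total
        e2 <- error_freq(model, pos, sec)
        if (f2 >= config$second_enrichment * e2 &&
            f2 > config$second_relative_freq * f1) {
          reasons <- c(reasons, "ambiguous_second")
        }
      }
      if (reads < config$min_reads) reasons <- c(reasons, "min_reads")
    }
    if (length(sec_by_pool[[pool]] %||% integer(0)) > 0) {
      reasons <- c(reasons, "secondary_mutation")
    }
    subst <- NA_character_
    if (!is.na(cand)) {
      ref_aa <- translate_codon(ref)
      alt_aa <- translate_codon(cand)
      if (alt_aa != ref_aa && alt_aa != "*") subst <- hgvs_p(pos, ref_aa, alt_aa)
    }
    data.frame(transformant_id = design$transformant_id[i], pool_id = pool,
               position = pos,
               status = if (length(reasons)) "no_call" else "called",
               codon = cand, substitution = subst,
               supporting_reads = reads, frequency = unname(f1),
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  tally <- table(unlist(strsplit(calls$reasons[calls$reasons != ""], ",")))
  attr(calls, "filter_tally") <- tally
  calls
}

#' Detect secondary mutations at non-target codons
#'
#' A non-target position is flagged when its most frequent non-reference
#' codon is nonsynonymous or nonsense and passes both the error-model
#' enrichment filter (frequency at least `min_enrichment` times its error
#' frequency) and the minimum-read filter. Synonymous changes are exempt.
#'
#' @param counts Count table restricted to one pool.
#' @param model Error model.
#' @param reference Reference codons indexed by position.
#' @param target_positions Positions that are designed targets (excluded).
#' @param config A [calling_config()].
#' @return Integer vector of flagged positions (empty when clean).
#' @export
detect_secondary_mutations <- function(counts, model, reference,
                                       target_positions = integer(0),
                                       config = calling_config()) {
  pos_all <- setdiff(unique(counts$position), target_positions)
  flagged <- integer(0)
  for (pos in pos_all) {
    sub <- counts[counts$position == pos, , drop = FALSE]
    cnt <- stats::setNames(sub$count, sub$codon)
    total <- sum(cnt)
    if (total == 0) next
    ref <- reference[pos]
    var_cnt <- sort(cnt[names(cnt) != ref & cnt > 0], decreasing = TRUE)
    if (length(var_cnt) == 0) next
    cand <- names(var_cnt)[1]
    aa_ref <- translate_codon(ref)
    aa_alt <- translate_codon(cand)
    if (aa_alt == aa_ref) next  # synonymous exemption
    f <- var_cnt[1] / total
    e <- error_freq(model, pos, cand)
    if (f >= config$min_enrichment * e && var_cnt[1] >= config$min_reads) {
      flagged <- c(flagged, pos)
    }
  }
  sort(flagged)
}
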