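# Readers and writers for the formats the pipeline touches, plus the
# end-to-end orchestrator. TSV is the canonical tabular format (CSV accepted
# on read by sniffing); internal scores are always fractions, with percent
# columns auto-detected by header suffix.

#' Read sequence records from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ","))
  stats::setNames(toupper(as.character(seqs)), ids)
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a delimited table with schema validation
#'
#' Reads TSV (or CSV, sniffed from the header line), checks required
#' columns, coerces declared numeric columns (errors name the offending row
#' and column), preserves unknown columns, and converts `*_pct` columns to
#' fractions.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @param numeric_cols Columns that must parse as numeric.
#' @return Data frame.
#' @export
read_table <- function(path, required = character(0), numeric_cols = character(0)) {
  tab <- utils::read.delim(path, sep = sniff_sep(path), stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (cl in intersect(numeric_cols, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[cl]]))
    bad <- which(is.na(v) & !is.na(tab[[cl]]) & tab[[cl]] != "")
    if (length(bad)) stop("unparseable numeric value in column '", cl, "', row ", bad[1])
    tab[[cl]] <- v
  }
  for (cl in grep("_pct$", names(tab), value = TRUE)) {
    if (is.numeric(tab[[cl]])) {
      newname <- sub("_pct$", "", cl)
      tab[[newname]] <- tab[[cl]] / 100
      tab[[cl]] <- NULL
    }
  }
  tab
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic-data pipeline end to end
#'
#' Executes the stages in dependency order on seeded synthetic inputs:
#' variant-library design on a CDS, pooled-sequencing simulation and variant
#' calling, plate-growth simulation and normalization with isolate QC,
#' variant-score aggregation, clinically anchored classification, the
#' pairwise-additive diploid fit with leave-one-out validation and logistic
#' boundary, the all-pairs genotype scan, and conservation statistics.
#' When `out_dir` is given, stage outputs are written as TSV/JSON together
#' with a manifest recording the seed and configuration.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param cds Coding sequence for the design stage (defaults to the packaged
#'   synthetic CDS).
#' @param anchors Named list with numeric `pathogenic`, `benign` and
#'   `primad` anchor growth scores used to derive the clinical thresholds.
#'   Defaults to the published PSAT1 anchor extremes (pathogenic up to 0.82,
#'   benign from 0.91, primate homozygotes from 0.84).
#' @param n_perm Permutations for the site-set test.
#' @param out_dir Optional output directory.
#' @return List with elements `design`, `calls`, `scores`, `thresholds`,
#'   `classification`, `diploid`, `conservation`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(),
                         cds = NULL,
                         anchors = list(pathogenic = c(0.57, 0.72, 0.82),
                                        benign = c(0.91, 0.97),
                                        primad = c(0.84, 0.93, 1.01)),
                         n_perm = 2000L, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cds <- cds %||% read_fasta(system.file("extdata", "synthetic_psat1_like_cds.fa",
                                         package = "vemap"))[[1]]
  # 1. library design
  subs <- enumerate_snv_substitutions(cds, cds_id = "pipeline_cds")
  subs <- assign_variant_codons(subs)
  pools <- build_single_codon_pools(subs)

  # 2. true allele effects (restricted to the designed substitution space)
  eff <- simulate_allele_effects(config)
  n_use <- min(nrow(eff), nrow(subs))
  eff <- eff[seq_len(n_use), ]
  eff$label <- subs$label[seq_len(n_use)]
  eff$residue_index <- subs$residue_index[seq_len(n_use)]
  eff$ref_aa <- subs$ref_aa[seq_len(n_use)]
  eff$alt_aa <- subs$alt_aa[seq_len(n_use)]

  # 3. pooled sequencing + calling for a subset of transformants
  reference <- stats::setNames(split_codons(cds), seq_along(split_codons(cds)))
  members <- attr(pools, "members")[seq_len(n_use), ]
  # greedy pooling: groups of <=12 transformants, no target codon repeated
  pool_of <- integer(n_use)
  pool_sizes <- integer(0)
  pool_res <- list()
  for (i in seq_len(n_use)) {
    placed <- FALSE
    for (p in seq_along(pool_sizes)) {
      if (pool_sizes[p] < 12L && !(members$residue_index[i] %in% pool_res[[p]])) {
        pool_of[i] <- p; pool_sizes[p] <- pool_sizes[p] + 1L
        pool_res[[p]] <- c(pool_res[[p]], members$residue_index[i])
        placed <- TRUE; break
      }
    }
    if (!placed) {
      pool_sizes <- c(pool_sizes, 1L)
      pool_res[[length(pool_sizes)]] <- members$residue_index[i]
      pool_of[i] <- length(pool_sizes)
    }
  }
  design <- data.frame(pool_id = sprintf("seqpool_%03d", pool_of),
                       transformant_id = paste0("tf_", seq_len(n_use)),
                       position = members$residue_index)
  true_codons <- stats::setNames(members$variant_codon, design$transformant_id)
  pool_counts <- simulate_read_pools(design, true_codons, reference, config)
  ctrl_counts <- simulate_control_counts(unique(design$position), reference, config)
  emodel <- estimate_error_model(ctrl_counts, pseudocount = calling_config()$pseudocount)
  calls <- call_pool_variants(pool_counts, emodel, design, reference)

  # 4. plate growth + normalization + QC + aggregation
  obs <- simulate_plate_set(eff, config)
  norm <- normalize_growth(obs, ploidy = "haploid")
  qc <- qc_filter_isolates(norm)
  scores <- aggregate_variant_scores(qc$scores)
  scores <- merge(scores, eff[c("label", "residue_index")], by = "label")

  # 5. classification under both anchor schemes
  np <- length(anchors$pathogenic); nb <- length(anchors$benign); nh <- length(anchors$primad)
  anno <- data.frame(
    label = c(paste0("anchor_path_", seq_len(np)), paste0("anchor_ben_", seq_len(nb)),
              paste0("anchor_primad_", seq_len(nh))),
    clinvar_pathogenic = rep(c(TRUE, FALSE, FALSE), c(np, nb, nh)),
    clinvar_benign = rep(c(FALSE, TRUE, FALSE), c(np, nb, nh)),
    primad_homozygote = rep(c(FALSE, FALSE, TRUE), c(np, nb, nh)))
  anchor_scores <- data.frame(label = anno$label,
                              score = c(anchors$pathogenic, anchors$benign, anchors$primad))
  scheme1 <- derive_clinical_thresholds(anchor_scores, anno, include_primad = FALSE)
  scheme2 <- derive_clinical_thresholds(anchor_scores, anno, include_primad = TRUE)
  classification <- summarize_classification(scores, scheme1, scheme2 = scheme2)

  # 6. diploid model
  pairs <- simulate_diploid_pairs(eff, config)
  dfit <- fit_diploid_growth(pairs)
  cv <- loocv_diploid(pairs)
  lab_pred <- predict(dfit, pairs)
  lb <- fit_logistic_boundary(lab_pred, pairs$label)
  allele_scores <- c(scores$score, 1, 0)  # variants + WT + null
  scan <- predict_all_pairs(allele_scores, dfit, boundary = lb$boundary)

  # 7. conservation statistics
  profiles <- simulate_residue_profiles(eff, config)
  med <- median_growth_per_residue(scores)
  profiles <- merge(profiles[c("residue_index", "consurf_score", "consurf_grade")],
                    med, by = "residue_index")
  sens <- profiles$residue_index[order(profiles$median_growth)][
    seq_len(min(12L, nrow(profiles)))]
  site_test <- site_set_median_test(sens, scores, n_perm = n_perm,
                                    seed = derive_seed(config$seed, 707L))
  rho <- spearman_conservation_correlation(profiles)
  classified <- data.frame(residue_index = scores$residue_index,
                           functional_class = classify_functional(scores$score))
  enr <- amorphic_conservation_enrichment(classified, profiles)

  manifest <- list(seed = config$seed, n_variants = n_use,
                   config = unclass(config), timestamp = as.character(Sys.time()))
  out <- list(design = list(substitutions = subs, pools = pools),
              calls = calls, scores = scores,
              thresholds = list(clinvar_only = scheme1, clinvar_plus_primad = scheme2),
              classification = classification,
              diploid = list(pairs = pairs, fit = dfit, loocv = cv,
                             boundary = lb, scan = scan),
              conservation = list(profiles = profiles, site_test = site_test,
                                  spearman = rho, enrichment = enr),
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(as.data.frame(subs), file.path(out_dir, "design.tsv"))
    write_tsv(calls, file.path(out_dir, "calls.tsv"))
    write_tsv(scores, file.path(out_dir, "scores.tsv"))
    write_tsv(pairs, file.path(out_dir, "diploid_pairs.tsv"))
    write_tsv(scan$histogram, file.path(out_dir, "allpairs_histogram.tsv"))
    classification_json <- classification
    if (!is.null(classification_json$reclassified)) {
      classification_json$reclassified <-
        as.data.frame(classification_json$reclassified)
    }
    jsonlite::write_json(list(
      thresholds = lapply(out$thresholds, unclass),
      classification = classification_json,
      diploid = list(coefficients = as.list(coef(dfit)), r_squared = dfit$r.squared,
                     loocv = cv[c("rmse", "mae")], boundary = lb$boundary,
                     below_boundary = scan$below_boundary, n_pairs = scan$n_pairs),
      conservation = list(site_test = site_test, spearman = rho,
                          enrichment = enr[c("p.value", "amorphic_conserved_fraction",
                                             "overall_conserved_fraction")]),
      manifest = manifest),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
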