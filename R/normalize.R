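# Growth normalization: convert raw pixelsums into genotype growth scores on
# the null = 0 / wild-type = 1 scale via a joint linear model with plate,
# edge and neighbor effects; isolate-level QC; per-variant aggregation.

#' Normalize growth observations to the null = 0 / wild type = 1 scale
#'
#' Fits a single linear model to all observations: a fixed effect per
#' genotype (each variant isolate its own level; the wild-type and null
#' controls each one shared level), a fixed effect per plate-replicate, a
#' perimeter-well (edge) indicator and, for haploid plates, the
#' neighbor-competition covariate of [neighbor_covariate()]. Genotype effects
#' are then rescaled affinely so the fitted null control is exactly 0 and the
#' fitted wild-type control exactly 1. Diploid plates use the same model
#' without the neighbor term (checkerboard pinning makes neighbor effects
#' negligible) and anchor on the homozygous controls.
#'
#' @param obs Growth observations (`plate_id`, `replicate`, `row`, `col`,
#'   `is_edge`, `isolate_id`, `genotype`, `pixelsum`).
#' @param ploidy `"haploid"` (neighbor term on) or `"diploid"` (off).
#' @param wt_label,null_label Genotype labels of the anchoring controls
#'   (defaults `"WT"`/`"null"`; use `"WT/WT"`/`"null/null"` for diploids).
#' @param unit `"isolate"` to estimate one effect per variant isolate
#'   (default, required for isolate-level QC) or `"genotype"` for one effect
#'   per genotype label.
#' @param neighbor Override the ploidy-based default for the neighbor term.
#' @param pin_effect Reserved switch for pin-position normalization; omitted
#'   by default because it does not reduce noise in this assay design.
#' @return Object of class `growth_norm` with elements `scores` (data frame
#'   `unit`, `genotype`, `score`), `well_values` (per-observation normalized
#'   values for control-variability estimation), `anchors`, `aliased`,
#'   `sigma`, and the call. `coef()` returns the named score vector.
#' @export
normalize_growth <- function(obs, ploidy = c("haploid", "diploid"),
                             wt_label = NULL, null_label = NULL,
                             unit = c("isolate", "genotype"),
                             neighbor = NULL, pin_effect = FALSE) {
  ploidy <- match.arg(ploidy)
  unit <- match.arg(unit)
  wt_label <- wt_label %||% if (ploidy == "haploid") "WT" else "WT/WT"
  null_label <- null_label %||% if (ploidy == "haploid") "null" else "null/null"
  neighbor <- neighbor %||% (ploidy == "haploid")
  stopifnot(all(c("plate_id", "replicate", "row", "col", "is_edge",
                  "isolate_id", "genotype", "pixelsum") %in% names(obs)))
  if (!any(obs$genotype == wt_label) || !any(obs$genotype == null_label)) {
    stop("anchoring controls '", wt_label, "' and '", null_label,
         "' must both be present")
  }
  is_ctrl <- obs$genotype %in% c(wt_label, null_label)
  term <- if (unit == "isolate") ifelse(is_ctrl, obs$genotype, obs$isolate_id)
          else obs$genotype
  df <- data.frame(y = obs$pixelsum,
                   g = factor(term),
                   plate_f = factor(paste(obs$plate_id, obs$replicate)),
                   edge = as.numeric(obs$is_edge))
  form <- y ~ g + edge
  if (nlevels(df$plate_f) > 1) form <- stats::update(form, . ~ . + plate_f)
  if (neighbor) {
    df$nbz <- neighbor_covariate(obs)
    if (stats::sd(df$nbz) > 0) form <- stats::update(form, . ~ . + nbz)
  }
  fit <- stats::lm(form, data = df)
  cf <- stats::coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    warning("rank-deficient normalization model; aliased terms: ",
            paste(aliased, collapse = ", "))
    cf[is.na(cf)] <- 0
  }
  lv <- levels(df$g)
  b <- stats::setNames(numeric(length(lv)), lv)
  has <- paste0("g", lv) %in% names(cf)
  b[lv[has]] <- cf[paste0("g", lv[has])]  # reference level stays 0
  b_null <- b[null_label]
  b_wt <- b[wt_label]
  denom <- b_wt - b_null
  if (abs(denom) < .Machine$double.eps * 1e3) stop("wild-type and null anchors coincide")
  scores <- (b - b_null) / denom
  genotype_of <- if (unit == "isolate") {
    m <- obs$genotype[match(lv, ifelse(is_ctrl, obs$genotype, obs$isolate_id))]
    stats::setNames(m, lv)
  } else stats::setNames(lv, lv)
  # per-observation normalized value: unit score plus residual on score scale
  wv <- scores[as.character(df$g)] + stats::residuals(fit) / denom
  structure(list(
    scores = data.frame(unit = lv, genotype = unname(genotype_of[lv]),
                        score = unname(scores[lv]), stringsAsFactors = FALSE),
    well_values = data.frame(obs[c("plate_id", "replicate", "well", "isolate_id",
                                   "genotype")], value = unname(wv)),
    anchors = c(null = unname(b_null), WT = unname(b_wt)),
    aliased = aliased,
    sigma = stats::sigma(fit) / abs(denom),
    ploidy = ploidy, unit = unit,
    wt_label = wt_label, null_label = null_label,
    call = match.call()), class = "growth_norm")
}

#' @export
print.growth_norm <- function(x, ...) {
  cat(sprintf("Growth normalization (%s, per-%s): %d units on %d plate-replicates\n",
              x$ploidy, x$unit, nrow(x$scores),
              length(unique(paste(x$well_values$plate_id, x$well_values$replicate)))))
  cat(sprintf("  residual SD on growth scale: %.4f\n", x$sigma))
  ctrl <- x$scores$score[match(c(x$null_label, x$wt_label), x$scores$unit)]
  cat(sprintf("  anchors after rescaling: null = %g, WT = %g\n", ctrl[1], ctrl[2]))
  if (length(x$aliased)) cat("  aliased terms:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.growth_norm <- function(object, ...) {
  stats::setNames(object$scores$score, object$scores$unit)
}

#' Control-derived threshold for isolate-to-isolate variability
#'
#' The 95th percentile of the per-plate-replicate standard deviation of the
#' normalized wild-type control wells: how variable technical replicates of a
#' single genotype are in this dataset.
#'
#' @param norm A [normalize_growth()] fit.
#' @param probs Quantile (default 0.95).
#' @return Numeric threshold on the normalized growth scale.
#' @export
control_sd_threshold <- function(norm, probs = 0.95) {
  wv <- norm$well_values
  wt <- wv[wv$genotype == norm$wt_label, , drop = FALSE]
  grp <- paste(wt$plate_id, wt$replicate)
  sds <- tapply(wt$value, grp, stats::sd)
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0) stop("cannot derive control SD: need >=2 WT wells per plate")
  as.numeric(stats::quantile(sds, probs))
}

#' Isolate-level quality filtering
#'
#' Removes (i) isolates flagged for secondary mutations (or any supplied
#' exclusion list, e.g. no-calls from pooled sequencing), then (ii) *all*
#' isolates of variants whose isolate-to-isolate standard deviation exceeds
#' the threshold (by default the control-derived 95th percentile of
#' [control_sd_threshold()]). The secondary-mutation rule takes precedence:
#' a flagged isolate is removed regardless of variance.
#'
#' @param norm A per-isolate [normalize_growth()] fit.
#' @param exclude_isolates Character isolate ids to drop (flagged isolates).
#' @param sd_threshold Numeric threshold; derived from controls when `NULL`.
#' @return List with `scores` (retained isolate-level scores), `removed`
#'   (data frame `unit`, `genotype`, `reason`), and `sd_threshold`.
#' @export
qc_filter_isolates <- function(norm, exclude_isolates = character(0),
                               sd_threshold = NULL) {
  stopifnot(inherits(norm, "growth_norm"), norm$unit == "isolate")
  sc <- norm$scores
  ctrl <- sc$genotype %in% c(norm$wt_label, norm$null_label)
  removed <- data.frame(unit = character(0), genotype = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  flag <- !ctrl & sc$unit %in% exclude_isolates
  if (any(flag)) {
    removed <- rbind(removed, data.frame(unit = sc$unit[flag],
                                         genotype = sc$genotype[flag],
                                         reason = "secondary_mutation"))
  }
  keep <- sc[!flag & !ctrl, , drop = FALSE]
  sd_threshold <- sd_threshold %||% control_sd_threshold(norm)
  vsd <- tapply(keep$score, keep$genotype, stats::sd)
  high <- names(vsd)[!is.na(vsd) & vsd > sd_threshold]
  if (length(high)) {
    hv <- keep$genotype %in% high
    removed <- rbind(removed, data.frame(unit = keep$unit[hv],
                                         genotype = keep$genotype[hv],
                                         reason = "high_variance"))
    keep <- keep[!hv, , drop = FALSE]
  }
  list(scores = keep, removed = removed, sd_threshold = sd_threshold)
}

#' Aggregate isolate scores into per-variant scores
#'
#' Per-variant mean and standard error (SD/sqrt(n)); single-isolate variants
#' receive SE = 0 and a low-replication flag. Annotation columns (keyed by
#' the HGVS-style `label`) are joined when supplied; duplicate annotation
#' rows with conflicting values raise an error.
#'
#' @param isolate_scores Data frame `unit`, `genotype`, `score` (the `scores`
#'   element of [qc_filter_isolates()]).
#' @param annotations Optional data frame with a `label` column.
#' @return Data frame `label`, `score`, `se`, `n_isolates`,
#'   `low_replication`, plus any annotation columns.
#' @export
aggregate_variant_scores <- function(isolate_scores, annotations = NULL) {
  sp <- split(isolate_scores$score, isolate_scores$genotype)
  out <- data.frame(
    label = names(sp),
    score = vapply(sp, mean, numeric(1)),
    se = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
                numeric(1)),
    n_isolates = vapply(sp, length, integer(1)),
    stringsAsFactors = FALSE)
  out$low_replication <- out$n_isolates == 1L
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    stopifnot("label" %in% names(annotations))
    if (anyDuplicated(annotations$label)) {
      dup <- annotations$label[duplicated(annotations$label)]
      conf <- !all(vapply(dup, function(l) {
        nrow(unique(annotations[annotations$label == l, , drop = FALSE])) == 1
      }, logical(1)))
      if (conf) stop("conflicting duplicate annotations")
      annotations <- annotations[!duplicated(annotations$label), , drop = FALSE]
    }
    out <- merge(out, annotations, by = "label", all.x = TRUE, sort = FALSE)
  }
  out[order(out$label), , drop = FALSE]
}
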