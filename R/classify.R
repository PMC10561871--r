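# Functional and clinically anchored classification of variant scores.

#' Functional classification of a normalized growth score
#'
#' Bands scores by comparability to the null and wild-type controls:
#' scores at or below 0.05 are amorphs (comparable to the null control),
#' scores in (0.05, 0.95] are hypomorphs, and scores above 0.95 (including
#' above-wild-type values) are unimpaired.
#'
#' @param score Numeric vector of normalized growth scores (finite).
#' @param amorph_max,unimpaired_min_exclusive Band boundaries (defaults 0.05
#'   and 0.95, both inclusive on the impaired side).
#' @return Factor with levels `amorph`, `hypomorph`, `unimpaired`.
#' @export
classify_functional <- function(score, amorph_max = 0.05,
                                unimpaired_min_exclusive = 0.95) {
  if (any(!is.finite(score))) stop("non-finite growth score")
  out <- ifelse(score <= amorph_max, "amorph",
                ifelse(score <= unimpaired_min_exclusive, "hypomorph", "unimpaired"))
  factor(out, levels = c("amorph", "hypomorph", "unimpaired"))
}

#' Derive clinically anchored thresholds from annotated variants
#'
#' The deleterious (supporting pathogenicity) bound is the maximum score
#' among pathogenic-annotated anchor variants; the non-deleterious
#' (supporting benignity) bound is the minimum score among the benign anchor
#' set — benign/likely-benign variants, extended by primate-homozygote
#' (primAD) variants when `include_primad = TRUE`. Scores between the bounds
#' are of uncertain clinical significance. With the published PSAT1 anchors
#' these bounds are 0.82/0.91 (ClinVar only) and 0.82/0.84 (ClinVar plus
#' primAD).
#'
#' @param scores Data frame with `label` and `score`.
#' @param annotations Data frame with `label` and logical columns
#'   `clinvar_pathogenic`, `clinvar_benign`, and optionally
#'   `primad_homozygote`.
#' @param include_primad Extend the benign anchor set with primAD
#'   homozygotes.
#' @param margin Optional margin subtracted/added to the bounds (default 0:
#'   bounds are the exact anchor extremes).
#' @return List of class `threshold_scheme`: `deleterious_max`,
#'   `non_deleterious_min`, `scheme_id`, `anchors`.
#' @export
derive_clinical_thresholds <- function(scores, annotations, include_primad = FALSE,
                                       margin = 0) {
  d <- merge(scores[c("label", "score")], annotations, by = "label")
  path <- d$score[isTRUE_col(d$clinvar_pathogenic)]
  ben <- d$score[isTRUE_col(d$clinvar_benign)]
  if (include_primad && "primad_homozygote" %in% names(d)) {
    ben <- c(ben, d$score[isTRUE_col(d$primad_homozygote)])
  }
  if (length(path) == 0) stop("no pathogenic-annotated anchor variants")
  if (length(ben) == 0) stop("no benign-annotated anchor variants")
  lo <- max(path) + margin
  hi <- min(ben) - margin
  if (lo >= hi) {
    stop(sprintf("inconsistent anchors: pathogenic max (%.3f) >= benign min (%.3f)",
                 max(path), min(ben)))
  }
  structure(list(deleterious_max = lo, non_deleterious_min = hi,
                 scheme_id = if (include_primad) "clinvar_plus_primad" else "clinvar_only",
                 anchors = list(pathogenic = path, benign = ben)),
            class = "threshold_scheme")
}

isTRUE_col <- function(x) !is.na(x) & as.logical(x)

#' Manually specified threshold scheme
#'
#' @param deleterious_max,non_deleterious_min Bounds (deleterious_max must be
#'   below non_deleterious_min).
#' @param scheme_id Identifier.
#' @return A `threshold_scheme`.
#' @export
threshold_scheme <- function(deleterious_max, non_deleterious_min,
                             scheme_id = "manual") {
  if (!(deleterious_max < non_deleterious_min)) {
    stop("deleterious_max must be < non_deleterious_min")
  }
  structure(list(deleterious_max = deleterious_max,
                 non_deleterious_min = non_deleterious_min,
                 scheme_id = scheme_id, anchors = NULL),
            class = "threshold_scheme")
}

#' @export
print.threshold_scheme <- function(x, ...) {
  cat(sprintf("Threshold scheme '%s': deleterious <= %.3f < uncertain < %.3f <= non-deleterious\n",
              x$scheme_id, x$deleterious_max, x$non_deleterious_min))
  invisible(x)
}

#' Clinically anchored classification
#'
#' Scores at or below the deleterious bound are deleterious; scores at or
#' above the non-deleterious bound — including values above wild type, since
#' increased activity is not associated with serine-deficiency disease — are
#' non-deleterious; the open band between is uncertain.
#'
#' @param score Numeric scores.
#' @param scheme A [threshold_scheme()] or [derive_clinical_thresholds()]
#'   result.
#' @return Factor with levels `deleterious`, `uncertain`, `non_deleterious`.
#' @export
classify_clinical <- function(score, scheme) {
  stopifnot(inherits(scheme, "threshold_scheme"))
  out <- ifelse(score <= scheme$deleterious_max, "deleterious",
                ifelse(score >= scheme$non_deleterious_min, "non_deleterious",
                       "uncertain"))
  factor(out, levels = c("deleterious", "uncertain", "non_deleterious"))
}

#' Summarize a classification run
#'
#' Per-class counts and percentages under one scheme, optional subgroup
#' cross-tabulations by annotation flags (empty subgroups give zero rows,
#' not absent rows), and — when a second scheme is supplied — the
#' reclassification table between the two schemes.
#'
#' @param scores Data frame with `label` and `score`.
#' @param scheme A `threshold_scheme`.
#' @param annotations Optional annotation data frame (`label` + logical flag
#'   columns); each flag column yields a subgroup tabulation.
#' @param scheme2 Optional second scheme for the reclassification delta.
#' @return List with `counts` (named integer), `percent`, `n`, `subgroups`
#'   (list of per-flag class counts), and optionally `reclassified` (table
#'   of scheme1 class x scheme2 class).
#' @export
summarize_classification <- function(scores, scheme, annotations = NULL,
                                     scheme2 = NULL) {
  stopifnot(nrow(scores) > 0)
  cls <- classify_clinical(scores$score, scheme)
  counts <- table(cls)
  out <- list(n = nrow(scores),
              counts = stats::setNames(as.integer(counts), names(counts)),
              percent = stats::setNames(round(100 * as.integer(counts) / nrow(scores), 1),
                                        names(counts)),
              scheme_id = scheme$scheme_id)
  if (!is.null(annotations)) {
    d <- merge(scores[c("label", "score")], annotations, by = "label", all.x = TRUE)
    flags <- setdiff(names(annotations), "label")
    out$subgroups <- lapply(stats::setNames(flags, flags), function(fl) {
      sel <- isTRUE_col(d[[fl]])
      tab <- table(classify_clinical(d$score[sel], scheme))
      stats::setNames(as.integer(tab), names(tab))
    })
  }
  if (!is.null(scheme2)) {
    cls2 <- classify_clinical(scores$score, scheme2)
    out$reclassified <- table(from = cls, to = cls2)
  }
  out
}
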