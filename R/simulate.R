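# Seeded generators producing every input the pipeline consumes: allele
# effects with the bimodal structure of a saturation complementation screen,
# plate-structured growth observations, pooled codon-count tables with
# reproducible per-variant error frequencies, diploid allele pairs generated
# by the pairwise-additive model, and renderable plate images.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generators in one validated
#' list. The defaults describe the study conditions the pipeline is designed
#' for: a trimodal allele-effect mixture whose class proportions echo the
#' published PSAT1 map (57% non-deleterious, 28% deleterious, 15% uncertain),
#' 96-well plates carrying 2 null and 4 wild-type control patches, three
#' replicate pinnings, three independent isolates per variant, and a diploid
#' pairwise-additive model with coefficients a = 0.05, b = 0.28, c = 0.73.
#'
#' @param seed Integer seed; fully determines every draw.
#' @param n_variants Number of amino-acid substitutions to simulate.
#' @param effect_mixture List with `weights` (named, summing to 1) and
#'   per-component `c(mean, sd)` parameters for the `unimpaired`, `low` and
#'   `intermediate` components. Draws are clamped to `[0, 1.15]`.
#' @param plate_sd Dispersion of additive plate offsets, on the normalized
#'   growth scale (multiplied internally by `base_signal`).
#' @param edge_factor Multiplicative growth factor for perimeter wells
#'   (modelled as the additive offset `(edge_factor - 1) * base_signal`).
#' @param neighbor_coef Strength of neighbor competition: coefficient (on the
#'   normalized scale) of the plate-standardized mean pixelsum of orthogonally
#'   adjacent wells, applied with a negative sign.
#' @param noise_sd Replicate noise, multiplicative lognormal on pixelsum.
#' @param n_replicates Replicate pinnings per plate.
#' @param n_isolates Independent isolates per variant.
#' @param base_signal,base_background Pixelsum of a wild-type patch above
#'   background, and the background pixelsum of an empty/null patch.
#' @param read_depth Reads per pool position in pooled sequencing.
#' @param error_rate_range Range of uniform per-variant sequencing-error
#'   frequencies.
#' @param n_error_codons Number of error-prone non-reference codons per
#'   position.
#' @param diploid_coeffs Named vector `c(a, b, c)` of the pairwise-additive
#'   diploid model `d = a + b*x_j + c*x_k`.
#' @param diploid_noise_sd Gaussian noise on simulated diploid growth; the
#'   default 0.07 matches the residual scale reported for the experimental
#'   diploid assay (cross-validated RMSE near 0.07).
#' @param conservation_coupling Correlation strength in `[0, 1]` between
#'   per-residue substitution sensitivity and the synthetic conservation
#'   score.
#' @param tile_px,patch_radius Plate-image rendering geometry in pixels.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_variants = 500L,
                       effect_mixture = list(
                         weights = c(unimpaired = 0.57, low = 0.28, intermediate = 0.15),
                         unimpaired = c(mean = 1.00, sd = 0.035),
                         low = c(mean = 0.02, sd = 0.03),
                         intermediate = c(mean = 0.86, sd = 0.03)),
                       plate_sd = 0.1,
                       edge_factor = 0.9,
                       neighbor_coef = 0.2,
                       noise_sd = 0.05,
                       n_replicates = 3L,
                       n_isolates = 3L,
                       base_signal = 5e4,
                       base_background = 2e3,
                       read_depth = 2000L,
                       error_rate_range = c(1e-4, 5e-3),
                       n_error_codons = 3L,
                       diploid_coeffs = c(a = 0.05, b = 0.28, c = 0.73),
                       diploid_noise_sd = 0.07,
                       conservation_coupling = 0.5,
                       tile_px = 24L,
                       patch_radius = 8L) {
  w <- effect_mixture$weights
  if (is.null(names(w)) || !setequal(names(w), c("unimpaired", "low", "intermediate"))) {
    stop("effect_mixture$weights must be named unimpaired/low/intermediate")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) stop("mixture weights must be >= 0 and sum to 1")
  disp <- c(plate_sd = plate_sd, noise_sd = noise_sd,
            diploid_noise_sd = diploid_noise_sd,
            sapply(effect_mixture[c("unimpaired", "low", "intermediate")], `[[`, "sd"))
  if (any(disp < 0)) stop("all dispersions must be >= 0")
  if (length(error_rate_range) != 2 || any(error_rate_range < 0) || diff(error_rate_range) < 0) {
    stop("error_rate_range must be an increasing non-negative pair")
  }
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 effect_mixture = effect_mixture, plate_sd = plate_sd,
                 edge_factor = edge_factor, neighbor_coef = neighbor_coef,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 n_isolates = as.integer(n_isolates), base_signal = base_signal,
                 base_background = base_background, read_depth = as.integer(read_depth),
                 error_rate_range = error_rate_range,
                 n_error_codons = as.integer(n_error_codons),
                 diploid_coeffs = diploid_coeffs, diploid_noise_sd = diploid_noise_sd,
                 conservation_coupling = conservation_coupling,
                 tile_px = as.integer(tile_px), patch_radius = as.integer(patch_radius)),
            class = "sim_config")
}

#' Simulate true allele effects from the trimodal mixture
#'
#' Draws one true effect per variant from a three-component mixture: a large
#' component near wild type (1), a component at the null level (0), and a
#' mildly hypomorphic component. Variants are laid out over residues with up
#' to six substitutions per residue and given HGVS-style synthetic labels.
#'
#' @param config A [sim_config()].
#' @return Data frame with `label`, `residue_index`, `ref_aa`, `alt_aa`,
#'   `effect`; attribute `component` records the generating component.
#' @export
simulate_allele_effects <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 101L))
  n <- config$n_variants
  mix <- config$effect_mixture
  comp <- sample(names(mix$weights), n, replace = TRUE, prob = mix$weights)
  draw <- function(par, k) stats::rnorm(k, par[["mean"]], par[["sd"]])
  eff <- numeric(n)
  for (cm in unique(comp)) {
    idx <- comp == cm
    eff[idx] <- draw(mix[[cm]], sum(idx))
  }
  eff <- pmin(pmax(eff, 0), 1.15)
  per_res <- 6L
  n_res <- ceiling(n / per_res)
  residue <- rep(seq_len(n_res) + 1L, each = per_res)[seq_len(n)]
  ref_aa <- sample(AA1, n_res, replace = TRUE)[residue - 1L]
  alt_aa <- character(n)
  for (r in unique(residue)) {
    idx <- which(residue == r)
    alt_aa[idx] <- sample(setdiff(AA1, ref_aa[idx[1]]), length(idx))
  }
  out <- data.frame(label = hgvs_p(residue, ref_aa, alt_aa),
                    residue_index = residue, ref_aa = ref_aa, alt_aa = alt_aa,
                    effect = eff, stringsAsFactors = FALSE)
  attr(out, "component") <- comp
  out
}

# ---- plate growth observations -------------------------------------------

CONTROL_WELLS <- list(null = c("A1", "H12"), WT = c("A12", "H1", "D6", "E7"))

#' Mean pixelsum of orthogonally adjacent wells, standardized per plate
#'
#' The neighbor-competition covariate used by both the generator and the
#' normalizer: for each occupied well, the mean `value` of its occupied
#' orthogonal neighbors (fewer at plate borders and in checkerboard layouts),
#' centered and scaled within each plate-replicate; zero when a plate has no
#' variation or a well has no occupied neighbor.
#'
#' @param obs Data frame with `plate_id`, `replicate`, `row`, `col` columns.
#' @param value Numeric vector aligned with `obs` (defaults to
#'   `obs$pixelsum`).
#' @return Numeric covariate vector aligned with `obs`.
#' @export
neighbor_covariate <- function(obs, value = obs$pixelsum) {
  out <- neighbor_mean(obs, value)
  grp <- paste(obs$plate_id, obs$replicate, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    s <- stats::sd(out[idx])
    out[idx] <- if (is.na(s) || s < 1e-12) 0 else (out[idx] - mean(out[idx])) / s
  }
  out
}

# Raw mean of orthogonal neighbors' values per well (missing neighbors at
# borders/checkerboard gaps excluded; isolated wells get the plate mean).
neighbor_mean <- function(obs, value = obs$pixelsum) {
  stopifnot(length(value) == nrow(obs))
  out <- numeric(nrow(obs))
  grp <- paste(obs$plate_id, obs$replicate, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    key <- matrix(NA_integer_, nrow = max(obs$row[idx]) + 1L, ncol = max(obs$col[idx]) + 1L)
    key[cbind(obs$row[idx], obs$col[idx])] <- idx
    nb <- vapply(idx, function(i) {
      r <- obs$row[i]; cl <- obs$col[i]
      cand <- rbind(c(r - 1L, cl), c(r + 1L, cl), c(r, cl - 1L), c(r, cl + 1L))
      cand <- cand[cand[, 1] >= 1 & cand[, 2] >= 1 &
                   cand[, 1] <= nrow(key) & cand[, 2] <= ncol(key), , drop = FALSE]
      js <- key[cand]
      js <- js[!is.na(js)]
      if (length(js) == 0) NA_real_ else mean(value[js])
    }, numeric(1))
    nb[is.na(nb)] <- mean(nb, na.rm = TRUE)
    out[idx] <- nb
  }
  out
}

# Lay out isolates and controls on as many 96-well plates as needed.
# Control wells are fixed: null at A1/H12, wild type at A12/H1/D6/E7.
plate_layout <- function(isolate_ids, genotypes) {
  stopifnot(length(isolate_ids) == length(genotypes), !anyDuplicated(isolate_ids))
  ctrl <- unlist(CONTROL_WELLS, use.names = FALSE)
  free <- setdiff(well_label(rep(1:8, each = 12), rep(1:12, times = 8)), ctrl)
  per_plate <- length(free)
  n_plates <- ceiling(length(isolate_ids) / per_plate)
  rows <- list()
  k <- 0L
  for (p in seq_len(n_plates)) {
    take <- isolate_ids[(k + 1):min(k + per_plate, length(isolate_ids))]
    gt <- genotypes[(k + 1):min(k + per_plate, length(genotypes))]
    k <- k + length(take)
    wells <- c(free[seq_along(take)],
               CONTROL_WELLS$null, CONTROL_WELLS$WT)
    ids <- c(take, paste0("null_ctrl_", seq_along(CONTROL_WELLS$null), "_P", p),
             paste0("WT_ctrl_", seq_along(CONTROL_WELLS$WT), "_P", p))
    gts <- c(gt, rep("null", 2), rep("WT", 4))
    rows[[p]] <- data.frame(plate_id = sprintf("P%02d", p), well = wells,
                            isolate_id = ids, genotype = gts,
                            stringsAsFactors = FALSE)
  }
  lay <- do.call(rbind, rows)
  if (anyDuplicated(lay[c("plate_id", "well")])) stop("duplicate well assignment in layout")
  lay$row <- well_row(lay$well)
  lay$col <- well_col(lay$well)
  lay$is_edge <- is_edge_well(lay$row, lay$col)
  lay
}

#' Simulate plate-structured growth observations
#'
#' Generates raw pixelsum observations for a haploid complementation screen:
#' each variant contributes `n_isolates` independently arrayed isolates, every
#' plate carries 2 null and 4 wild-type control patches at fixed wells, and
#' each plate is pinned in `n_replicates` replicates. The observation model is
#' the one the normalizer fits: an additive genotype signal
#' (`background + effect * base_signal`), a per-plate-replicate offset, a
#' perimeter-well offset, and a neighbor-competition term proportional to the
#' plate-standardized mean pixelsum of orthogonally adjacent wells (resolved
#' by fixed-point iteration so the generated data satisfy the model exactly at
#' zero noise), followed by multiplicative lognormal replicate noise.
#'
#' @param true_effects Named numeric vector of true allele effects (names are
#'   variant labels), or a data frame as from [simulate_allele_effects()].
#' @param config A [sim_config()].
#' @param layout Optional pre-built layout (as from the internal layout
#'   builder) to reuse; duplicate well assignments raise an error.
#' @return Data frame of growth observations (`plate_id`, `replicate`, `well`,
#'   `row`, `col`, `is_edge`, `isolate_id`, `genotype`, `pixelsum`) with a
#'   `truth` attribute carrying the generating effects and config.
#' @export
simulate_plate_set <- function(true_effects, config = sim_config(), layout = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.data.frame(true_effects)) {
    true_effects <- stats::setNames(true_effects$effect, true_effects$label)
  }
  set.seed(derive_seed(config$seed, 202L))
  iso <- data.frame(
    isolate_id = paste0(rep(names(true_effects), each = config$n_isolates), "_iso",
                        rep(seq_len(config$n_isolates), times = length(true_effects))),
    genotype = rep(names(true_effects), each = config$n_isolates),
    stringsAsFactors = FALSE)
  # isolates are arrayed in random well order, as independently picked
  # transformants would be; co-locating a variant's isolates would let them
  # share local plate environment and correlate their errors
  iso <- iso[sample.int(nrow(iso)), , drop = FALSE]
  lay <- layout %||% plate_layout(iso$isolate_id, iso$genotype)
  if (anyDuplicated(lay[c("plate_id", "well")])) stop("duplicate well assignment in layout")
  eff_all <- c(true_effects, WT = 1, null = 0)
  sig <- config$base_signal
  obs <- do.call(rbind, lapply(seq_len(config$n_replicates), function(rep_i) {
    d <- lay
    d$replicate <- rep_i
    d
  }))
  rownames(obs) <- NULL
  grp <- paste(obs$plate_id, obs$replicate)
  plate_off <- stats::rnorm(length(unique(grp)), 0, config$plate_sd * sig)
  names(plate_off) <- unique(grp)
  base <- config$base_background + eff_all[obs$genotype] * sig +
    plate_off[grp] + (config$edge_factor - 1) * sig * obs$is_edge
  y <- as.numeric(base)
  if (config$neighbor_coef != 0) {
    # the intended competition penalty is proportional to the mean growth
    # effect of the orthogonal neighbors (0-1 scale); the normalizer's
    # covariate is standardized to unit sd, so the generating coefficient is
    # rescaled by the sd of the plate-centered mean-neighbor effect, and the
    # term is resolved self-consistently (neighbors respond to realized
    # pixelsums) by fixed-point iteration
    nb_eff <- neighbor_mean(obs, eff_all[obs$genotype])
    grp_sd <- stats::sd(nb_eff - stats::ave(nb_eff, grp))
    gamma <- -config$neighbor_coef * sig * grp_sd
    for (it in 1:200) {
      y_new <- as.numeric(base) + gamma * neighbor_covariate(obs, y)
      if (max(abs(y_new - y)) < 1e-9) { y <- y_new; break }
      y <- y_new
    }
  }
  if (config$noise_sd > 0) y <- y * exp(stats::rnorm(length(y), 0, config$noise_sd))
  # no clamping: strong nuisance settings may push a null well slightly
  # negative, and clamping would break the linear structure being modelled
  obs$pixelsum <- y
  obs <- obs[c("plate_id", "replicate", "well", "row", "col", "is_edge",
               "isolate_id", "genotype", "pixelsum")]
  attr(obs, "truth") <- list(effects = eff_all, config = config)
  obs
}

#' Simulate diploid growth observations on checkerboard plates
#'
#' Diploid genotypes (allele pairs) are arrayed on alternating wells so no two
#' occupied wells are orthogonal neighbors, which is why the diploid
#' normalization model omits the neighbor term. Homozygous wild-type and null
#' controls occupy their fixed control wells. The observation model matches
#' [simulate_plate_set()] minus the neighbor term.
#'
#' @param diploid_growth Named numeric vector: true diploid growth per
#'   genotype id (on the homozygous null = 0 / homozygous WT = 1 scale).
#' @param config A [sim_config()].
#' @return Growth observation data frame as in [simulate_plate_set()].
#' @export
simulate_diploid_plate_set <- function(diploid_growth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 203L))
  all_wells <- expand.grid(row = 1:8, col = 1:12)
  checker <- all_wells[(all_wells$row + all_wells$col) %% 2 == 0, ]
  wells <- well_label(checker$row, checker$col)
  ctrl <- unlist(CONTROL_WELLS, use.names = FALSE)
  free <- setdiff(wells, ctrl)
  ids <- rep(names(diploid_growth), each = config$n_isolates)
  iso <- paste0(ids, "_iso", rep(seq_len(config$n_isolates), times = length(diploid_growth)))
  per_plate <- length(free)
  n_plates <- ceiling(length(iso) / per_plate)
  rows <- list()
  k <- 0L
  for (p in seq_len(n_plates)) {
    take <- seq(k + 1, min(k + per_plate, length(iso)))
    k <- max(take)
    ctrl_use <- intersect(ctrl, wells)  # control wells on the checkerboard
    rows[[p]] <- data.frame(
      plate_id = sprintf("DP%02d", p),
      well = c(free[seq_along(take)], CONTROL_WELLS$null[1], CONTROL_WELLS$WT[c(2, 3)]),
      isolate_id = c(iso[take], paste0("nullnull_P", p),
                     paste0("WTWT_", 1:2, "_P", p)),
      genotype = c(ids[take], "null/null", rep("WT/WT", 2)),
      stringsAsFactors = FALSE)
  }
  lay <- do.call(rbind, rows)
  lay$row <- well_row(lay$well)
  lay$col <- well_col(lay$well)
  lay$is_edge <- is_edge_well(lay$row, lay$col)
  eff_all <- c(diploid_growth, `WT/WT` = 1, `null/null` = 0)
  sig <- config$base_signal
  obs <- do.call(rbind, lapply(seq_len(config$n_replicates), function(rep_i) {
    d <- lay; d$replicate <- rep_i; d
  }))
  rownames(obs) <- NULL
  grp <- paste(obs$plate_id, obs$replicate)
  plate_off <- stats::rnorm(length(unique(grp)), 0, config$plate_sd * sig)
  names(plate_off) <- unique(grp)
  y <- config$base_background + eff_all[obs$genotype] * sig +
    plate_off[grp] + (config$edge_factor - 1) * sig * obs$is_edge
  if (config$noise_sd > 0) y <- y * exp(stats::rnorm(length(y), 0, config$noise_sd))
  obs$pixelsum <- as.numeric(y)
  obs <- obs[c("plate_id", "replicate", "well", "row", "col", "is_edge",
               "isolate_id", "genotype", "pixelsum")]
  attr(obs, "truth") <- list(effects = eff_all, config = config)
  obs
}

# ---- pooled sequencing ----------------------------------------------------

# Deterministic per-position error-prone codons and rates, shared by pool and
# control simulation so an error model estimated from controls matches the
# rates that generated the pools.
position_error_rates <- function(seed, position, ref_codon, range, n_codons) {
  set.seed(derive_seed(seed, 1000L + position))
  all_codons <- names(genetic_code())
  cods <- sample(setdiff(all_codons, ref_codon), n_codons)
  rate <- stats::runif(n_codons, range[1], range[2])
  stats::setNames(rate, cods)
}

#' Simulate pooled-sequencing codon counts
#'
#' Each pool of up to 12 transformants is sequenced to `read_depth` reads per
#' position. At a transformant's target codon its variant codon appears at
#' frequency `1/n_members`, sequencing errors generate each error-prone codon
#' at its per-position error frequency, and the reference codon takes the
#' remaining mass; counts are multinomial draws. The per-position error
#' frequencies are a deterministic function of the seed, so control
#' sequencing simulated with the same config shares them.
#'
#' @param pool_design Data frame with `pool_id`, `transformant_id`,
#'   `position`; target positions must be unique within each pool.
#' @param true_codons Named character vector mapping `transformant_id` to the
#'   variant codon truly present.
#' @param reference Character vector of reference codons indexed by position.
#' @param config A [sim_config()].
#' @return Data frame `pool_id`, `position`, `codon`, `count` with a `truth`
#'   attribute (true codon per transformant and the error-rate map).
#' @export
simulate_read_pools <- function(pool_design, true_codons, reference,
                                config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  for (p in unique(pool_design$pool_id)) {
    pos <- pool_design$position[pool_design$pool_id == p]
    if (anyDuplicated(pos)) stop("repeated target codon in pool ", p)
  }
  set.seed(derive_seed(config$seed, 303L))
  rows <- list()
  rate_map <- list()
  for (p in unique(pool_design$pool_id)) {
    sub <- pool_design[pool_design$pool_id == p, , drop = FALSE]
    n_members <- nrow(sub)
    for (i in seq_len(n_members)) {
      pos <- sub$position[i]
      ref <- reference[pos]
      vcod <- true_codons[[sub$transformant_id[i]]]
      rates <- position_error_rates(config$seed, pos, ref,
                                    config$error_rate_range, config$n_error_codons)
      rate_map[[as.character(pos)]] <- rates
      p_var <- stats::setNames(1 / n_members, vcod)
      # sequencing errors can also hit the true variant codon
      for (cd in names(rates)) {
        if (cd %in% names(p_var)) p_var[cd] <- p_var[cd] + rates[cd]
        else p_var[cd] <- rates[cd]
      }
      p_all <- c(p_var, stats::setNames(max(0, 1 - sum(p_var)), ref))
      cnt <- stats::rmultinom(1, config$read_depth, p_all)[, 1]
      rows[[length(rows) + 1L]] <- data.frame(
        pool_id = p, position = pos, codon = names(p_all), count = as.integer(cnt),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$count > 0 | out$codon == reference[out$position], ]
  rownames(out) <- NULL
  attr(out, "truth") <- list(true_codons = true_codons, error_rates = rate_map,
                             design = pool_design)
  out
}

#' Simulate wild-type-only control sequencing
#'
#' Control counts over the given positions from reference material only:
#' error-prone codons appear at their per-position error frequencies and the
#' reference codon takes the rest. Shares the error-rate map with
#' [simulate_read_pools()] under the same config.
#'
#' @param positions Integer positions to cover.
#' @param reference Reference codons indexed by position.
#' @param config A [sim_config()].
#' @param depth Reads per position (defaults to 10x the pool depth).
#' @return Data frame `pool_id` ("WT_control"), `position`, `codon`, `count`.
#' @export
simulate_control_counts <- function(positions, reference, config = sim_config(),
                                    depth = 10L * config$read_depth) {
  set.seed(derive_seed(config$seed, 404L))
  rows <- lapply(positions, function(pos) {
    ref <- reference[pos]
    rates <- position_error_rates(config$seed, pos, ref,
                                  config$error_rate_range, config$n_error_codons)
    p_all <- c(rates, stats::setNames(max(0, 1 - sum(rates)), ref))
    cnt <- stats::rmultinom(1, depth, p_all)[, 1]
    data.frame(pool_id = "WT_control", position = pos, codon = names(p_all),
               count = as.integer(cnt), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- diploid allele pairs -------------------------------------------------

#' Simulate diploid allele pairs under the pairwise-additive model
#'
#' Generates observed diploid growth `d = a + b*x_j + c*x_k + noise`, where
#' `x_j <= x_k` are the ordered haploid scores of the two alleles. When
#' `pairs` is not supplied, a patient/carrier trio design is built that
#' emulates the clinical genotype spectrum of PSAT1 serine-biosynthesis
#' deficiency: `n_patients` biallelic patient genotypes drawn from impaired
#' alleles (including one mild homozygote), one carrier genotype
#' (allele x wild type) per patient allele up to `n_carriers`, plus
#' homozygous wild-type and null controls and two additional constructed
#' genotypes (23 pairs in all under the defaults).
#'
#' @param haploid_effects Optional data frame from
#'   [simulate_allele_effects()] used as the allele pool; severe patient
#'   alleles are drawn uniformly when it lacks impaired alleles.
#' @param config A [sim_config()]; `diploid_coeffs` and `diploid_noise_sd`
#'   control generation.
#' @param pairs Optional data frame with `score1`, `score2` (and optionally
#'   `genotype_id`, `label`) for which to generate `d` directly.
#' @param n_patients,n_carriers Trio-design sizes.
#' @return Data frame with `genotype_id`, `allele1`, `allele2`, `score1`,
#'   `score2`, `x_j`, `x_k`, `d`, `label`; `truth` attribute records the
#'   generating coefficients.
#' @export
simulate_diploid_pairs <- function(haploid_effects = NULL, config = sim_config(),
                                   pairs = NULL, n_patients = 9L, n_carriers = 10L) {
  stopifnot(inherits(config, "sim_config"))
  co <- config$diploid_coeffs
  set.seed(derive_seed(config$seed, 505L))
  if (is.null(pairs)) {
    sev_pool <- NULL
    if (!is.null(haploid_effects)) {
      sev_pool <- haploid_effects[haploid_effects$effect < 0.6, , drop = FALSE]
    }
    draw_allele <- function(k, lo, hi) {
      if (!is.null(sev_pool) && nrow(sev_pool) >= k && hi <= 0.6) {
        i <- sample(nrow(sev_pool), k)
        list(label = sev_pool$label[i], score = sev_pool$effect[i])
      } else {
        list(label = sprintf("allele_%02d", sample.int(1e4, k)),
             score = stats::runif(k, lo, hi))
      }
    }
    sev <- draw_allele(2L * (n_patients - 1L), 0, 0.6)
    mild <- draw_allele(1L, 0.75, 0.85)
    # patients: n_patients - 1 severe genotypes (mix of hom/het) + 1 mild homozygote
    pat <- list()
    for (i in seq_len(n_patients - 1L)) {
      a1 <- 2L * i - 1L
      a2 <- if (i %% 3 == 0) a1 else 2L * i  # every third patient homozygous
      pat[[i]] <- data.frame(allele1 = sev$label[a1], allele2 = sev$label[a2],
                             score1 = sev$score[a1], score2 = sev$score[a2],
                             label = "patient", stringsAsFactors = FALSE)
    }
    pat[[n_patients]] <- data.frame(allele1 = mild$label, allele2 = mild$label,
                                    score1 = mild$score, score2 = mild$score,
                                    label = "patient", stringsAsFactors = FALSE)
    pat <- do.call(rbind, pat)
    carrier_alleles <- unique(data.frame(label = c(pat$allele1, pat$allele2),
                                         score = c(pat$score1, pat$score2)))
    carrier_alleles <- carrier_alleles[seq_len(min(n_carriers, nrow(carrier_alleles))), ]
    car <- data.frame(allele1 = carrier_alleles$label, allele2 = "WT",
                      score1 = carrier_alleles$score, score2 = 1,
                      label = "carrier", stringsAsFactors = FALSE)
    extra <- data.frame(
      allele1 = c("WT", "null", sev$label[1], sev$label[2]),
      allele2 = c("WT", "null", sev$label[1], "WT"),
      score1 = c(1, 0, sev$score[1], sev$score[2]),
      score2 = c(1, 0, sev$score[1], 1),
      label = "control", stringsAsFactors = FALSE)
    pairs <- rbind(pat, car, extra)
    pairs$genotype_id <- sprintf("G%02d", seq_len(nrow(pairs)))
  } else {
    pairs <- as.data.frame(pairs)
    if (is.null(pairs$genotype_id)) pairs$genotype_id <- sprintf("G%02d", seq_len(nrow(pairs)))
    if (is.null(pairs$label)) pairs$label <- "unknown"
    if (is.null(pairs$allele1)) pairs$allele1 <- sprintf("a%02d", seq_len(nrow(pairs)))
    if (is.null(pairs$allele2)) pairs$allele2 <- sprintf("b%02d", seq_len(nrow(pairs)))
  }
  xs <- order_alleles(pairs$score1, pairs$score2)
  pairs$x_j <- xs$x_j
  pairs$x_k <- xs$x_k
  pairs$d <- co[["a"]] + co[["b"]] * pairs$x_j + co[["c"]] * pairs$x_k +
    stats::rnorm(nrow(pairs), 0, config$diploid_noise_sd)
  pairs <- pairs[c("genotype_id", "allele1", "allele2", "score1", "score2",
                   "x_j", "x_k", "d", "label")]
  attr(pairs, "truth") <- list(coeffs = co, noise_sd = config$diploid_noise_sd)
  pairs
}

# ---- conservation profiles ------------------------------------------------

#' Simulate per-residue conservation profiles coupled to sensitivity
#'
#' Builds a synthetic stand-in for a per-residue structure/conservation
#' annotation table: a conservation score whose rank is coupled (with
#' strength `conservation_coupling`) to the realized per-residue median
#' effect, so that more substitution-sensitive residues tend to receive more
#' negative (more conserved) scores, plus a 1-9 conservation grade.
#'
#' @param effects Data frame from [simulate_allele_effects()] (or any table
#'   with `residue_index` and `effect`).
#' @param config A [sim_config()].
#' @return Data frame `residue_index`, `median_growth`, `consurf_score`,
#'   `consurf_grade`.
#' @export
simulate_residue_profiles <- function(effects, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 606L))
  med <- tapply(effects$effect, effects$residue_index, stats::median)
  r <- length(med)
  z <- stats::qnorm((rank(med, ties.method = "average") - 0.5) / r)
  a <- config$conservation_coupling
  score <- a * z + sqrt(1 - a^2) * stats::rnorm(r)
  grade <- cut(score, breaks = stats::quantile(score, probs = seq(0, 1, length.out = 10)),
               labels = FALSE, include.lowest = TRUE)
  data.frame(residue_index = as.integer(names(med)),
             median_growth = as.numeric(med),
             consurf_score = round(score, 3),
             consurf_grade = 10L - as.integer(grade),  # 9 = most conserved
             row.names = NULL)
}

# ---- plate images ---------------------------------------------------------

#' Render a plate image from growth observations
#'
#' Draws one grayscale image of a 96-patch plate: disk-shaped patches on a
#' zero background, one per observation, each disk carrying a total intensity
#' equal to the observation's pixelsum (spread uniformly over the disk).
#' Intensities are in the raw pixelsum units; see [write_plate_png()] for
#' quantized file output.
#'
#' @param observations Growth observations for a single plate-replicate (at
#'   most one observation per well).
#' @param config A [sim_config()]; `tile_px` and `patch_radius` set geometry.
#' @return Numeric matrix of size `(8*tile_px) x (12*tile_px)` with attribute
#'   `wells` (the rendered well labels).
#' @export
render_plate_image <- function(observations, config = sim_config()) {
  if (anyDuplicated(observations[c("row", "col")])) {
    stop("multiple observations for the same well")
  }
  tp <- config$tile_px
  rad <- config$patch_radius
  img <- matrix(0, nrow = 8 * tp, ncol = 12 * tp)
  cx <- (tp + 1) / 2
  off <- expand.grid(dr = seq_len(tp), dc = seq_len(tp))
  disk <- (off$dr - cx)^2 + (off$dc - cx)^2 <= rad^2
  ndisk <- sum(disk)
  for (i in seq_len(nrow(observations))) {
    r0 <- (observations$row[i] - 1L) * tp
    c0 <- (observations$col[i] - 1L) * tp
    # images are physical: a non-positive pixelsum renders as an empty patch
    per_px <- max(observations$pixelsum[i], 0) / ndisk
    img[cbind(r0 + off$dr[disk], c0 + off$dc[disk])] <- per_px
  }
  attr(img, "wells") <- well_label(observations$row, observations$col)
  img
}

#' Write / read a rendered plate image as 8-bit PNG
#'
#' The image is scaled by its maximum into `[0, 1]` before writing; the scale
#' factor is returned (and re-applied by `read_plate_png`), so round-tripped
#' pixelsums agree with the rendered ones up to 8-bit quantization.
#'
#' @param img Matrix from [render_plate_image()].
#' @param path Output path.
#' @return `write_plate_png` returns the scale factor invisibly;
#'   `read_plate_png` returns the rescaled intensity matrix.
#' @export
write_plate_png <- function(img, path) {
  mx <- max(img)
  scale <- if (mx > 0) mx else 1
  png::writePNG(img / scale, target = path)
  invisible(scale)
}

#' @rdname write_plate_png
#' @param scale Scale factor returned by `write_plate_png`.
#' @export
read_plate_png <- function(path, scale = 1) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * scale
}
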