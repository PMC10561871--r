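# Synthetic-data generators: mixture structure, determinism, and the
# statistical properties the downstream stages rely on.

test_that("allele-effect mixture honors degenerate weights and the seed", {
  cfg <- sim_config(seed = 3, n_variants = 50,
                    effect_mixture = list(
                      weights = c(unimpaired = 0, low = 1, intermediate = 0),
                      unimpaired = c(mean = 1, sd = 0.03),
                      low = c(mean = 0, sd = 0),
                      intermediate = c(mean = 0.86, sd = 0.03)))
  eff <- simulate_allele_effects(cfg)
  expect_true(all(eff$effect == 0))
  cfg2 <- small_config(seed = 11)
  expect_identical(simulate_allele_effects(cfg2), simulate_allele_effects(cfg2))
  expect_false(identical(simulate_allele_effects(small_config(seed = 12))$effect,
                         simulate_allele_effects(cfg2)$effect))
})

test_that("default mixture echoes the published class proportions at n = 2000", {
  eff <- simulate_allele_effects(sim_config(seed = 1, n_variants = 2000))
  scheme <- threshold_scheme(0.82, 0.91)
  frac <- table(classify_clinical(eff$effect, scheme)) / nrow(eff)
  expect_lt(abs(frac[["deleterious"]] - 0.28), 0.03)
  expect_lt(abs(frac[["uncertain"]] - 0.15), 0.03)
  expect_lt(abs(frac[["non_deleterious"]] - 0.57), 0.03)
})

test_that("mixture configuration is validated", {
  expect_error(sim_config(effect_mixture = list(
    weights = c(unimpaired = 0.6, low = 0.6, intermediate = -0.2),
    unimpaired = c(mean = 1, sd = 0.03), low = c(mean = 0, sd = 0.02),
    intermediate = c(mean = 0.86, sd = 0.03))), "sum to 1")
  expect_error(sim_config(noise_sd = -0.1), "dispersions")
  expect_error(sim_config(error_rate_range = c(0.1, 0.01)), "error_rate_range")
})

test_that("plate simulation produces the documented structure", {
  # nuisances and noise disabled, all effects 1: every observation identical
  cfg <- sim_config(seed = 2, n_variants = 10, noise_sd = 0, plate_sd = 0,
                    edge_factor = 1, neighbor_coef = 0)
  eff <- data.frame(label = paste0("v", 1:10), residue_index = 2:11,
                    ref_aa = "A", alt_aa = "V", effect = 1)
  obs <- simulate_plate_set(eff, cfg)
  non_null <- obs[obs$genotype != "null", ]
  expect_equal(length(unique(non_null$pixelsum)), 1L)
  # null controls carry only the background term
  expect_true(all(obs$pixelsum[obs$genotype == "null"] == cfg$base_background))
  # every plate has its fixed control complement
  per_plate <- table(obs$genotype[obs$replicate == 1], obs$plate_id[obs$replicate == 1])
  expect_true(all(per_plate["WT", ] == 4))
  expect_true(all(per_plate["null", ] == 2))
  # determinism
  expect_identical(obs, simulate_plate_set(eff, cfg))
  # duplicate wells rejected
  lay <- vemap:::plate_layout(paste0("i", 1:5), paste0("v", 1:5))
  lay$well[2] <- lay$well[1]
  expect_error(simulate_plate_set(eff, cfg, layout = lay), "duplicate well")
})

test_that("plate simulation -> normalization recovers the generating effects", {
  # exact at zero noise with all nuisance effects enabled
  cfg0 <- sim_config(seed = 5, n_variants = 60, noise_sd = 0)
  obs0 <- simulate_plate_set(simulate_allele_effects(cfg0), cfg0)
  nm0 <- normalize_growth(obs0, "haploid")
  truth0 <- attr(obs0, "truth")$effects
  expect_lt(max(abs(nm0$scores$score - truth0[nm0$scores$genotype])), 1e-6)
  # RMSE below 0.02 at replicate noise 0.05 with plate/edge/neighbor effects
  cfg <- sim_config(seed = 6, n_variants = 300, noise_sd = 0.05)
  obs <- simulate_plate_set(simulate_allele_effects(cfg), cfg)
  ag <- aggregate_variant_scores(qc_filter_isolates(normalize_growth(obs, "haploid"))$scores)
  truth <- attr(obs, "truth")$effects[ag$label]
  expect_lt(sqrt(mean((ag$score - truth)^2)), 0.02)
})

test_that("pooled read simulation respects design, depth and the seed", {
  cfg <- sim_config(seed = 4, error_rate_range = c(0, 0), read_depth = 6000)
  reference <- stats::setNames(rep("GCT", 40), 1:40)
  des <- data.frame(pool_id = rep("p1", 12), transformant_id = paste0("t", 1:12),
                    position = 2:13)
  tc <- stats::setNames(rep("GTT", 12), des$transformant_id)
  counts <- simulate_read_pools(des, tc, reference, cfg)
  expect_identical(counts, simulate_read_pools(des, tc, reference, cfg))
  # with zero error rates the variant frequency is 1/12 up to multinomial noise
  v <- counts[counts$codon == "GTT", ]
  expect_equal(tapply(counts$count, counts$position, sum),
               tapply(rep(cfg$read_depth, nrow(des)), des$position, sum),
               ignore_attr = TRUE)
  freq <- v$count / cfg$read_depth
  expect_true(all(abs(freq - 1 / 12) < 5 * sqrt((1 / 12) * (11 / 12) / cfg$read_depth)))
  # repeated target codon in one pool is rejected
  des_bad <- des
  des_bad$position[2] <- des_bad$position[1]
  expect_error(simulate_read_pools(des_bad, tc, reference, cfg), "repeated target")
})

test_that("diploid pair generation applies d = a + b*x_j + c*x_k", {
  cfg <- sim_config(seed = 9, diploid_noise_sd = 0)
  p1 <- simulate_diploid_pairs(config = cfg,
                               pairs = data.frame(score1 = c(1, 0), score2 = c(1, 0)))
  expect_equal(p1$d, c(0.05 + 0.28 + 0.73, 0.05))   # 1.06 and the intercept
  # zero-noise table refit recovers the generating coefficients
  set.seed(1)
  tab <- data.frame(score1 = runif(30), score2 = runif(30))
  p2 <- simulate_diploid_pairs(config = cfg, pairs = tab)
  expect_equal(coef(fit_diploid_growth(p2)), c(a = 0.05, b = 0.28, c = 0.73),
               tolerance = 1e-8)
  # trio design has the documented composition
  trio <- simulate_diploid_pairs(config = sim_config(seed = 10))
  expect_equal(as.integer(table(trio$label)[c("patient", "carrier", "control")]),
               c(9L, 10L, 4L))
  expect_equal(nrow(trio), 23L)
  expect_true(all(trio$x_j <= trio$x_k))
})

test_that("plate rendering is quantitative and deterministic", {
  cfg <- sim_config(seed = 2, tile_px = 24, patch_radius = 8)
  obs <- data.frame(row = rep(1:8, each = 12), col = rep(1:12, times = 8),
                    pixelsum = 0)
  img0 <- render_plate_image(obs, cfg)
  expect_true(all(img0 == 0))                        # uniform background
  obs$pixelsum[30] <- 5e4
  img <- render_plate_image(obs, cfg)
  expect_equal(sum(img), 5e4)
  expect_identical(img, render_plate_image(obs, cfg)) # byte-identical
  # single bright patch round-trips through the quantification pipeline
  q <- quantify_plate_image(img)
  w <- well_label(obs$row[30], obs$col[30])
  expect_lt(abs(q$pixelsum[q$well == w] - 5e4) / 5e4, 0.01)
  expect_error(render_plate_image(rbind(obs, obs[1, ]), cfg), "same well")
})

test_that("residue profiles couple conservation to realized sensitivity", {
  cfg <- sim_config(seed = 13, n_variants = 600)
  eff <- simulate_allele_effects(cfg)
  prof <- simulate_residue_profiles(eff, cfg)
  expect_equal(nrow(prof), length(unique(eff$residue_index)))
  rho <- suppressWarnings(stats::cor(prof$consurf_score, prof$median_growth,
                                     method = "spearman"))
  expect_gt(rho, 0.2)                                # positive coupling
  expect_identical(prof, simulate_residue_profiles(eff, cfg))
})
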