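# Pooled variant calling: error-model estimator, the four rejection filters,
# secondary-mutation screening, and end-to-end precision/recall.

make_counts <- function(pool, pos, codons, counts) {
  data.frame(pool_id = pool, position = pos, codon = codons, count = counts,
             stringsAsFactors = FALSE)
}

# a permissive error model: every variant codon near the pseudocount floor
flat_model <- function(positions, total = 1e6) {
  ctrl <- do.call(rbind, lapply(positions, function(p) {
    make_counts("ctrl", p, "GCT", total)
  }))
  estimate_error_model(ctrl)
}

test_that("error-model estimator follows the pseudocount formula", {
  ctrl <- make_counts("ctrl", 5, c("GCT", "GTT"), c(9990, 10))
  m <- estimate_error_model(ctrl, pseudocount = 1)
  expect_equal(error_freq(m, 5, "GTT"), 11 / (10000 + 64))
  # a codon never observed receives the strictly positive floor
  expect_equal(error_freq(m, 5, "TTT"), 1 / (10000 + 64))
  # doubling all control counts leaves the frequency asymptotically unchanged
  m2 <- estimate_error_model(make_counts("ctrl", 5, c("GCT", "GTT"), c(19980, 20)))
  expect_equal(error_freq(m2, 5, "GTT"), error_freq(m, 5, "GTT"), tolerance = 0.05)
  # and converges to the raw frequency as depth grows
  m3 <- estimate_error_model(make_counts("ctrl", 5, c("GCT", "GTT"), c(999000, 1000)))
  expect_equal(error_freq(m3, 5, "GTT"), 0.001, tolerance = 1e-3)
  expect_error(estimate_error_model(make_counts("ctrl", 7, "GCT", 0)), "zero total")
  expect_error(error_freq(m, 99, "GTT"), "absent")
})

test_that("the four filters reject and pass exactly as specified", {
  ref <- stats::setNames(rep("GCT", 10), 1:10)
  des <- data.frame(pool_id = "p1", transformant_id = "t1", position = 3)
  # called: candidate 80/1000 (40x its error 0.002), second 10 reads at 2x its
  # error (not enriched), 80 >= 15 reads
  ctrl <- rbind(make_counts("ctrl", 3, c("GCT", "GTT", "GAT"), c(1e5 - 701, 200, 501)))
  m <- estimate_error_model(ctrl)
  cnt <- make_counts("p1", 3, c("GCT", "GTT", "GAT"), c(910, 80, 10))
  call <- call_pool_variants(cnt, m, des, ref)
  expect_equal(call$status, "called")
  expect_equal(call$codon, "GTT")
  expect_equal(call$substitution, hgvs_p(3, "A", "V"))
  expect_equal(call$frequency, 0.08)
  # (iii) fewer than 15 supporting reads
  cnt2 <- make_counts("p1", 3, c("GCT", "GTT"), c(988, 12))
  call2 <- call_pool_variants(cnt2, flat_model(3), des, ref)
  expect_equal(call2$status, "no_call")
  expect_match(call2$reasons, "min_reads")
  # exactly 15 reads passes (strict "less than" semantics)
  cnt2b <- make_counts("p1", 3, c("GCT", "GTT"), c(985, 15))
  expect_equal(call_pool_variants(cnt2b, flat_model(3), des, ref)$status, "called")
  # (ii) ambiguous second: 30 reads, 15x its error and 37.5% of the candidate
  ctrl3 <- make_counts("ctrl", 3, c("GCT", "GAT"), c(1e5 - 200, 200))
  m3 <- estimate_error_model(ctrl3)
  cnt3 <- make_counts("p1", 3, c("GCT", "GTT", "GAT"), c(890, 80, 30))
  call3 <- call_pool_variants(cnt3, m3, des, ref)
  expect_equal(call3$status, "no_call")
  expect_match(call3$reasons, "ambiguous_second")
  # (i) candidate below 3.3x its error frequency
  ctrl4 <- make_counts("ctrl", 3, c("GCT", "GTT"), c(97000, 3000))
  cnt4 <- make_counts("p1", 3, c("GCT", "GTT"), c(950, 50))  # f = 0.05 < 3.3 * 0.03
  call4 <- call_pool_variants(cnt4, estimate_error_model(ctrl4), des, ref)
  expect_equal(call4$status, "no_call")
  expect_match(call4$reasons, "low_enrichment")
  # zero variant reads
  cnt5 <- make_counts("p1", 3, "GCT", 1000)
  call5 <- call_pool_variants(cnt5, flat_model(3), des, ref)
  expect_equal(call5$status, "no_call")
  expect_match(call5$reasons, "no_variant_reads")
  # every no-call carries a machine-readable reason, tallied in the summary
  tally <- attr(rbind_calls <- call_pool_variants(cnt4, estimate_error_model(ctrl4),
                                                  des, ref), "filter_tally")
  expect_equal(unname(tally[["low_enrichment"]]), 1)
})

test_that("design constraints are enforced", {
  ref <- stats::setNames(rep("GCT", 20), 1:20)
  m <- flat_model(2:14)
  cnt <- make_counts("p1", 3, c("GCT", "GTT"), c(900, 100))
  expect_error(call_pool_variants(cnt, m, data.frame(pool_id = character(0),
                                                     transformant_id = character(0),
                                                     position = integer(0)),
                                  ref), "empty pool")
  des13 <- data.frame(pool_id = "p1", transformant_id = paste0("t", 1:13),
                      position = 2:14)
  expect_error(call_pool_variants(cnt, m, des13, ref), "more than 12")
  des_dup <- data.frame(pool_id = "p1", transformant_id = c("t1", "t2"),
                        position = c(3, 3))
  expect_error(call_pool_variants(cnt, m, des_dup, ref), "repeats a target")
  des_missing <- data.frame(pool_id = "p1", transformant_id = "t1", position = 9)
  expect_error(call_pool_variants(cnt, m, des_missing, ref), "absent from counts")
})

test_that("raising the candidate count never converts a call into a no-call", {
  ref <- stats::setNames(rep("GCT", 5), 1:5)
  des <- data.frame(pool_id = "p1", transformant_id = "t1", position = 2)
  ctrl <- make_counts("ctrl", 2, c("GCT", "GTT", "GAT"), c(98800, 700, 500))
  m <- estimate_error_model(ctrl)
  was_called <- FALSE
  for (k in c(5, 10, 15, 40, 80, 200, 500)) {
    cnt <- make_counts("p1", 2, c("GCT", "GTT", "GAT"), c(1000, k, 12))
    st <- call_pool_variants(cnt, m, des, ref)$status
    if (was_called) expect_equal(st, "called")
    if (st == "called") was_called <- TRUE
  }
  expect_true(was_called)
})

test_that("secondary mutations are screened with the synonymous exemption", {
  ref <- stats::setNames(c("GCT", "GCT", "TTA"), 1:3)
  ctrl <- rbind(make_counts("ctrl", 2, c("GCT", "GAT"), c(99900, 100)),
                make_counts("ctrl", 3, c("TTA", "TTG", "CTA"), c(99800, 100, 100)))
  m <- estimate_error_model(ctrl)
  # synonymous non-target variant at high frequency: not flagged (TTA -> TTG, Leu)
  syn <- make_counts("p1", 3, c("TTA", "TTG"), c(800, 200))
  expect_length(detect_secondary_mutations(syn, m, ref), 0)
  # missense at 50/1000 with low error: flagged (GCT -> GAT, Ala -> Asp)
  mis <- make_counts("p1", 2, c("GCT", "GAT"), c(950, 50))
  expect_equal(detect_secondary_mutations(mis, m, ref), 2L)
  # noise-level missense below 3.3x error: not flagged
  lowf <- make_counts("p1", 2, c("GCT", "GAT"), c(99700, 300))  # f = 0.003 ~ 3x e
  expect_length(detect_secondary_mutations(lowf, m, ref), 0)
  # a flagged secondary rejects the pool's transformants
  des <- data.frame(pool_id = "p1", transformant_id = "t1", position = 1)
  cnt <- rbind(make_counts("p1", 1, c("GCT", "GTT"), c(900, 100)), mis)
  ctrl1 <- rbind(make_counts("ctrl", 1, "GCT", 1e5), ctrl)
  call <- call_pool_variants(cnt, estimate_error_model(ctrl1), des,
                             stats::setNames(c("GCT", "GCT", "GCT", "TTA"), 0:3)[2:4])
  expect_equal(call$status, "no_call")
  expect_match(call$reasons, "secondary_mutation")
})

test_that("noise-free simulated pools are called with precision and recall 1", {
  cfg <- sim_config(seed = 21, error_rate_range = c(0, 0), read_depth = 2500)
  reference <- stats::setNames(rep(c("GCT", "AAA", "TGG", "CGT"), 15), 1:60)
  des <- data.frame(pool_id = rep(paste0("p", 1:5), each = 12),
                    transformant_id = paste0("t", 1:60),
                    position = rep(1:12, 5) + rep(c(0, 12, 24, 36, 48), each = 12))
  alts <- c(GCT = "GAT", AAA = "ACA", TGG = "TGT", CGT = "CAT")
  tc <- stats::setNames(unname(alts[reference[des$position]]), des$transformant_id)
  counts <- simulate_read_pools(des, tc, reference, cfg)
  ctrl <- simulate_control_counts(unique(des$position), reference, cfg, depth = 50000L)
  m <- estimate_error_model(ctrl)
  calls <- call_pool_variants(counts, m, des, reference)
  expect_true(all(calls$status == "called"))                       # recall = 1
  expect_true(all(calls$codon == tc[calls$transformant_id]))       # precision = 1
})

test_that("a variant forced below 3.3x its error rate is not called", {
  # constructed counts: candidate frequency 0.008 with error frequency 0.003
  ref <- stats::setNames("GCT", 1)
  ctrl <- make_counts("ctrl", 1, c("GCT", "GTT"), c(99700, 300))
  m <- estimate_error_model(ctrl)
  des <- data.frame(pool_id = "p1", transformant_id = "t1", position = 1)
  cnt <- make_counts("p1", 1, c("GCT", "GTT"), c(9920, 80))
  call <- call_pool_variants(cnt, m, des, ref)
  expect_equal(call$status, "no_call")
  expect_match(call$reasons, "low_enrichment")
})
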