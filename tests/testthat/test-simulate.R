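# Synthetic-data generator: determinism, planted ground truth, and
# statistical targets.

test_that("genome CpG density matches the configured Poisson process", {
  cfg <- sim_config(seed = 3, n_chroms = 1, chrom_length = 1e6,
                    n_cpg_islands = 0, background_cpg_rate = 0.01,
                    n_genes = 0, n_planted_dmrs = 0)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$islands), 0)
  expect_equal(nrow(g$genes), 0)
  # Poisson(1e4) within 3 sigma (minus a handful of position collisions)
  expect_gt(nrow(g$cpg), 1e4 - 3 * 100 - 60)
  expect_lt(nrow(g$cpg), 1e4 + 3 * 100)
  expect_false(is.unsorted(g$cpg$pos, strictly = TRUE))
})

test_that("generators are deterministic given the config seed", {
  cfg <- sim_config(seed = 11, n_chroms = 1, chrom_length = 2e5,
                    n_cpg_islands = 3, n_planted_dmrs = 5, n_genes = 5,
                    n_vpr = 50, n_vpp = 10, n_vppr = 10)
  g1 <- generate_genome(cfg); g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  m1 <- generate_methylomes(g1, cfg); m2 <- generate_methylomes(g2, cfg)
  expect_identical(m1, m2)
  v1 <- generate_variants(g1, cfg); v2 <- generate_variants(g2, cfg)
  expect_identical(v1, v2)
  expect_identical(generate_expression(cfg), generate_expression(cfg))
  expect_identical(generate_dose_response(cfg), generate_dose_response(cfg))
})

test_that("oversized island requests and bad configs are rejected", {
  expect_error(generate_genome(
    sim_config(n_chroms = 1, chrom_length = 1e4, n_cpg_islands = 20)),
    "island")
  expect_error(sim_config(dmr_delta = 0), "dmr_delta")
  expect_error(sim_config(wgs_depth = 0), "wgs_depth")
  expect_error(sim_config(frac_hyper = 1.2), "frac_hyper")
  expect_error(sim_config(ploidy = 0), "ploidy")
})

test_that("planted DMR truth is honored by the noiseless methylomes", {
  cfg <- sim_config(seed = 5, n_chroms = 1, chrom_length = 5e5,
                    n_cpg_islands = 5, n_planted_dmrs = 12,
                    frac_reverting = 1, frac_hyper = 1, dmr_delta = 0.4,
                    noiseless = TRUE)
  g <- generate_genome(cfg)
  m <- generate_methylomes(g, cfg)
  expect_equal(nrow(m$truth), 12)
  expect_true(all(m$truth$direction == "hyper"))
  expect_true(all(m$truth$reverting))
  expect_equal(m$truth$m_resistant - m$truth$m_parental, rep(0.4, 12))
  # P5 strictly between resistant and P12 at every planted CpG, all lines
  for (ln in c("line1", "line2")) {
    r <- m$tracks[[paste0(ln, "_resistant")]]$records$methylation
    p5 <- m$tracks[[paste0(ln, "_P5")]]$records$methylation
    p12 <- m$tracks[[paste0(ln, "_P12")]]$records$methylation
    for (d in seq_len(nrow(m$truth))) {
      run <- m$truth$first_idx[d]:m$truth$last_idx[d]
      expect_true(all(p5[run] > pmin(r[run], p12[run]) &
                        p5[run] < pmax(r[run], p12[run])))
    }
  }
  # planted DMRs are non-overlapping and within bounds
  expect_true(all(m$truth$start >= 0 & m$truth$end <= cfg$chrom_length))
  o <- order(m$truth$start)
  expect_true(all(m$truth$start[o][-1] >= m$truth$end[o][-12]))
})

test_that("observed methylation shift in planted DMRs matches dmr_delta", {
  cfg <- sim_config(seed = 8, n_chroms = 2, chrom_length = 1e6,
                    n_planted_dmrs = 30, dmr_delta = 0.5,
                    coverage_mean = 30)
  g <- generate_genome(cfg)
  m <- generate_methylomes(g, cfg)
  idx <- unlist(mapply(seq, m$truth$first_idx, m$truth$last_idx))
  for (ln in c("line1", "line2")) {
    d <- m$tracks[[paste0(ln, "_resistant")]]$records$methylation[idx] -
      m$tracks[[paste0(ln, "_parental")]]$records$methylation[idx]
    sgn <- ifelse(rep(m$truth$direction, m$truth$n_cpgs) == "hyper", 1, -1)
    expect_equal(mean(d * sgn), 0.5, tolerance = 0.05 / 0.5)
  }
})

test_that("variant VAFs follow the planted clonal structure", {
  cfg <- sim_config(seed = 2, n_vpr = 100, n_vpp = 20, n_vppr = 30,
                    ploidy = 4, noiseless = TRUE)
  g <- generate_genome(cfg)
  v <- generate_variants(g, cfg)$variants
  vpr <- v[v$class_true == "VpR", ]
  expect_true(all(vpr$vaf_parental == 0))
  expect_true(all(vpr$vaf_resistant == 0.25))
  expect_true(all(vpr$vaf_P12 == 0.25))  # resistant genotype persists
  vpp <- v[v$class_true == "VpP", ]
  expect_true(all(vpp$vaf_resistant == 0))
  expect_true(all(vpp$vaf_parental > 0))
  expect_true(all(v$ref != v$alt))

  cfg2 <- sim_config(seed = 2, n_vpr = 0, n_vpp = 30, n_vppr = 30,
                     noiseless = TRUE)
  v2 <- generate_variants(g, cfg2)$variants
  expect_false(any(v2$vaf_parental == 0 & v2$vaf_resistant > 0.1))

  cfg3 <- sim_config(seed = 2, n_vpr = 50, n_vpp = 0, n_vppr = 0,
                     ploidy = 2, noiseless = TRUE)
  v3 <- generate_variants(g, cfg3)$variants
  expect_true(all(v3$vaf_resistant == 0.5))
})

test_that("expression table separates reverting, stable and null genes", {
  cfg <- sim_config(seed = 4, n_genes = 200, noiseless = TRUE,
                    expr_frac_de = 0.4, frac_reverting = 0.3)
  e <- generate_expression(cfg)
  expect_equal(nrow(e), 200)
  s <- expression_reversion_score(e$log2fc_P_vs_R, e$log2fc_P12_vs_R)
  expect_true(all(s[e$class_true == "reverting"] == 1))
  expect_true(all(s[e$class_true == "null"] == 0))
  expect_true(all(abs(e$log2fc_P_vs_R[e$class_true == "null"]) < 1))
  # stable genes keep resistant-like expression in P12: huge ratio score
  expect_true(all(s[e$class_true == "stable"] > 100))
})

test_that("dose-response surfaces follow the 3-parameter model and Loewe", {
  cfg <- sim_config(seed = 6, noiseless = TRUE, ic50_true = 10,
                    ic50_true_b = 100, hill_top = 100, hill_bottom = 0)
  dr <- generate_dose_response(cfg, doses_a = 10 * 2^(-3:3),
                               doses_b = 100 * 2^(-3:3))
  # viability at the true IC50 is halfway between the plateaus
  expect_equal(dr$drug_a$viability[dr$drug_a$dose == 10], 50)
  expect_equal(dr$drug_b$viability[dr$drug_b$dose == 100], 50)
  # zero-dose corner of the combination grid sits at the top plateau
  expect_equal(dr$combo$viability[dr$combo$dose_a == 0 &
                                    dr$combo$dose_b == 0], 100)
  # no planted synergy: surface equals the Loewe expectation exactly
  s <- dr$combo$dose_a / 10 + dr$combo$dose_b / 100
  expect_equal(dr$combo$viability, 100 / (1 + s))
  expect_error(generate_dose_response(cfg, doses_a = c(10, 5, 20)),
               "increasing")
})

test_that("feature tracks are enriched in planted DMRs as configured", {
  cfg <- sim_config(seed = 9, n_chroms = 2, chrom_length = 1e6,
                    n_planted_dmrs = 40, feature_enrichment_factor = 40,
                    feature_bg_coverage = 0.02)
  g <- generate_genome(cfg)
  m <- generate_methylomes(g, cfg)
  g <- generate_features(g, m$truth, cfg, track_names = c("tfbs", "atac"))
  expect_named(g$feature_tracks, c("tfbs", "atac"))
  ft <- attr(g, "feature_truth")
  # planted overlap probability 0.8: both tracks should cover most DMRs
  frac <- overlap_fraction(m$truth[, c("chrom", "start", "end")],
                           g$feature_tracks$tfbs)
  expect_gte(frac, 0.6)
  expect_true(all(ft$tfbs %in% c(TRUE, FALSE)))
})
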