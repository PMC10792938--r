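# Smoothing, DMR calling (with the exhaustive-scan oracle), summaries,
# amplicon validation and metaprofiles.

test_that("coverage-weighted smoothing averages correctly", {
  pos <- seq(0, 90, 10)
  t_const <- make_track("l1", "parental", pos, rep(0.8, 10))
  expect_equal(smooth_methylation(t_const, 5)$records$methylation,
               rep(0.8, 10))
  t3 <- make_track("l1", "parental", c(0, 10, 20), c(0, 1, 0), cov = 10)
  expect_identical(smooth_methylation(t3, 1), t3)
  sm <- smooth_methylation(t3, 3)$records$methylation
  expect_equal(sm[2], 1 / 3)      # equal-coverage mean of (0, 1, 0)
  expect_equal(sm[1], 0.5)        # truncated edge window (0, 1)
  # coverage weighting: middle CpG carries double weight
  t3w <- make_track("l1", "parental", c(0, 10, 20), c(0, 1, 0),
                    cov = c(10, 20, 10))
  expect_equal(smooth_methylation(t3w, 3)$records$methylation[2],
               20 / 40)
  # empty track passes through
  t0 <- make_track("l1", "parental", numeric(0), numeric(0))
  expect_equal(nrow(smooth_methylation(t0, 5)$records), 0)
})

# noiseless two-line fixture: 50 CpGs, a shifted run at indices 21..30
two_line_tracks <- function(delta_a = 0.5, delta_b = 0.5, run = 21:30,
                            base = 0.2) {
  pos <- seq(0, by = 100, length.out = 50)
  mk <- function(line, state, delta) {
    m <- rep(base, 50)
    if (state == "resistant") m[run] <- m[run] + delta
    make_track(line, state, pos, pmin(1, pmax(0, m)))
  }
  list(a_p = mk("lineA", "parental", 0), a_r = mk("lineA", "resistant", delta_a),
       b_p = mk("lineB", "parental", 0), b_r = mk("lineB", "resistant", delta_b))
}

test_that("a planted run is called as exactly one DMR in both-line mode", {
  tr <- two_line_tracks()
  dmrs <- call_dmrs(tr, dmr_call_params())
  expect_equal(nrow(dmrs), 1)
  expect_equal(dmrs$direction, "hyper")
  expect_equal(dmrs$n_cpgs, 10)
  expect_equal(dmrs$start, 2000)
  expect_equal(dmrs$end, 2901)
  expect_equal(dmrs$mean_lineA_parental, 0.2)
  expect_equal(dmrs$mean_lineA_resistant, 0.7)
})

test_that("DMR calling enforces min CpGs, both lines, and direction", {
  # 3 qualifying CpGs only
  expect_equal(nrow(call_dmrs(two_line_tracks(run = 21:23),
                              dmr_call_params())), 0)
  # shift in one line only
  expect_equal(nrow(call_dmrs(two_line_tracks(delta_b = 0),
                              dmr_call_params())), 0)
  # opposite directions between lines
  tr <- two_line_tracks(delta_a = 0.5, delta_b = -0.5, base = 0.5)
  expect_equal(nrow(call_dmrs(tr, dmr_call_params())), 0)
  # hypomethylated run is called with direction hypo
  tr2 <- two_line_tracks(delta_a = -0.5, delta_b = -0.5, base = 0.7)
  d2 <- call_dmrs(tr2, dmr_call_params())
  expect_equal(d2$direction, "hypo")
})

test_that("per-CpG mode requires the smoothed difference at every CpG", {
  tr <- two_line_tracks()
  d <- call_dmrs(tr, dmr_call_params(delta_mode = "per_cpg"))
  expect_equal(nrow(d), 1)
  # running-mean smoothing erodes the run edges, so the per-CpG call is
  # strictly inside the planted run
  expect_gte(d$start, 2000)
  expect_lte(d$end, 2901)
  expect_lte(d$n_cpgs, 10)
})

test_that("calling matches the exhaustive-scan oracle on small inputs", {
  params <- dmr_call_params(min_cpgs = 3, min_delta = 0.3)
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    pos <- sort(sample(0:(20 * n), n))
    mk <- function(line, state) {
      base <- round(stats::runif(n), 2)
      make_track(line, state, pos, base)
    }
    # correlated tracks with random shifted blocks
    base <- round(stats::runif(n), 2)
    shift <- numeric(n)
    for (b in 1:6) {
      i <- sample(n - 10, 1); k <- sample(2:9, 1)
      shift[i:(i + k)] <- round(stats::runif(1, -0.6, 0.6), 2)
    }
    tracks <- list(
      make_track("l1", "parental", pos, base),
      make_track("l1", "resistant", pos, pmin(1, pmax(0, base + shift))),
      make_track("l2", "parental", pos, base),
      make_track("l2", "resistant", pos, pmin(1, pmax(0, base + shift))))
    got <- call_dmrs(tracks, params)
    want <- oracle_call_dmrs(tracks, params)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_cpgs, want$n_cpgs)
      expect_equal(got$direction, want$direction)
    }
  }
})

test_that("relaxing thresholds never reduces the number of DMRs", {
  cfg <- sim_config(seed = 21, n_chroms = 1, chrom_length = 1e6,
                    n_planted_dmrs = 15, dmr_delta = 0.5)
  g <- generate_genome(cfg)
  m <- generate_methylomes(g, cfg)
  pr <- m$tracks[grep("parental|resistant", names(m$tracks))]
  n_ref <- nrow(call_dmrs(pr, dmr_call_params(min_delta = 0.4)))
  expect_gte(nrow(call_dmrs(pr, dmr_call_params(min_delta = 0.3))), n_ref)
  expect_gte(nrow(call_dmrs(pr, dmr_call_params(min_cpgs = 3))), n_ref)
})

test_that("record order and chromosome mismatches are handled", {
  tr <- two_line_tracks()
  # shuffled input records are re-sorted by the constructor
  shuf <- tr
  set.seed(1)
  o <- sample(50)
  r <- tr$a_r$records[o, ]
  shuf$a_r <- dmrevert:::new_methylome_track("lineA", "resistant", r)
  expect_equal(call_dmrs(shuf, dmr_call_params()),
               call_dmrs(tr, dmr_call_params()))
  # a track missing a chromosome triggers a named error
  tr$b_p$records$chrom <- "chr2"
  expect_error(call_dmrs(tr, dmr_call_params()), "chr")
})

test_that("DMR summaries report counts, directions and sizes", {
  d1 <- data.frame(chrom = "chr1", start = 0, end = 100, n_cpgs = 5,
                   length = 100, direction = "hyper")
  s <- summarize_dmrs(d1)
  expect_equal(s$n, 1); expect_equal(s$hyper_fraction, 1)
  expect_equal(s$mean_length, 100); expect_false(s$empty)
  d2 <- rbind(d1, d1); d2$direction <- "hypo"
  expect_equal(summarize_dmrs(d2)$hyper_fraction, 0)
  s0 <- summarize_dmrs(d1[0, ])
  expect_true(s0$empty); expect_equal(s0$n, 0)
})

test_that("hyper fraction of called DMRs tracks the planted fraction", {
  cfg <- sim_config(seed = 31, n_chroms = 2, chrom_length = 2e6,
                    n_planted_dmrs = 50, dmr_delta = 0.5, frac_hyper = 0.96)
  g <- generate_genome(cfg)
  m <- generate_methylomes(g, cfg)
  pr <- m$tracks[grep("parental|resistant", names(m$tracks))]
  s <- summarize_dmrs(call_dmrs(pr, dmr_call_params()))
  expect_equal(s$hyper_fraction, 0.96, tolerance = 0.05 / 0.96)
})

test_that("amplicon validation applies the 0.2 threshold and direction", {
  expect_true(validate_amplicon(0.1, 0.4))
  expect_false(validate_amplicon(0.5, 0.6))
  expect_false(validate_amplicon(0.3, 0.1, wgbs_direction = "hyper"))
  expect_true(validate_amplicon(0.3, 0.1, wgbs_direction = "hypo"))
  expect_true(validate_amplicon(0.1, 0.4, wgbs_direction = "hyper"))
})

test_that("metaprofiles resolve body and flank signal", {
  pos <- seq(0, 9990, 10)
  m_const <- make_track("l1", "parental", pos, rep(0.7, length(pos)))
  regions <- intervals("chr1", 4000, 6000)
  prof <- metaprofile(regions, m_const, flank = 2000, body_bins = 5,
                      flank_bins = 4)
  expect_true(all(abs(prof$mean_methylation[prof$n_cpgs > 0] - 0.7) < 1e-12))
  # step track: 1 inside the region, 0 outside
  step <- ifelse(pos >= 4000 & pos < 6000, 1, 0)
  m_step <- make_track("l1", "parental", pos, step)
  p2 <- metaprofile(regions, m_step, flank = 2000, body_bins = 5,
                    flank_bins = 4)
  expect_true(all(p2$mean_methylation[p2$section == "body"] == 1))
  expect_true(all(p2$mean_methylation[p2$section != "body"] == 0))
  # region at the chromosome edge: flank truncated, no error
  p3 <- metaprofile(intervals("chr1", 0, 1000), m_const, flank = 2000,
                    body_bins = 3, flank_bins = 2)
  expect_true(all(p3$n_cpgs[p3$section == "upstream"] == 0))
  expect_true(all(is.nan(p3$mean_methylation[p3$section == "upstream"])))
})
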