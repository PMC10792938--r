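# Synthetic-data generator: genomes, methylomes, variant tables, feature
# tracks, expression tables and dose-response surfaces with planted ground
# truth, emulating a four-state (parental / resistant / P5 / P12) drug
# resistance study in two cell lines.

STATES <- c("parental", "resistant", "P5", "P12")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design: two cell lines sampled at four states, DMRs of 4-30 CpGs
#' with a methylation shift of 0.4 that is >96% hypermethylated in the
#' resistant state, ~10% of DMRs reverting after drug withdrawal, 30x
#' bisulfite coverage, a near-tetraploid clonal structure sequenced at 40x,
#' and low-nanomolar IC50 dose-response curves.
#'
#' @param seed integer seed; identical configs give identical outputs.
#' @param n_chroms,chrom_length number and length (bp) of simulated
#'   chromosomes.
#' @param n_cpg_islands total CpG islands across the genome.
#' @param background_cpg_rate,island_cpg_rate CpG densities (CpGs/bp)
#'   outside and inside islands.
#' @param n_genes gene models to simulate (also the row count of the
#'   expression table).
#' @param n_lines number of cell lines (>= 2; DMRs are planted in all).
#' @param n_planted_dmrs,dmr_cpg_range,dmr_delta planted DMR count, CpG-run
#'   length range, and true methylation difference (resistant - parental,
#'   in (0, 1]).
#' @param frac_hyper fraction of planted DMRs hypermethylated in resistant.
#' @param frac_reverting fraction of planted DMRs whose P12 methylation
#'   returns to the parental level (P5 halfway between).
#' @param coverage_mean mean per-CpG read coverage (Poisson, floored at 1).
#' @param dispersion beta-binomial overdispersion of methylation counts
#'   (0 = pure binomial).
#' @param noiseless if TRUE, observed levels/VAFs/viabilities equal their
#'   true values (no sampling noise).
#' @param ploidy allele count of the simulated clone (4 = near-tetraploid).
#' @param chrom_ploidy optional named vector overriding `ploidy` for
#'   individual chromosomes (models chromosome losses).
#' @param n_vpr,n_vpp,n_vppr counts of variants present only in resistant,
#'   only in parental, and in both.
#' @param wgs_depth sequencing depth for binomial VAF noise.
#' @param feature_enrichment_factor ratio of feature-overlap probability in
#'   planted DMRs to the background genome coverage of the track.
#' @param feature_bg_coverage fraction of the genome covered by background
#'   features of a track.
#' @param expr_frac_de fraction of genes differentially expressed between
#'   parental and resistant.
#' @param expr_noise_sd Gaussian sd on simulated log2 fold changes.
#' @param ic50_true,ic50_true_b true IC50s (nM) of the two drugs.
#' @param hill_top,hill_bottom viability plateaus (%) of the 3-parameter
#'   log-logistic response.
#' @param dr_noise_sd Gaussian sd (viability %) on dose-response readouts.
#' @param synergy_offset planted deviation (viability %) from Loewe
#'   additivity at saturating co-doses; negative = synergistic killing.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1e6,
                       n_cpg_islands = 20L,
                       background_cpg_rate = 0.01,
                       island_cpg_rate = 0.1,
                       n_genes = 40L,
                       n_lines = 2L,
                       n_planted_dmrs = 50L,
                       dmr_cpg_range = c(4L, 30L),
                       dmr_delta = 0.4,
                       frac_hyper = 0.96,
                       frac_reverting = 0.10,
                       coverage_mean = 30,
                       dispersion = 0.02,
                       noiseless = FALSE,
                       ploidy = 4L,
                       chrom_ploidy = NULL,
                       n_vpr = 3000L,
                       n_vpp = 150L,
                       n_vppr = 500L,
                       wgs_depth = 40,
                       feature_enrichment_factor = 40,
                       feature_bg_coverage = 0.02,
                       expr_frac_de = 0.3,
                       expr_noise_sd = 0.1,
                       ic50_true = 12.70,
                       ic50_true_b = 500,
                       hill_top = 100,
                       hill_bottom = 0,
                       dr_noise_sd = 2,
                       synergy_offset = 0) {
  cfg <- as.list(environment())
  counts <- c("n_chroms", "n_cpg_islands", "n_genes", "n_lines",
              "n_planted_dmrs", "n_vpr", "n_vpp", "n_vppr")
  for (nm in counts)
    if (cfg[[nm]] < 0) stop(sprintf("%s must be >= 0", nm))
  if (chrom_length <= 0 || background_cpg_rate <= 0 || island_cpg_rate <= 0)
    stop("chrom_length and CpG rates must be positive")
  if (dmr_delta <= 0 || dmr_delta > 1) stop("dmr_delta must be in (0, 1]")
  if (frac_hyper < 0 || frac_hyper > 1 || frac_reverting < 0 || frac_reverting > 1)
    stop("frac_hyper and frac_reverting must be in [0, 1]")
  if (ploidy < 1) stop("ploidy must be >= 1")
  if (wgs_depth < 1) stop("wgs_depth must be >= 1")
  if (length(dmr_cpg_range) != 2 || dmr_cpg_range[1] > dmr_cpg_range[2] ||
      dmr_cpg_range[1] < 1)
    stop("dmr_cpg_range must be c(min, max) with 1 <= min <= max")
  if (hill_top <= hill_bottom) stop("hill_top must exceed hill_bottom")
  if (ic50_true <= 0 || ic50_true_b <= 0) stop("IC50s must be positive")
  structure(cfg, class = "sim_config")
}

sim_chrom_names <- function(config) paste0("chr", seq_len(config$n_chroms))

#' Simulate a genome annotation
#'
#' Places CpG islands, a CpG coordinate set denser inside islands than
#' outside (Poisson point processes), and gene models with TSS and exons.
#' All coordinates are 0-based half-open.
#'
#' @param config a [sim_config()].
#' @return object of class `genome_annotation`: a list with `chromosomes`
#'   (named lengths), `cpg` (data.frame chrom/pos), `islands` (intervals),
#'   `genes` (data.frame id/chrom/strand/tss/start/end), `exons`
#'   (data.frame gene_id/chrom/start/end) and `feature_tracks` (empty named
#'   list, to be filled by [generate_features()]).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  chroms <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                            sim_chrom_names(config))
  mean_island_len <- 1000
  if (config$n_cpg_islands * mean_island_len >
      config$n_chroms * config$chrom_length)
    stop("island count x mean island size exceeds total chromosome length")

  # islands: random non-overlapping placements, lengths ~ U(500, 1500)
  islands <- intervals()
  if (config$n_cpg_islands > 0) {
    lens <- round(stats::runif(config$n_cpg_islands, 500, 1500))
    chrom_of <- sample(names(chroms), config$n_cpg_islands, replace = TRUE)
    placed <- vector("list", config$n_cpg_islands)
    for (i in seq_len(config$n_cpg_islands)) {
      for (att in 1:1000) {
        s <- floor(stats::runif(1, 0, chroms[chrom_of[i]] - lens[i]))
        cand <- intervals(chrom_of[i], s, s + lens[i])
        prev <- do.call(rbind, placed[seq_len(i - 1)])
        if (i == 1 || !any(overlaps_any(cand, merge_intervals(prev)))) {
          placed[[i]] <- cand
          break
        }
        if (att == 1000) stop("could not place non-overlapping CpG islands")
      }
    }
    islands <- merge_intervals(do.call(rbind, placed))
  }

  # CpGs: homogeneous Poisson outside islands, denser inside
  cpg <- do.call(rbind, lapply(names(chroms), function(chrom) {
    L <- chroms[[chrom]]
    isl <- islands[islands$chrom == chrom, , drop = FALSE]
    bg_len <- L - interval_bp(isl)
    n_bg <- stats::rpois(1, config$background_cpg_rate * bg_len)
    pos_bg <- floor(stats::runif(n_bg, 0, L))
    pos_isl <- numeric(0)
    if (nrow(isl) > 0) {
      # drop background CpGs falling inside islands, then fill islands
      keep <- !overlaps_any(intervals(rep(chrom, length(pos_bg)),
                                      pos_bg, pos_bg + 1), isl)
      pos_bg <- pos_bg[keep]
      pos_isl <- unlist(lapply(seq_len(nrow(isl)), function(i) {
        len <- isl$end[i] - isl$start[i]
        n <- stats::rpois(1, config$island_cpg_rate * len)
        floor(stats::runif(n, isl$start[i], isl$end[i]))
      }))
    }
    pos <- sort(unique(c(pos_bg, pos_isl)))
    if (length(pos) == 0) return(NULL)
    data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(cpg)) cpg <- data.frame(chrom = character(), pos = numeric())
  rownames(cpg) <- NULL

  # gene models with TSS and exons
  genes <- data.frame(id = character(), chrom = character(),
                      strand = character(), tss = numeric(),
                      start = numeric(), end = numeric())
  exons <- data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric())
  if (config$n_genes > 0) {
    g_chrom <- sample(names(chroms), config$n_genes, replace = TRUE)
    g_len <- round(stats::runif(config$n_genes, 5000, 20000))
    g_start <- floor(stats::runif(config$n_genes,
                                  0, chroms[g_chrom] - g_len))
    g_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    genes <- data.frame(
      id = sprintf("gene%03d", seq_len(config$n_genes)),
      chrom = g_chrom, strand = g_strand,
      tss = ifelse(g_strand == "+", g_start, g_start + g_len),
      start = g_start, end = g_start + g_len,
      stringsAsFactors = FALSE)
    exons <- do.call(rbind, lapply(seq_len(config$n_genes), function(i) {
      k <- sample(2:6, 1)
      # partition the gene span into 2k+1 segments; odd segments are exons
      cuts <- sort(stats::runif(2 * k, genes$start[i], genes$end[i]))
      s <- floor(c(genes$start[i], cuts[seq(2, 2 * k, 2)]))
      e <- floor(c(cuts[seq(1, 2 * k - 1, 2)], genes$end[i]))
      keep <- e > s
      data.frame(gene_id = genes$id[i], chrom = genes$chrom[i],
                 start = s[keep], end = e[keep], stringsAsFactors = FALSE)
    }))
    rownames(exons) <- NULL
  }

  structure(list(chromosomes = chroms, cpg = cpg, islands = islands,
                 genes = genes, exons = exons,
                 feature_tracks = stats::setNames(list(), character(0))),
            class = "genome_annotation")
}

new_methylome_track <- function(line_id, state, records) {
  stopifnot(state %in% STATES)
  records <- records[order(records$chrom, records$pos), , drop = FALSE]
  rownames(records) <- NULL
  if (nrow(records) > 0) {
    if (any(records$methylation < 0 | records$methylation > 1))
      stop("methylation levels must lie in [0, 1]")
    if (any(records$coverage < 0)) stop("coverage must be >= 0")
    dup <- unlist(tapply(records$pos, records$chrom,
                         function(p) duplicated(p)))
    if (any(dup)) stop("duplicated CpG positions within a chromosome")
  }
  structure(list(line_id = line_id, state = state, records = records),
            class = "methylome_track")
}

#' @export
print.methylome_track <- function(x, ...) {
  cat(sprintf("<methylome_track> line=%s state=%s CpGs=%d\n",
              x$line_id, x$state, nrow(x$records)))
  invisible(x)
}

# beta-binomial methylation draw at true level mu
rbetabinom_meth <- function(n, cov, mu, rho) {
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  if (rho <= 0) {
    p <- mu
  } else {
    nu <- 1 / rho - 1
    p <- stats::rbeta(n, mu * nu, (1 - mu) * nu)
  }
  stats::rbinom(n, cov, p) / pmax(cov, 1)
}

#' Simulate methylomes for all lines and states with planted DMRs
#'
#' Background CpGs share a per-CpG baseline across every line and state
#' (island CpGs low, non-island CpGs high). Planted DMRs shift the
#' resistant level by +/- `dmr_delta` in every line; reverting DMRs return
#' the P12 level to parental, with the P5 level halfway (hence strictly
#' between resistant and P12); non-reverting DMRs keep the resistant level
#' in P5 and P12. Observed levels are beta-binomial draws at
#' `coverage_mean` unless `config$noiseless`.
#'
#' @param genome a [generate_genome()] result.
#' @param config the same [sim_config()].
#' @return list with `tracks` (named `"<line>_<state>"` list of
#'   `methylome_track`) and `truth` (data.frame of planted DMRs with true
#'   per-state levels and reverting flags).
#' @export
generate_methylomes <- function(genome, config) {
  stopifnot(inherits(genome, "genome_annotation"))
  set.seed(config$seed + 202L)
  cpg <- genome$cpg
  n <- nrow(cpg)
  if (n == 0) stop("genome has no CpGs")
  in_island <- overlaps_any(intervals(cpg$chrom, cpg$pos, cpg$pos + 1),
                            genome$islands)
  baseline <- numeric(n)
  baseline[in_island] <- stats::rbeta(sum(in_island), 1.5, 8)
  baseline[!in_island] <- stats::rbeta(sum(!in_island), 8, 1.5)

  # plant DMRs as runs of consecutive CpGs, non-overlapping with a gap of
  # at least one non-DMR CpG between runs
  used <- logical(n)  # includes the 1-CpG guard on each side
  idx_by_chrom <- split(seq_len(n), cpg$chrom)
  truth <- NULL
  if (config$n_planted_dmrs > 0) {
    rows <- vector("list", config$n_planted_dmrs)
    # exact composition: frac_hyper / frac_reverting are fractions of the
    # planted set, not per-DMR probabilities
    n_pl <- config$n_planted_dmrs
    hyper_flags <- rev_flags <- logical(n_pl)
    hyper_flags[sample(n_pl, round(config$frac_hyper * n_pl))] <- TRUE
    rev_flags[sample(n_pl, round(config$frac_reverting * n_pl))] <- TRUE
    for (d in seq_len(config$n_planted_dmrs)) {
      k <- sample(seq(config$dmr_cpg_range[1], config$dmr_cpg_range[2]), 1)
      ok <- FALSE
      for (att in 1:2000) {
        ii <- idx_by_chrom[[sample(length(idx_by_chrom), 1)]]
        if (length(ii) < k + 2) next
        s <- sample(length(ii) - k + 1, 1)
        run <- ii[s:(s + k - 1)]
        guard <- ii[max(1, s - 1):min(length(ii), s + k)]
        if (!any(used[guard])) {
          used[guard] <- TRUE
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place non-overlapping planted DMRs; ",
                    "reduce n_planted_dmrs or dmr_cpg_range")
      hyper <- hyper_flags[d]
      reverting <- rev_flags[d]
      if (hyper) {
        m_p <- stats::runif(1, 0.05, max(0.051, 0.95 - config$dmr_delta))
        m_r <- m_p + config$dmr_delta
      } else {
        m_p <- stats::runif(1, min(0.949, 0.05 + config$dmr_delta), 0.95)
        m_r <- m_p - config$dmr_delta
      }
      m_p12 <- if (reverting) m_p else m_r
      m_p5 <- (m_r + m_p12) / 2
      rows[[d]] <- data.frame(
        dmr_id = sprintf("planted%03d", d),
        chrom = cpg$chrom[run[1]],
        start = cpg$pos[run[1]],
        end = cpg$pos[run[k]] + 1,
        first_idx = run[1], last_idx = run[k], n_cpgs = k,
        direction = if (hyper) "hyper" else "hypo",
        reverting = reverting,
        m_parental = m_p, m_resistant = m_r, m_P5 = m_p5, m_P12 = m_p12,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  } else {
    truth <- data.frame(dmr_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        first_idx = integer(), last_idx = integer(),
                        n_cpgs = integer(), direction = character(),
                        reverting = logical(), m_parental = numeric(),
                        m_resistant = numeric(), m_P5 = numeric(),
                        m_P12 = numeric())
  }

  # true level matrix per state
  mu <- sapply(STATES, function(st) baseline, simplify = FALSE)
  if (nrow(truth) > 0) {
    for (d in seq_len(nrow(truth))) {
      run <- truth$first_idx[d]:truth$last_idx[d]
      mu$parental[run] <- truth$m_parental[d]
      mu$resistant[run] <- truth$m_resistant[d]
      mu$P5[run] <- truth$m_P5[d]
      mu$P12[run] <- truth$m_P12[d]
    }
  }

  lines <- paste0("line", seq_len(config$n_lines))
  tracks <- list()
  for (ln in lines) {
    for (st in STATES) {
      if (config$noiseless) {
        meth <- mu[[st]]
        cov <- rep(config$coverage_mean, n)
      } else {
        cov <- pmax(1, stats::rpois(n, config$coverage_mean))
        meth <- rbetabinom_meth(n, cov, mu[[st]], config$dispersion)
      }
      tracks[[paste0(ln, "_", st)]] <- new_methylome_track(
        ln, st, data.frame(chrom = cpg$chrom, pos = cpg$pos,
                           methylation = meth, coverage = cov,
                           stringsAsFactors = FALSE))
    }
  }
  list(tracks = tracks, truth = truth)
}

SNV_CLASSES <- {
  b <- c("A", "C", "G", "T")
  do.call(rbind, lapply(b, function(r)
    data.frame(ref = r, alt = setdiff(b, r), stringsAsFactors = FALSE)))
}

#' Simulate a variant table with a planted clonal structure
#'
#' VpR variants sit on one of `ploidy` haplotypes of the resistant clone
#' (true VAF `1/ploidy` in resistant and P12, 0 in parental); VpP variants
#' mirror that in the parental sample only; VpPR variants carry 1..ploidy
#' copies in every sample. Observed VAFs are binomial read draws at
#' `wgs_depth` (exact true values if `config$noiseless`). Substitution
#' types are drawn uniformly over the 12 SNV classes.
#'
#' @param genome a [generate_genome()] result.
#' @param config the same [sim_config()].
#' @return list with `variants` (data.frame with per-sample `vaf_*` and
#'   `cov_*` columns, `ref`, `alt`, and the true class in `class_true`)
#'   and `truth` (the planted class/copy table).
#' @export
generate_variants <- function(genome, config) {
  stopifnot(inherits(genome, "genome_annotation"))
  if (config$wgs_depth < 1) stop("wgs_depth must be >= 1")
  set.seed(config$seed + 303L)
  n_tot <- config$n_vpr + config$n_vpp + config$n_vppr
  if (n_tot == 0)
    return(list(variants = data.frame(), truth = data.frame()))
  chroms <- genome$chromosomes
  chrom <- sample(names(chroms), n_tot, replace = TRUE)
  pos <- floor(stats::runif(n_tot, 0, chroms[chrom]))
  cls <- SNV_CLASSES[sample(nrow(SNV_CLASSES), n_tot, replace = TRUE), ]
  class_true <- rep(c("VpR", "VpP", "VpPR"),
                    c(config$n_vpr, config$n_vpp, config$n_vppr))

  ploidy_of <- rep(config$ploidy, n_tot)
  if (!is.null(config$chrom_ploidy)) {
    hit <- chrom %in% names(config$chrom_ploidy)
    ploidy_of[hit] <- config$chrom_ploidy[chrom[hit]]
  }
  copies <- ifelse(class_true == "VpPR",
                   sample(seq_len(config$ploidy), n_tot, replace = TRUE), 1L)
  vaf_true <- pmin(1, copies / ploidy_of)
  truth <- data.frame(
    chrom = chrom, pos = pos, ref = cls$ref, alt = cls$alt,
    class_true = class_true, copies = copies,
    vaf_parental_true = ifelse(class_true == "VpR", 0, vaf_true),
    vaf_resistant_true = ifelse(class_true == "VpP", 0, vaf_true),
    vaf_P12_true = ifelse(class_true == "VpP", 0, vaf_true),
    stringsAsFactors = FALSE)

  draw <- function(true_vaf) {
    if (config$noiseless) {
      list(vaf = true_vaf, cov = rep(config$wgs_depth, n_tot))
    } else {
      cov <- rep(config$wgs_depth, n_tot)
      list(vaf = stats::rbinom(n_tot, cov, true_vaf) / cov, cov = cov)
    }
  }
  par <- draw(truth$vaf_parental_true)
  res <- draw(truth$vaf_resistant_true)
  p12 <- draw(truth$vaf_P12_true)
  variants <- data.frame(
    chrom = chrom, pos = pos, ref = cls$ref, alt = cls$alt,
    vaf_parental = par$vaf, vaf_resistant = res$vaf, vaf_P12 = p12$vaf,
    cov_parental = par$cov, cov_resistant = res$cov, cov_P12 = p12$cov,
    class_true = class_true, stringsAsFactors = FALSE)
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  truth <- truth[o, , drop = FALSE]
  rownames(variants) <- rownames(truth) <- NULL
  list(variants = variants, truth = truth)
}

#' Simulate feature tracks with controllable enrichment in planted DMRs
#'
#' Each track gets background features covering `feature_bg_coverage` of
#' the genome plus, for each planted DMR independently with probability
#' `min(1, feature_enrichment_factor * feature_bg_coverage)`, one feature
#' overlapping that DMR.
#'
#' @param genome a [generate_genome()] result (tracks are attached to its
#'   `feature_tracks` slot in the returned copy).
#' @param dmr_truth planted-DMR data.frame from [generate_methylomes()]
#'   (may be empty for a pure-background track).
#' @param config the same [sim_config()].
#' @param track_names names of tracks to simulate.
#' @return the genome with `feature_tracks` filled, plus attribute-free
#'   truth in `attr(, "feature_truth")` (data.frame dmr_id x track overlap
#'   flags).
#' @export
generate_features <- function(genome, dmr_truth, config,
                              track_names = c("tfbs", "atac", "h3k27ac")) {
  stopifnot(inherits(genome, "genome_annotation"))
  set.seed(config$seed + 404L)
  chroms <- genome$chromosomes
  genome_bp <- sum(chroms)
  p_dmr <- min(1, config$feature_enrichment_factor * config$feature_bg_coverage)
  truth_rows <- list()
  for (tn in track_names) {
    mean_len <- 600
    n_bg <- round(config$feature_bg_coverage * genome_bp / mean_len)
    chrom <- sample(names(chroms), n_bg, replace = TRUE)
    len <- round(stats::runif(n_bg, 200, 1000))
    start <- floor(stats::runif(n_bg, 0, chroms[chrom] - len))
    feats <- intervals(chrom, start, start + len)
    overlap_flag <- logical(nrow(dmr_truth))
    if (nrow(dmr_truth) > 0) {
      hit <- stats::runif(nrow(dmr_truth)) < p_dmr
      overlap_flag <- hit
      if (any(hit)) {
        d <- dmr_truth[hit, , drop = FALSE]
        mid <- floor((d$start + d$end) / 2)
        flen <- round(stats::runif(nrow(d), 200, 1000))
        fs <- pmax(0, mid - floor(flen / 2))
        fe <- pmin(unname(chroms[d$chrom]), fs + flen)
        feats <- rbind(feats, intervals(d$chrom, fs, fe))
      }
    }
    genome$feature_tracks[[tn]] <- merge_intervals(feats)
    truth_rows[[tn]] <- overlap_flag
  }
  ft <- data.frame(dmr_id = dmr_truth$dmr_id, truth_rows,
                   stringsAsFactors = FALSE)
  attr(genome, "feature_truth") <- ft
  genome
}

#' Simulate a gene-level log2 fold-change table
#'
#' Differentially expressed genes get `|log2FC(P, R)| >= 1.5`; among them,
#' reverting genes have `log2FC(P12, R)` tracking `log2FC(P, R)` while
#' non-reverting genes have `log2FC(P12, R)` near 0. Null genes have
#' `|log2FC| < 1` in both contrasts.
#'
#' @param config a [sim_config()]; uses `n_genes`, `expr_frac_de`,
#'   `frac_reverting` and `expr_noise_sd` (0 if `noiseless`).
#' @return data.frame with gene_id, log2fc_P_vs_R, log2fc_P12_vs_R and the
#'   planted label in `class_true` (`reverting`/`stable`/`null`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 505L)
  n <- config$n_genes
  sd <- if (config$noiseless) 0 else config$expr_noise_sd
  de <- stats::runif(n) < config$expr_frac_de
  rev <- de & (stats::runif(n) < config$frac_reverting)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  l1 <- ifelse(de, sign * stats::runif(n, 1.5, 4), stats::runif(n, -0.9, 0.9))
  l2 <- ifelse(rev, l1, ifelse(de, 0, l1))
  l1 <- l1 + stats::rnorm(n, 0, sd)
  l2 <- l2 + stats::rnorm(n, 0, sd)
  data.frame(gene_id = sprintf("gene%03d", seq_len(n)),
             log2fc_P_vs_R = l1, log2fc_P12_vs_R = l2,
             class_true = ifelse(rev, "reverting",
                                 ifelse(de, "stable", "null")),
             stringsAsFactors = FALSE)
}

# 3-parameter log-logistic viability (Hill slope 1)
hill3 <- function(dose, ic50, top, bottom) {
  bottom + (top - bottom) / (1 + dose / ic50)
}

#' Simulate single-drug dose-response data and a Loewe combination surface
#'
#' Single-agent viabilities follow the three-parameter log-logistic model
#' (Hill slope 1) at the configured IC50/top/bottom, plus Gaussian noise.
#' The combination surface is built under Loewe additivity plus the
#' planted `synergy_offset`, weighted smoothly toward saturating co-doses
#' so that single-agent margins are unperturbed.
#'
#' @param config a [sim_config()].
#' @param doses_a,doses_b dose grids (nM) for the two drugs; must be
#'   strictly increasing. Defaults span IC50/32 .. IC50*32.
#' @return list with `drug_a`, `drug_b` (data.frames dose/viability),
#'   `combo` (data.frame dose_a/dose_b/viability on the full grid
#'   including zero doses) and `truth` (the true parameters).
#' @export
generate_dose_response <- function(config,
                                   doses_a = config$ic50_true * 2^seq(-5, 5),
                                   doses_b = config$ic50_true_b * 2^seq(-5, 5)) {
  stopifnot(inherits(config, "sim_config"))
  if (is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE))
    stop("dose grids must be strictly increasing")
  set.seed(config$seed + 606L)
  sd <- if (config$noiseless) 0 else config$dr_noise_sd
  top <- config$hill_top; bot <- config$hill_bottom
  va <- hill3(doses_a, config$ic50_true, top, bot) + stats::rnorm(length(doses_a), 0, sd)
  vb <- hill3(doses_b, config$ic50_true_b, top, bot) + stats::rnorm(length(doses_b), 0, sd)
  ga <- c(0, doses_a); gb <- c(0, doses_b)
  grid <- expand.grid(dose_a = ga, dose_b = gb)
  s <- grid$dose_a / config$ic50_true + grid$dose_b / config$ic50_true_b
  loewe <- (bot * s + top) / (1 + s)
  w <- (grid$dose_a / (grid$dose_a + config$ic50_true)) *
       (grid$dose_b / (grid$dose_b + config$ic50_true_b))
  vio <- loewe + config$synergy_offset * w + stats::rnorm(nrow(grid), 0, sd)
  list(drug_a = data.frame(dose = doses_a, viability = va),
       drug_b = data.frame(dose = doses_b, viability = vb),
       combo = data.frame(dose_a = grid$dose_a, dose_b = grid$dose_b,
                          viability = vio),
       truth = list(ic50_a = config$ic50_true, ic50_b = config$ic50_true_b,
                    top = top, bottom = bot,
                    synergy_offset = config$synergy_offset))
}
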