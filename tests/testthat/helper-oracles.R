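# Independent brute-force oracles and small fixture builders shared by
# the test files. Oracles deliberately use naive loops so they share no
# code path with the package implementation.

make_track <- function(line_id, state, pos, meth, cov = 30, chrom = "chr1") {
  dmrevert:::new_methylome_track(
    line_id, state,
    data.frame(chrom = rep_len(chrom, length(pos)), pos = pos,
               methylation = meth,
               coverage = rep_len(cov, length(pos)),
               stringsAsFactors = FALSE))
}

# naive running median of a vector (independent of stats::runmed)
naive_runmed <- function(x, w) {
  h <- (w - 1) %/% 2
  vapply(seq_along(x), function(i)
    stats::median(x[max(1, i - h):min(length(x), i + h)]), 0)
}

# Exhaustive-scan DMR oracle for the default region_mean semantics on a
# single-chromosome input: candidate CpGs by naive median-smoothed
# difference, maximal same-sign runs found by scanning every position,
# then the n >= min_cpgs and per-line |mean raw diff| >= min_delta
# filters.
oracle_call_dmrs <- function(tracks, params) {
  lines <- unique(vapply(tracks, function(t) t$line_id, ""))
  get <- function(ln, st)
    tracks[[which(vapply(tracks, function(t)
      t$line_id == ln && t$state == st, TRUE))[1]]]$records
  pos <- get(lines[1], "parental")$pos
  raw_d <- sapply(lines, function(ln)
    get(ln, "resistant")$methylation - get(ln, "parental")$methylation)
  sm_d <- sapply(lines, function(ln)
    naive_runmed(get(ln, "resistant")$methylation, params$smoothing_window) -
      naive_runmed(get(ln, "parental")$methylation, params$smoothing_window))
  n <- length(pos)
  cand_sign <- integer(n)
  for (i in seq_len(n)) {
    s <- sign(sm_d[i, 1])
    if (s != 0 && all(sign(sm_d[i, ]) == s) &&
        all(abs(sm_d[i, ]) >= params$candidate_delta))
      cand_sign[i] <- s
  }
  out <- list()
  i <- 1
  while (i <= n) {
    if (cand_sign[i] == 0) { i <- i + 1; next }
    j <- i
    while (j < n && cand_sign[j + 1] == cand_sign[i]) j <- j + 1
    run <- i:j
    if (length(run) >= params$min_cpgs) {
      rm_line <- colMeans(raw_d[run, , drop = FALSE])
      if (all(abs(rm_line) >= params$min_delta) &&
          all(sign(rm_line) == cand_sign[i]))
        out[[length(out) + 1]] <- data.frame(
          start = pos[i], end = pos[j] + 1, n_cpgs = length(run),
          direction = if (cand_sign[i] > 0) "hyper" else "hypo",
          stringsAsFactors = FALSE)
    }
    i <- j + 1
  }
  if (length(out) == 0)
    return(data.frame(start = numeric(), end = numeric(),
                      n_cpgs = integer(), direction = character()))
  do.call(rbind, out)
}

# per-bp labeling oracle for the CpG-island context partition
oracle_cpg_labels <- function(islands, L, flank = 2000) {
  lab <- rep("ocean", L)
  for (i in seq_len(nrow(islands))) {
    s <- islands$start[i]; e <- islands$end[i]
    shelf <- intersect(seq(max(0, s - 2 * flank), min(L, e + 2 * flank) - 1),
                       0:(L - 1))
    lab[shelf + 1][lab[shelf + 1] == "ocean"] <- "shelf"
  }
  for (i in seq_len(nrow(islands))) {
    s <- islands$start[i]; e <- islands$end[i]
    shore <- seq(max(0, s - flank), min(L, e + flank) - 1)
    lab[shore + 1] <- "shore"
  }
  for (i in seq_len(nrow(islands)))
    lab[(islands$start[i] + 1):islands$end[i]] <- "island"
  lab
}

# per-bp labeling oracle for the gene context partition
oracle_gene_labels <- function(genes, exons, L) {
  lab <- rep("intergenic", L)
  for (i in seq_len(nrow(genes)))
    lab[(genes$start[i] + 1):genes$end[i]] <- "intron"
  for (i in seq_len(nrow(exons)))
    lab[(exons$start[i] + 1):exons$end[i]] <- "exon"
  lab
}

# truth-table oracle for VAF-trajectory classification
oracle_variant_class <- function(vp, vr, vpr_min = 0.1) {
  if (vp > 0 && vr == 0) return("VpP")
  if (vp == 0 && vr > vpr_min) return("VpR")
  if (vp > 0 && vr > 0) return("VpPR")
  "unclassified"
}

# quadratic all-pairs overlap oracle (half-open)
oracle_overlap_fraction <- function(regions, features) {
  hit <- vapply(seq_len(nrow(regions)), function(i) {
    any(vapply(seq_len(nrow(features)), function(j)
      regions$chrom[i] == features$chrom[j] &&
        regions$start[i] < features$end[j] &&
        features$start[j] < regions$end[i], TRUE))
  }, TRUE)
  mean(hit)
}

# match called DMRs against planted truth by interval overlap
dmr_precision_recall <- function(called, truth) {
  ov <- dmrevert:::overlaps_any
  truth_iv <- truth[, c("chrom", "start", "end")]
  called_iv <- called[, c("chrom", "start", "end")]
  list(precision = if (nrow(called) > 0)
         mean(ov(called_iv, merge_intervals(truth_iv))) else NaN,
       recall = if (nrow(truth) > 0)
         mean(ov(truth_iv, merge_intervals(called_iv))) else NaN)
}
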