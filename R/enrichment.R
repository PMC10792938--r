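# Monte-Carlo feature enrichment: each region of interest is repeatedly
# replaced by a random genomic region matched on length and CpG count,
# and the count of feature-overlapping regions is compared between the
# observed set and each random replicate set.

#' Enrichment-test parameters
#'
#' @param n_iterations number of random replicate region sets (the study
#'   used 1e6; the default is desk scale).
#' @param length_tolerance relative tolerance on the matched region's
#'   length.
#' @param cpg_tolerance tolerance on the matched region's CpG count: a
#'   value < 1 is a fraction of the template's count (minimum 1 CpG), a
#'   value >= 1 an absolute count.
#' @param seed RNG seed; results are deterministic given the seed.
#' @param significance_levels empirical significance levels tested, most
#'   lenient to strictest.
#' @param max_attempts rejection-sampling attempt budget per template and
#'   requested sample.
#' @return object of class `enrichment_params`.
#' @export
enrichment_params <- function(n_iterations = 1e4, length_tolerance = 0.1,
                              cpg_tolerance = 0.1, seed = 1L,
                              significance_levels = c(0.05, 0.01, 0.001),
                              max_attempts = 5000) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (length_tolerance < 0 || cpg_tolerance < 0)
    stop("tolerances must be >= 0")
  structure(list(n_iterations = as.integer(n_iterations),
                 length_tolerance = length_tolerance,
                 cpg_tolerance = cpg_tolerance, seed = as.integer(seed),
                 significance_levels = sort(significance_levels,
                                            decreasing = TRUE),
                 max_attempts = max_attempts),
            class = "enrichment_params")
}

# Precomputed CpG lookup: per-chromosome sorted positions plus lengths.
build_cpg_index <- function(genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  pos <- split(genome$cpg$pos, genome$cpg$chrom)
  list(chromosomes = genome$chromosomes,
       pos = lapply(pos, sort))
}

count_cpgs_in <- function(index, chrom, start, end) {
  p <- index$pos[[chrom]]
  if (is.null(p)) return(rep(0L, length(start)))
  findInterval(end - 1e-9, p) - findInterval(start - 1e-9, p)
}

#' Sample random regions matched on length and CpG count
#'
#' Rejection sampling: candidate regions are drawn uniformly over the
#' genome with lengths uniform within `length_tolerance` of the template,
#' and accepted when their CpG count is within `cpg_tolerance` of the
#' template's.
#'
#' @param template one-row interval data.frame (chrom, start, end).
#' @param index a [build_cpg_index()] result.
#' @param n number of matched regions to return.
#' @param params an [enrichment_params()].
#' @param target_cpgs CpG count to match; default: the template's count
#'   in `index`.
#' @return interval data.frame of `n` matched regions.
#' @export
sample_matched_regions <- function(template, index, n,
                                   params = enrichment_params(),
                                   target_cpgs = NULL) {
  len <- template$end - template$start
  target <- if (is.null(target_cpgs))
    count_cpgs_in(index, template$chrom, template$start, template$end)
  else target_cpgs
  tol <- if (params$cpg_tolerance < 1)
    max(1, ceiling(params$cpg_tolerance * target)) else params$cpg_tolerance
  chroms <- names(index$chromosomes)
  lmax <- ceiling(len * (1 + params$length_tolerance))
  wt <- pmax(0, unname(index$chromosomes) - lmax)
  if (sum(wt) <= 0) stop("genome too small for the template length")
  got_c <- character(0); got_s <- numeric(0); got_e <- numeric(0)
  attempts <- 0; budget <- params$max_attempts * n
  while (length(got_s) < n) {
    k <- min(max(2 * (n - length(got_s)), 1000), budget - attempts)
    if (k <= 0)
      stop(sprintf(
        "no length/CpG-matched placement found for template %s:%g-%g",
        template$chrom, template$start, template$end))
    attempts <- attempts + k
    cand_len <- round(stats::runif(k, len * (1 - params$length_tolerance),
                                   len * (1 + params$length_tolerance)))
    cand_len <- pmax(1, cand_len)
    ci <- sample.int(length(chroms), k, replace = TRUE, prob = wt)
    cand_chrom <- chroms[ci]
    cand_start <- floor(stats::runif(k) *
                          (unname(index$chromosomes)[ci] - cand_len))
    cand_end <- cand_start + cand_len
    for (chrom in unique(cand_chrom)) {
      sel <- which(cand_chrom == chrom)
      cnt <- count_cpgs_in(index, chrom, cand_start[sel], cand_end[sel])
      ok <- sel[abs(cnt - target) <= tol]
      if (length(ok) > 0) {
        got_c <- c(got_c, cand_chrom[ok])
        got_s <- c(got_s, cand_start[ok])
        got_e <- c(got_e, cand_end[ok])
      }
    }
  }
  intervals(got_c[1:n], got_s[1:n], got_e[1:n])
}

#' Monte-Carlo enrichment test of one feature track in a region set
#'
#' Per iteration, every region is replaced by one length/CpG-matched
#' random region and the number of regions overlapping the feature track
#' is recomputed. `exceed_fraction` is the fraction of iterations in
#' which the observed count strictly exceeds the random one; the feature
#' is significant at level l when `exceed_fraction >= 1 - l`, and the
#' strictest such level is reported.
#'
#' @param regions interval data.frame (>= 1 region).
#' @param features interval data.frame (merged internally).
#' @param genome a `genome_annotation` (for the CpG index), or a
#'   prebuilt [build_cpg_index()] result.
#' @param params an [enrichment_params()].
#' @return one-row data.frame: feature observed count, null mean,
#'   exceed_fraction, significance (`none` or the level).
#' @export
enrichment_test <- function(regions, features, genome,
                            params = enrichment_params()) {
  stopifnot(nrow(regions) >= 1)
  index <- if (inherits(genome, "genome_annotation"))
    build_cpg_index(genome) else genome
  set.seed(params$seed)
  feat <- if (nrow(features) > 0) merge_intervals(features) else features
  observed <- if (nrow(feat) > 0) sum(overlaps_any(regions, feat)) else 0L
  n_iter <- params$n_iterations
  # random counts accumulated region by region (matched sampling is
  # per-template, so the per-iteration replicate set is one matched
  # random region per original region)
  rand_counts <- integer(n_iter)
  for (i in seq_len(nrow(regions))) {
    samp <- sample_matched_regions(regions[i, , drop = FALSE], index,
                                   n_iter, params)
    if (nrow(feat) > 0)
      rand_counts <- rand_counts + overlaps_any(samp, feat)
  }
  exceed <- mean(observed > rand_counts)
  sig <- "none"
  for (l in params$significance_levels)  # lenient -> strict
    if (exceed >= 1 - l) sig <- as.character(l)
  data.frame(observed = observed, null_mean = mean(rand_counts),
             exceed_fraction = exceed, significance = sig,
             stringsAsFactors = FALSE)
}

#' Enrichment panel over several feature tracks
#'
#' Runs [enrichment_test()] per track with a per-track random stream
#' derived from the base seed and the track's rank in alphabetical
#' order, so results do not depend on the order tracks are supplied in.
#'
#' @param regions interval data.frame.
#' @param feature_tracks named list of interval data.frames.
#' @param genome a `genome_annotation` or [build_cpg_index()] result.
#' @param params an [enrichment_params()].
#' @return data.frame with one row per track (feature name first).
#' @export
enrichment_panel <- function(regions, feature_tracks, genome,
                             params = enrichment_params()) {
  nm <- names(feature_tracks)
  if (is.null(nm) || any(nm == "")) stop("feature tracks must be named")
  if (anyDuplicated(nm)) stop("duplicate feature track names")
  index <- if (inherits(genome, "genome_annotation"))
    build_cpg_index(genome) else genome
  ranks <- match(nm, sort(nm))
  res <- lapply(seq_along(feature_tracks), function(i) {
    p <- params
    p$seed <- params$seed + 1000L * ranks[i]
    cbind(data.frame(feature = nm[i], stringsAsFactors = FALSE),
          enrichment_test(regions, feature_tracks[[i]], index, p))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
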