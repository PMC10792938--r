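# VAF-trajectory variant classification, kernel-density clonality
# analysis against ploidy-expected modes, bisulfite-aware validation
# filtering and P12 persistence checks.

#' Clonality-analysis parameters
#'
#' @param vpr_min_vaf minimum resistant VAF for a variant absent in
#'   parental to be called VpR (default 0.1, strict >).
#' @param wgbs_min_coverage minimum coverage in the validating bisulfite
#'   sample (default 15, strict >).
#' @param kde_bandwidth Gaussian KDE bandwidth in VAF units; NULL =
#'   Silverman's rule clipped to \[0.01, 0.1\].
#' @param ploidy allele count used for expected clonal VAFs (default 4).
#' @param zero_epsilon VAFs <= this are treated as zero (default 0:
#'   caller output is trusted exactly).
#' @return object of class `clonality_params`.
#' @export
clonality_params <- function(vpr_min_vaf = 0.1, wgbs_min_coverage = 15,
                             kde_bandwidth = NULL, ploidy = 4L,
                             zero_epsilon = 0) {
  if (vpr_min_vaf <= 0 || vpr_min_vaf >= 1)
    stop("vpr_min_vaf must be in (0, 1)")
  if (ploidy < 1) stop("ploidy must be >= 1")
  structure(list(vpr_min_vaf = vpr_min_vaf,
                 wgbs_min_coverage = wgbs_min_coverage,
                 kde_bandwidth = kde_bandwidth, ploidy = as.integer(ploidy),
                 zero_epsilon = zero_epsilon),
            class = "clonality_params")
}

#' Classify variants by their parental-to-resistant VAF change
#'
#' VpP: present in parental, dropping to VAF 0 in resistant. VpR: VAF 0
#' in parental and strictly above `vpr_min_vaf` in resistant. VpPR: VAF
#' above 0 in both. Anything else (notably resistant-only variants at or
#' below the VpR threshold, or 0/0) is `unclassified`. Vectorized.
#'
#' @param vaf_parental,vaf_resistant VAFs in \[0, 1\].
#' @param params a [clonality_params()].
#' @return character vector in {VpP, VpR, VpPR, unclassified}.
#' @export
classify_variants <- function(vaf_parental, vaf_resistant,
                              params = clonality_params()) {
  stopifnot(all(vaf_parental >= 0 & vaf_parental <= 1),
            all(vaf_resistant >= 0 & vaf_resistant <= 1))
  eps <- params$zero_epsilon
  p0 <- vaf_parental <= eps
  r0 <- vaf_resistant <= eps
  ifelse(!p0 & r0, "VpP",
         ifelse(p0 & vaf_resistant > params$vpr_min_vaf, "VpR",
                ifelse(!p0 & !r0, "VpPR", "unclassified")))
}

#' Kernel density estimate of a VAF distribution with its modes
#'
#' Gaussian KDE evaluated on \[0, 1\]; modes are local maxima with height
#' at least 10% of the global maximum, returned sorted by height
#' (primary mode first).
#'
#' @param vafs >= 2 VAF values in \[0, 1\].
#' @param bandwidth Gaussian bandwidth; NULL = Silverman's rule clipped
#'   to \[0.01, 0.1\] and floored at the data's quantization step (VAFs
#'   from integer read counts are multiples of 1/depth; a bandwidth
#'   below that spacing resolves read-depth granularity as spurious
#'   modes).
#' @return list: `x`, `y` (density curve on \[0, 1\]), `modes`
#'   (data.frame vaf/density, by decreasing density), `bandwidth`.
#' @export
vaf_density <- function(vafs, bandwidth = NULL) {
  if (length(vafs) < 2) stop("need at least 2 VAF values")
  stopifnot(all(vafs >= 0 & vafs <= 1))
  if (is.null(bandwidth)) {
    bandwidth <- min(0.1, max(0.01, stats::bw.nrd0(vafs)))
    u <- sort(unique(vafs))
    if (length(u) > 1)
      bandwidth <- max(bandwidth, min(min(diff(u)), 0.1))
  }
  d <- stats::density(vafs, bw = bandwidth, from = 0, to = 1, n = 512)
  y <- d$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  # plateau/edge handling: global maximum always counts
  is_max[which.max(y)] <- TRUE
  keep <- is_max & y >= 0.1 * max(y)
  modes <- data.frame(vaf = d$x[keep], density = y[keep])
  modes <- modes[order(-modes$density), , drop = FALSE]
  rownames(modes) <- NULL
  list(x = d$x, y = y, modes = modes, bandwidth = bandwidth)
}

#' Expected clonal VAF for a given ploidy, copy number and purity
#'
#' A clonal variant on `variant_copies` of `ploidy` tumour alleles in a
#' sample of purity `purity` (the non-tumour fraction is diploid
#' reference) has expected VAF
#' `purity * variant_copies / (purity * ploidy + (1 - purity) * 2)`.
#'
#' @param ploidy tumour allele count (>= 1).
#' @param variant_copies copies carrying the variant (1..ploidy).
#' @param purity tumour cell fraction in (0, 1].
#' @return expected VAF.
#' @export
expected_clonal_vaf <- function(ploidy, variant_copies = 1, purity = 1) {
  if (ploidy < 1) stop("ploidy must be >= 1")
  if (variant_copies < 1 || variant_copies > ploidy)
    stop("variant_copies must be in 1..ploidy")
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  purity * variant_copies / (purity * ploidy + (1 - purity) * 2)
}

#' Per-chromosome VAF summary with primary KDE mode
#'
#' Chromosome arms lost or gained relative to the genome-wide ploidy
#' shift the local clonal VAF mode away from `1/ploidy`; this summary
#' surfaces that per chromosome.
#'
#' @param variants data.frame with `chrom` and a VAF column.
#' @param vaf_column which VAF column to summarize.
#' @param params a [clonality_params()] (bandwidth).
#' @param min_variants chromosomes with fewer variants are flagged
#'   `low_support` (default 10).
#' @return data.frame: chrom, n, primary_mode (NA when n < 2),
#'   mean_vaf, low_support.
#' @export
per_chromosome_vaf <- function(variants, vaf_column = "vaf_resistant",
                               params = clonality_params(),
                               min_variants = 10L) {
  stopifnot(vaf_column %in% names(variants))
  out <- lapply(split(variants, variants$chrom), function(d) {
    v <- d[[vaf_column]]
    mode <- if (length(v) >= 2)
      vaf_density(v, params$kde_bandwidth)$modes$vaf[1] else NA_real_
    data.frame(chrom = d$chrom[1], n = nrow(d), primary_mode = mode,
               mean_vaf = mean(v), low_support = nrow(d) < min_variants,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom), , drop = FALSE]
}

#' Bisulfite-aware validation filter
#'
#' Bisulfite conversion makes C>T (and G>A) changes unreadable, so only
#' A>T and T>A substitutions are interpretable in bisulfite reads; in
#' addition the validating sample must be covered strictly above
#' `wgbs_min_coverage`.
#'
#' @param variants data.frame with ref, alt and a coverage column for the
#'   validating sample.
#' @param params a [clonality_params()].
#' @param coverage_column coverage in the validating bisulfite sample.
#' @return the qualifying subset of `variants`.
#' @export
wgbs_validation_filter <- function(variants, params = clonality_params(),
                                   coverage_column = "cov_P12") {
  stopifnot(all(c("ref", "alt", coverage_column) %in% names(variants)))
  keep <- ((variants$ref == "A" & variants$alt == "T") |
           (variants$ref == "T" & variants$alt == "A")) &
    variants[[coverage_column]] > params$wgbs_min_coverage
  variants[keep, , drop = FALSE]
}

#' Persistence of the resistant genotype in P12 cells
#'
#' Checks whether VpRs remain present (VAF > 0) and VpPs remain absent
#' (VAF = 0) after drug withdrawal, i.e. whether the resistant clone, not
#' a surviving parental subpopulation, repopulated the culture.
#'
#' @param vprs,vpps data.frames of VpR / VpP variants (pass them through
#'   [wgbs_validation_filter()] first) with a P12 VAF column.
#' @param vaf_column P12 VAF column name.
#' @return list: `vpr_present_fraction`, `vpp_absent_fraction`,
#'   `n_missing` (variants without a P12 measurement, excluded), and the
#'   per-variant tables with a `present_P12` flag.
#' @export
persistence_check <- function(vprs, vpps, vaf_column = "vaf_P12") {
  split_missing <- function(d) {
    if (nrow(d) == 0)
      return(list(ok = d, missing = d))
    miss <- is.na(d[[vaf_column]])
    list(ok = d[!miss, , drop = FALSE], missing = d[miss, , drop = FALSE])
  }
  r <- split_missing(vprs); p <- split_missing(vpps)
  r$ok$present_P12 <- if (nrow(r$ok)) r$ok[[vaf_column]] > 0 else logical(0)
  p$ok$present_P12 <- if (nrow(p$ok)) p$ok[[vaf_column]] > 0 else logical(0)
  list(vpr_present_fraction = if (nrow(r$ok)) mean(r$ok$present_P12) else NaN,
       vpp_absent_fraction = if (nrow(p$ok)) mean(!p$ok$present_P12) else NaN,
       n_missing = nrow(r$missing) + nrow(p$missing),
       vprs = r$ok, vpps = p$ok)
}
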