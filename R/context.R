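# Genomic-context annotation: CpG island/shore/shelf/ocean and
# exon/intron/intergenic composition at bp resolution, chi-square
# comparison against a background genome, nearest flanking genes by TSS,
# expression-change labels and simple feature-overlap fractions.

#' Partition a genome into CpG island / shore / shelf / ocean
#'
#' Shores are regions up to `flank` bp away from a CpG island, shelves up
#' to `flank` bp away from a shore, and the ocean is everything else.
#' Precedence island > shore > shelf resolves overlaps, so the four sets
#' partition every chromosome exactly.
#'
#' @param islands interval data.frame of CpG islands (merged or not).
#' @param chromosomes named vector of chromosome lengths (bp).
#' @param flank shore/shelf width in bp (default 2000).
#' @return named list of interval data.frames: island, shore, shelf,
#'   ocean.
#' @export
build_cpg_context <- function(islands, chromosomes, flank = 2000) {
  islands <- merge_intervals(islands)
  if (nrow(islands) > 0) {
    bad <- !(islands$chrom %in% names(chromosomes)) |
      islands$end > chromosomes[islands$chrom] | islands$start < 0
    if (any(bad))
      stop(sprintf("island out of chromosome bounds: %s:%d-%d",
                   islands$chrom[bad][1], islands$start[bad][1],
                   islands$end[bad][1]))
  }
  whole <- intervals(names(chromosomes), 0, unname(chromosomes))
  shore_zone <- merge_intervals(expand_intervals(islands, flank, chromosomes))
  shore <- subtract_intervals(shore_zone, islands)
  shelf_zone <- merge_intervals(expand_intervals(shore_zone, flank, chromosomes))
  shelf <- subtract_intervals(shelf_zone, shore_zone)
  ocean <- subtract_intervals(whole, shelf_zone)
  list(island = islands, shore = shore, shelf = shelf, ocean = ocean)
}

#' Partition a genome into exon / intron / intergenic
#'
#' Exons take precedence over introns where transcripts overlap; introns
#' are gene spans minus exons; intergenic is the rest.
#'
#' @param genes data.frame with chrom, start, end (gene spans).
#' @param exons interval data.frame of exons.
#' @param chromosomes named vector of chromosome lengths.
#' @return named list of interval data.frames: exon, intron, intergenic.
#' @export
build_gene_context <- function(genes, exons, chromosomes) {
  whole <- intervals(names(chromosomes), 0, unname(chromosomes))
  if (nrow(genes) == 0)
    return(list(exon = intervals(), intron = intervals(), intergenic = whole))
  gene_iv <- merge_intervals(intervals(genes$chrom, genes$start, genes$end))
  exon_iv <- if (nrow(exons) > 0)
    merge_intervals(intervals(exons$chrom, exons$start, exons$end))
  else intervals()
  intron <- subtract_intervals(gene_iv, exon_iv)
  intergenic <- subtract_intervals(whole, gene_iv)
  list(exon = exon_iv, intron = intron, intergenic = intergenic)
}

#' bp composition of regions over a context partition
#'
#' @param regions interval data.frame.
#' @param partition named list of interval sets (e.g. from
#'   [build_cpg_context()] or [build_gene_context()]).
#' @return data.frame: category, bp, fraction (fractions sum to 1 when
#'   the partition covers the regions).
#' @export
annotate_region_context <- function(regions, partition) {
  bp <- vapply(partition, function(iv)
    interval_bp(intersect_intervals(regions, iv)), 0)
  total <- sum(bp)
  data.frame(category = names(partition), bp = unname(bp),
             fraction = if (total > 0) unname(bp) / total
                        else rep(NA_real_, length(bp)),
             stringsAsFactors = FALSE)
}

#' Chi-square test of a bp composition against background fractions
#'
#' Pearson chi-square of the observed bp counts against expected counts
#' derived from the background composition's fractions; degrees of
#' freedom = categories - 1.
#'
#' @param observed data.frame from [annotate_region_context()] (bp counts
#'   used).
#' @param background data.frame with matching categories (fractions
#'   used), e.g. the whole-genome composition.
#' @return list: statistic, p_value, df.
#' @export
composition_chisq <- function(observed, background) {
  m <- match(observed$category, background$category)
  if (any(is.na(m))) stop("background is missing observed categories")
  o <- observed$bp
  p <- background$fraction[m]
  keep <- o > 0 | p > 0
  o <- o[keep]; p <- p[keep]
  if (sum(o) == 0) stop("all observed counts are zero")
  if (any(p <= 0 & o > 0))
    stop("background fraction is zero for an observed category")
  p <- p / sum(p)
  expected <- sum(o) * p
  stat <- sum((o - expected)^2 / expected)
  df <- length(o) - 1
  list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df)
}

#' Nearest flanking genes of a region by TSS
#'
#' Returns the nearest TSS on each side of the region; a TSS inside the
#' region has distance 0 (reported in the `inside` slot side). Ties are
#' broken by lower coordinate, then lexicographic gene id.
#'
#' @param region one-row interval data.frame (chrom, start, end).
#' @param genes data.frame with id, chrom, tss.
#' @return two-row data.frame (side `left`/`right`): gene id, tss, and
#'   distance in bp from the nearest region edge (0 if the TSS lies
#'   inside the region). A side with no gene on the chromosome carries NA
#'   gene id and distance with `empty = TRUE`.
#' @export
nearest_flanking_genes <- function(region, genes) {
  g <- genes[genes$chrom == region$chrom, , drop = FALSE]
  na_row <- function(side)
    data.frame(side = side, gene_id = NA_character_, tss = NA_real_,
               distance = NA_real_, empty = TRUE, stringsAsFactors = FALSE)
  mk <- function(side, gg, dist)
    data.frame(side = side, gene_id = gg$id, tss = gg$tss, distance = dist,
               empty = FALSE, stringsAsFactors = FALSE)
  if (nrow(g) == 0) {
    res <- rbind(na_row("left"), na_row("right"))
    rownames(res) <- NULL
    return(res)
  }
  g <- g[order(g$tss, g$id), , drop = FALSE]
  inside <- g[g$tss >= region$start & g$tss < region$end, , drop = FALSE]
  left <- g[g$tss < region$start, , drop = FALSE]
  right <- g[g$tss >= region$end, , drop = FALSE]
  lrow <- if (nrow(inside) > 0) mk("left", inside[1, ], 0)
          else if (nrow(left) > 0) {
            # nearest = max tss; ties broken by lexicographic id (rows
            # are sorted by tss then id, so the first of the max group)
            cand <- left[left$tss == left$tss[nrow(left)], , drop = FALSE]
            mk("left", cand[1, ], region$start - cand$tss[1])
          } else na_row("left")
  rrow <- if (nrow(inside) > 1) mk("right", inside[2, ], 0)
          else if (nrow(right) > 0)
            mk("right", right[1, ], right$tss[1] - (region$end - 1))
          else na_row("right")
  res <- rbind(lrow, rrow)
  rownames(res) <- NULL
  res
}

#' Label an expression change
#'
#' @param log2fc finite log2 fold change (resistant vs parental in the
#'   study convention).
#' @param threshold absolute log2FC above which a gene is called up/down
#'   (default 1; strict inequality).
#' @return `"up"`, `"down"` or `"neutral"` (vectorized).
#' @export
label_expression_change <- function(log2fc, threshold = 1) {
  stopifnot(all(is.finite(log2fc)))
  ifelse(log2fc > threshold, "up",
         ifelse(log2fc < -threshold, "down", "neutral"))
}

#' Fraction of regions overlapping a feature track
#'
#' A region counts once no matter how many feature intervals it touches;
#' half-open semantics (a shared endpoint is not an overlap).
#'
#' @param regions interval data.frame.
#' @param features interval data.frame (merged internally).
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(regions, features) {
  if (nrow(regions) == 0) return(NaN)
  if (nrow(features) == 0) return(0)
  mean(overlaps_any(regions, merge_intervals(features)))
}
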