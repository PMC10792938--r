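# Interval utilities. All genomic intervals in this package are 0-based
# half-open [start, end) data.frames with columns chrom, start, end.
# IRanges (1-based closed) is used internally for set operations; the
# +1/-0 conversion is confined to these helpers.

#' Construct an interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, `end > start`.
#' @return data.frame with columns chrom, start, end.
#' @export
intervals <- function(chrom = character(), start = integer(), end = integer()) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0 && any(df$end <= df$start))
    stop("interval end must be greater than start (0-based half-open)")
  df
}

as_iranges0 <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

from_iranges0 <- function(ir, chrom) {
  intervals(chrom = rep(chrom, length(ir)),
            start = IRanges::start(ir) - 1L,
            end = IRanges::end(ir))
}

#' Sort and merge an interval table
#'
#' Overlapping and bookended intervals are merged (BED `merge` semantics).
#'
#' @param df interval data.frame.
#' @return merged, sorted interval data.frame.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(intervals())
  out <- lapply(split(df, df$chrom), function(d) {
    ir <- IRanges::reduce(as_iranges0(d))
    from_iranges0(ir, d$chrom[1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Per-chromosome set subtraction: a \ b, both interval tables.
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0) return(intervals())
  out <- lapply(split(a, a$chrom), function(d) {
    chrom <- d$chrom[1]
    bsub <- b[b$chrom == chrom, , drop = FALSE]
    if (nrow(bsub) == 0) return(d[, c("chrom", "start", "end")])
    ir <- IRanges::setdiff(as_iranges0(d), as_iranges0(bsub))
    from_iranges0(ir, chrom)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Per-chromosome intersection of two interval tables.
intersect_intervals <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0) return(intervals())
  out <- lapply(chroms, function(chrom) {
    ir <- IRanges::intersect(
      as_iranges0(a[a$chrom == chrom, , drop = FALSE]),
      as_iranges0(b[b$chrom == chrom, , drop = FALSE]))
    from_iranges0(ir, chrom)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$start), , drop = FALSE]
}

# Total bp covered by an interval table (assumed merged).
interval_bp <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(df$end - df$start)
}

# Widen each interval by `flank` bp on both sides, clipped to chromosome
# bounds. `chromosomes` is a named vector of lengths.
expand_intervals <- function(df, flank, chromosomes) {
  if (nrow(df) == 0) return(df)
  df$start <- pmax(0, df$start - flank)
  df$end <- pmin(unname(chromosomes[df$chrom]), df$end + flank)
  df
}

# Does each query interval overlap >= 1 subject interval?  Half-open
# semantics: a shared endpoint is not an overlap.  Subject must be merged
# and sorted; queries may be in any order.  Vectorized via findInterval,
# O((n+m) log m); used in the enrichment Monte-Carlo hot loop.
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  hit <- logical(nrow(query))
  if (nrow(subject) == 0) return(hit)
  for (chrom in unique(query$chrom)) {
    qi <- which(query$chrom == chrom)
    ssub <- subject[subject$chrom == chrom, , drop = FALSE]
    if (nrow(ssub) == 0) next
    # features with start < q.end: index j = count of subject starts <= q.end - 1.
    # Merged+sorted => subject ends increasing, so overlap iff end[j] > q.start.
    j <- findInterval(query$end[qi] - 1e-9, ssub$start)
    ok <- j >= 1
    ok[ok] <- ssub$end[j[ok]] > query$start[qi][ok]
    hit[qi] <- ok
  }
  hit
}
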