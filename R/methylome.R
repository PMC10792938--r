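# DMR detection: smoothing of per-CpG methylation, calling of regions
# differential in BOTH cell lines, summaries, amplicon validation and
# methylation metaprofiles.

#' DMR calling parameters
#'
#' @param min_cpgs minimum consecutive qualifying CpGs per DMR (default 4).
#' @param min_delta minimum methylation difference resistant - parental
#'   (default 0.4).
#' @param smoothing_window CpG-count window of the smoother used for
#'   candidate detection (odd; 1 = no smoothing; default 5).
#' @param candidate_delta in `region_mean` mode, the per-CpG cut on the
#'   median-smoothed difference that defines candidate CpGs before the
#'   region-mean filter (default 0.2). Kept independent of `min_delta` so
#'   that relaxing `min_delta` never re-segments candidate runs.
#' @param min_coverage CpGs below this coverage in any contributing track
#'   are dropped before smoothing (default 1).
#' @param delta_mode `"region_mean"` (default) mirrors the standard
#'   bsseq-style workflow: candidate runs of CpGs whose edge-preserving
#'   median-smoothed difference clears `candidate_delta` with a
#'   consistent sign in every line, then filtered by `min_cpgs` and a
#'   per-line region mean raw difference of at least `min_delta`.
#'   `"per_cpg"` instead requires the running-mean smoothed difference to
#'   clear `min_delta` at every single CpG of the run.
#' @return object of class `dmr_call_params`.
#' @export
dmr_call_params <- function(min_cpgs = 4L, min_delta = 0.4,
                            smoothing_window = 5L, candidate_delta = 0.2,
                            min_coverage = 1,
                            delta_mode = c("region_mean", "per_cpg")) {
  if (min_cpgs < 1) stop("min_cpgs must be >= 1")
  if (min_delta <= 0 || min_delta > 1) stop("min_delta must be in (0, 1]")
  if (candidate_delta <= 0 || candidate_delta > 1)
    stop("candidate_delta must be in (0, 1]")
  if (smoothing_window < 1 || smoothing_window %% 2 == 0)
    stop("smoothing_window must be odd and >= 1")
  structure(list(min_cpgs = as.integer(min_cpgs), min_delta = min_delta,
                 smoothing_window = as.integer(smoothing_window),
                 candidate_delta = candidate_delta,
                 min_coverage = min_coverage,
                 delta_mode = match.arg(delta_mode)),
            class = "dmr_call_params")
}

# running-median smoothing of methylation levels (edge-preserving: a CpG
# whose window majority lies inside a shifted region keeps the full
# shift, unlike a running mean which attenuates region edges). Windows
# are symmetric in CpG count and truncated at chromosome ends.
median_smooth_track <- function(track, window) {
  rec <- track$records
  if (nrow(rec) == 0 || window == 1) return(track)
  h <- (window - 1L) %/% 2L
  for (chrom in unique(rec$chrom)) {
    ii <- which(rec$chrom == chrom)
    x <- rec$methylation[ii]
    n <- length(x)
    if (n >= window) {
      out <- stats::runmed(x, window, endrule = "keep")
      edge <- c(seq_len(h), (n - h + 1):n)
    } else {
      out <- x
      edge <- seq_len(n)
    }
    for (i in edge)
      out[i] <- stats::median(x[max(1, i - h):min(n, i + h)])
    rec$methylation[ii] <- out
  }
  new_methylome_track(track$line_id, track$state, rec)
}

#' Smooth a methylome track with a coverage-weighted running mean
#'
#' Each CpG's level is replaced by the coverage-weighted mean over a
#' window of `window` neighbouring CpGs (by CpG count, not bp) on the same
#' chromosome; windows are truncated at chromosome ends. `window = 1`
#' returns the input unchanged. This is a light-weight stand-in for
#' local-likelihood smoothers: the downstream DMR criterion is purely
#' threshold-based, so only local averaging matters here.
#'
#' @param track a `methylome_track`.
#' @param window odd CpG-count window size.
#' @return a `methylome_track` with smoothed levels (coverage unchanged).
#' @export
smooth_methylation <- function(track, window = 5L) {
  stopifnot(inherits(track, "methylome_track"))
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  rec <- track$records
  if (nrow(rec) == 0 || window == 1) return(track)
  h <- (window - 1L) %/% 2L
  sm <- unlist(lapply(split(seq_len(nrow(rec)), rec$chrom), function(ii) {
    m <- rec$methylation[ii]; cv <- rec$coverage[ii]
    n <- length(ii)
    cw <- c(0, cumsum(m * cv)); cc <- c(0, cumsum(cv))
    cn <- c(0, cumsum(m))
    lo <- pmax(1L, seq_len(n) - h); hi <- pmin(n, seq_len(n) + h)
    num <- cw[hi + 1] - cw[lo]; den <- cc[hi + 1] - cc[lo]
    out <- ifelse(den > 0, num / den,
                  (cn[hi + 1] - cn[lo]) / (hi - lo + 1))
    out
  }))
  # split() orders chromosomes alphabetically; records are sorted the same
  rec$methylation <- pmin(1, pmax(0, sm))
  new_methylome_track(track$line_id, track$state, rec)
}

# inner-join the CpG universes of a list of tracks; returns list(key df,
# matrix of methylation, matrix of coverage) with one column per track
join_tracks <- function(tracks) {
  keys <- lapply(tracks, function(t) paste(t$records$chrom, t$records$pos))
  common <- Reduce(intersect, keys)
  ref <- tracks[[1]]$records
  sel <- match(common, keys[[1]])
  key <- ref[sel, c("chrom", "pos")]
  o <- order(key$chrom, key$pos)
  key <- key[o, , drop = FALSE]
  meth <- sapply(seq_along(tracks), function(i) {
    idx <- match(paste(key$chrom, key$pos), keys[[i]])
    tracks[[i]]$records$methylation[idx]
  })
  cov <- sapply(seq_along(tracks), function(i) {
    idx <- match(paste(key$chrom, key$pos), keys[[i]])
    tracks[[i]]$records$coverage[idx]
  })
  if (length(common) == 1) { meth <- matrix(meth, 1); cov <- matrix(cov, 1) }
  colnames(meth) <- colnames(cov) <- names(tracks)
  rownames(key) <- NULL
  list(key = key, meth = meth, cov = cov)
}

#' Call DMRs common to all cell lines
#'
#' Finds maximal runs of consecutive CpGs whose smoothed methylation
#' difference resistant - parental has the same sign in EVERY
#' contributing line, and keeps runs with at least `min_cpgs` CpGs and a
#' methylation difference of at least `min_delta` in every line.
#' Direction (`hyper`/`hypo` in resistant) must agree across lines. In
#' the default `region_mean` mode, candidate CpGs are those whose
#' edge-preserving median-smoothed difference clears `candidate_delta`
#' in all lines, and `min_delta` applies to the per-line region mean of
#' the raw levels (the bsseq-style `n & meanDiff` filter); in `per_cpg`
#' mode the running-mean smoothed difference must clear `min_delta` at
#' every CpG. Tracks for additional states (P5, P12) may be supplied;
#' their per-line DMR means are attached for downstream reversion
#' scoring.
#'
#' @param tracks named list of `methylome_track`s covering states
#'   `parental` and `resistant` for at least one line (two in the study
#'   design); P5/P12 tracks optional.
#' @param params a [dmr_call_params()].
#' @return data.frame of DMRs (chrom, start, end: 0-based half-open,
#'   n_cpgs, length, direction) with one `mean_<line>_<state>` column per
#'   input track, sorted and non-overlapping.
#' @export
call_dmrs <- function(tracks, params = dmr_call_params()) {
  stopifnot(is.list(tracks), length(tracks) > 0)
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, function(t)
      paste0(t$line_id, "_", t$state), "")
  lines <- unique(vapply(tracks, function(t) t$line_id, ""))
  states_of <- function(ln)
    vapply(Filter(function(t) t$line_id == ln, tracks),
           function(t) t$state, "")
  calling_lines <- lines[vapply(lines, function(ln)
    all(c("parental", "resistant") %in% states_of(ln)), TRUE)]
  if (length(calling_lines) == 0)
    stop("need parental and resistant tracks for at least one line")

  # chromosome sets must agree across all tracks
  chrom_sets <- lapply(tracks, function(t) unique(t$records$chrom))
  all_chroms <- Reduce(union, chrom_sets)
  for (i in seq_along(tracks)) {
    missing <- setdiff(all_chroms, chrom_sets[[i]])
    if (length(missing) > 0)
      stop(sprintf("track %s is missing chromosome(s): %s",
                   names(tracks)[i], paste(missing, collapse = ", ")))
  }

  # coverage filter, then smoothing
  filt <- lapply(tracks, function(t) {
    rec <- t$records[t$records$coverage >= params$min_coverage, , drop = FALSE]
    new_methylome_track(t$line_id, t$state, rec)
  })
  sm <- if (params$delta_mode == "per_cpg")
    lapply(filt, smooth_methylation, window = params$smoothing_window)
  else
    lapply(filt, median_smooth_track, window = params$smoothing_window)
  j <- join_tracks(sm)
  raw <- join_tracks(filt)  # same key order: both sorted joins of same sets
  n <- nrow(j$key)
  find <- function(ln, st) {
    hit <- which(vapply(tracks, function(t)
      t$line_id == ln && t$state == st, TRUE))
    names(tracks)[hit[1]]
  }
  dmr_cols <- function(run) {
    means <- lapply(names(tracks), function(nm)
      mean(raw$meth[run, nm]))
    names(means) <- paste0(
      "mean_", vapply(tracks, function(t) t$line_id, ""), "_",
      vapply(tracks, function(t) t$state, ""))
    means
  }

  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_cpgs = integer(),
                      length = numeric(), direction = character())
  if (n == 0) return(empty)

  diffs <- sapply(calling_lines, function(ln)
    j$meth[, find(ln, "resistant")] - j$meth[, find(ln, "parental")])
  if (n == 1) diffs <- matrix(diffs, 1, dimnames = list(NULL, calling_lines))

  sgn <- sign(diffs[, 1])
  agree <- rowSums(sign(diffs) == sgn) == ncol(diffs) & sgn != 0
  cut <- if (params$delta_mode == "per_cpg") params$min_delta
         else params$candidate_delta
  qual <- agree & rowSums(abs(diffs) >= cut) == ncol(diffs)
  code <- ifelse(qual, sgn, 0)

  # raw (unsmoothed) per-line differences for the region-mean filter
  raw_diffs <- sapply(calling_lines, function(ln)
    raw$meth[, find(ln, "resistant")] - raw$meth[, find(ln, "parental")])
  if (n == 1) raw_diffs <- matrix(raw_diffs, 1)

  out <- list()
  for (chrom in unique(j$key$chrom)) {
    ci <- which(j$key$chrom == chrom)
    r <- rle(code[ci])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0 || r$lengths[k] < params$min_cpgs) next
      run <- ci[starts[k]:ends[k]]
      if (params$delta_mode == "region_mean") {
        rm_line <- colMeans(raw_diffs[run, , drop = FALSE])
        mean_ok <- all(abs(rm_line) >= params$min_delta) &&
          all(sign(rm_line) == r$values[k])
        if (!mean_ok) next
      }
      pos <- j$key$pos[run]
      row <- data.frame(chrom = chrom, start = pos[1],
                        end = pos[length(pos)] + 1,
                        n_cpgs = length(run),
                        length = pos[length(pos)] + 1 - pos[1],
                        direction = if (r$values[k] > 0) "hyper" else "hypo",
                        stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- cbind(row, dmr_cols(run))
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize a DMR set
#'
#' @param dmrs data.frame from [call_dmrs()].
#' @return one-row data.frame: count, hyper_fraction, mean/min/max CpG
#'   count and length, and an `empty` flag.
#' @export
summarize_dmrs <- function(dmrs) {
  if (nrow(dmrs) == 0)
    return(data.frame(n = 0L, hyper_fraction = 0, mean_cpgs = 0,
                      min_cpgs = 0L, max_cpgs = 0L, mean_length = 0,
                      min_length = 0, max_length = 0, empty = TRUE))
  data.frame(n = nrow(dmrs),
             hyper_fraction = mean(dmrs$direction == "hyper"),
             mean_cpgs = mean(dmrs$n_cpgs),
             min_cpgs = min(dmrs$n_cpgs),
             max_cpgs = max(dmrs$n_cpgs),
             mean_length = mean(dmrs$length),
             min_length = min(dmrs$length),
             max_length = max(dmrs$length),
             empty = FALSE)
}

#' Validate a DMR by targeted amplicon bisulfite sequencing means
#'
#' Deep amplicon sequencing gives much higher coverage than WGBS, so a
#' relaxed minimum methylation difference of 0.2 is applied; optionally
#' the sign must match the WGBS call direction.
#'
#' @param mean_parental,mean_resistant amplicon-level mean methylation.
#' @param min_diff minimum absolute difference (default 0.2).
#' @param wgbs_direction optional `"hyper"`/`"hypo"` from the WGBS DMR; if
#'   given, the amplicon difference must have the matching sign.
#' @return TRUE iff the amplicon validates the DMR.
#' @export
validate_amplicon <- function(mean_parental, mean_resistant,
                              min_diff = 0.2, wgbs_direction = NULL) {
  stopifnot(mean_parental >= 0, mean_parental <= 1,
            mean_resistant >= 0, mean_resistant <= 1)
  d <- mean_resistant - mean_parental
  ok <- abs(d) >= min_diff - 1e-9  # guard against FP representation
  if (!is.null(wgbs_direction))
    ok <- ok && ((wgbs_direction == "hyper" && d > 0) ||
                 (wgbs_direction == "hypo" && d < 0))
  ok
}

#' Methylation metaprofile over a region set
#'
#' Region bodies are rescaled to `body_bins` bins; flanks extend `flank`
#' bp in absolute coordinates on each side, split into `flank_bins` bins
#' (truncated at chromosome starts). Returns the per-bin mean methylation
#' over all regions, ignoring bins that contain no CpGs.
#'
#' @param regions interval data.frame (chrom, start, end).
#' @param track a `methylome_track`.
#' @param flank flank width in bp (default 2000).
#' @param body_bins,flank_bins bin counts for body and each flank.
#' @return data.frame: bin index, section (`upstream`/`body`/
#'   `downstream`), mean methylation (NaN where no region contributed a
#'   CpG) and total contributing CpG count.
#' @export
metaprofile <- function(regions, track, flank = 2000,
                        body_bins = 10L, flank_bins = 5L) {
  stopifnot(inherits(track, "methylome_track"),
            body_bins >= 1, flank_bins >= 1)
  rec <- track$records
  nb <- 2L * flank_bins + body_bins
  sums <- numeric(nb); counts <- integer(nb)
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]; s <- regions$start[i]; e <- regions$end[i]
    p <- rec$pos[rec$chrom == chrom]
    m <- rec$methylation[rec$chrom == chrom]
    # upstream flank (absolute bp), truncated at 0
    edges_up <- s - flank + (0:flank_bins) * (flank / flank_bins)
    edges_body <- s + (0:body_bins) * ((e - s) / body_bins)
    edges_dn <- e + (0:flank_bins) * (flank / flank_bins)
    assign_bins <- function(edges, offset) {
      b <- findInterval(p, edges, left.open = FALSE, rightmost.closed = TRUE)
      ok <- b >= 1 & b <= length(edges) - 1 & p >= edges[1] & p < edges[length(edges)]
      list(bin = b[ok] + offset, val = m[ok])
    }
    for (part in list(assign_bins(edges_up, 0L),
                      assign_bins(edges_body, flank_bins),
                      assign_bins(edges_dn, flank_bins + body_bins))) {
      if (length(part$bin) == 0) next
      t <- tapply(part$val, part$bin, sum)
      idx <- as.integer(names(t))
      sums[idx] <- sums[idx] + as.numeric(t)
      counts[idx] <- counts[idx] + as.integer(table(part$bin))
    }
  }
  data.frame(bin = seq_len(nb),
             section = rep(c("upstream", "body", "downstream"),
                           c(flank_bins, body_bins, flank_bins)),
             mean_methylation = ifelse(counts > 0, sums / counts, NaN),
             n_cpgs = counts)
}
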