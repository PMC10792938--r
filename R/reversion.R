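# Reversion scoring: does the methylation (or expression) change acquired
# in the resistant state revert after drug withdrawal (P12)?

#' Reversion-classification parameters
#'
#' @param quantile_cutoff empirical quantile of the score distribution
#'   above which a DMR is called reverting (default 0.90).
#' @param score_floor positive floor applied to ratio denominators in the
#'   expression score.
#' @return object of class `reversion_params`.
#' @export
reversion_params <- function(quantile_cutoff = 0.90, score_floor = 1e-8) {
  if (quantile_cutoff <= 0 || quantile_cutoff >= 1)
    stop("quantile_cutoff must be in (0, 1)")
  structure(list(quantile_cutoff = quantile_cutoff,
                 score_floor = score_floor),
            class = "reversion_params")
}

#' Methylation reversion score
#'
#' Quantifies what fraction of the resistance-associated methylation shift
#' is undone at P12. With `d1 = m_R - m_P` (the acquired shift) and
#' `d2 = m_P12 - m_R` (the post-withdrawal change), the score is
#' `clamp(-d2/d1, 0, 1)`: 0 if P12 stayed at the resistant level or
#' drifted further in the resistance direction; 1 if P12 reached or
#' overshot the parental level; the undone fraction in between. Scores
#' above 0.5 mean the P12 level is closer to parental than to resistant;
#' below 0.5, closer to resistant. The score is symmetric under
#' hyper/hypo exchange (m -> 1 - m).
#'
#' The published piecewise form of this score (0 when the P12 change
#' opposes the acquired shift, 1 when it overshoots, |D(P,P12)|/|D(P,R)|
#' otherwise) is internally inconsistent with that stated >0.5 property
#' under any sign convention; the clamp form implemented here reproduces
#' both boundary cases and the property exactly. Vectorized.
#'
#' @param m_P,m_R,m_P12 mean methylation (in \[0, 1\]) of the parental,
#'   resistant and P12 states. `m_R` must differ from `m_P` (otherwise the
#'   region was not differential and the score is undefined).
#' @return score in \[0, 1\].
#' @export
methylation_reversion_score <- function(m_P, m_R, m_P12) {
  stopifnot(all(m_P >= 0 & m_P <= 1), all(m_R >= 0 & m_R <= 1),
            all(m_P12 >= 0 & m_P12 <= 1))
  if (any(m_R == m_P))
    stop("undefined reversion score: m_R equals m_P (no methylation shift)")
  d1 <- m_R - m_P
  d2 <- m_P12 - m_R
  pmin(1, pmax(0, -d2 / d1))
}

#' Score DMRs and flag the reverting subset by a quantile cutoff
#'
#' Computes the per-line [methylation_reversion_score()] from the per-line
#' parental/resistant/P12 DMR means attached by [call_dmrs()], averages
#' over lines, takes the empirical `quantile_cutoff` quantile of all
#' per-DMR scores as the cutoff, and flags DMRs with score strictly above
#' it as reverting.
#'
#' @param dmrs data.frame from [call_dmrs()] with `mean_<line>_<state>`
#'   columns for states parental, resistant and P12.
#' @param params a [reversion_params()].
#' @return list: `dmrs` (input plus `reversion_score` and `reverting`
#'   columns) and `cutoff` (the score cutoff used).
#' @export
classify_reverting_dmrs <- function(dmrs, params = reversion_params()) {
  if (nrow(dmrs) == 0)
    return(list(dmrs = cbind(dmrs, reversion_score = numeric(0),
                             reverting = logical(0)), cutoff = NA_real_))
  cols <- grep("^mean_", names(dmrs), value = TRUE)
  lines <- unique(sub("^mean_(.*)_(parental|resistant|P5|P12)$", "\\1", cols))
  per_line <- sapply(lines, function(ln) {
    need <- paste0("mean_", ln, "_", c("parental", "resistant", "P12"))
    miss <- setdiff(need, names(dmrs))
    if (length(miss) > 0)
      stop(sprintf("DMR table is missing state means: %s",
                   paste(miss, collapse = ", ")))
    methylation_reversion_score(dmrs[[need[1]]], dmrs[[need[2]]],
                                dmrs[[need[3]]])
  })
  if (nrow(dmrs) == 1) per_line <- matrix(per_line, 1)
  score <- rowMeans(per_line)
  cutoff <- unname(stats::quantile(score, params$quantile_cutoff))
  dmrs$reversion_score <- score
  dmrs$reverting <- score > cutoff
  list(dmrs = dmrs, cutoff = cutoff)
}

#' Expression reversion score for a transcript
#'
#' Piecewise score on the log2 fold changes of the parental and P12
#' states, each against resistant: 0 if the parental-vs-resistant change
#' is small (`|log2FC(P,R)| < 1`); 0 if the two changes have opposite
#' sign; otherwise the ratio `max(|.|, |.|) / min(|.|, |.|)` of the two
#' absolute fold changes (denominator floored at `score_floor`). A score
#' near 1 means the P12 expression change mirrors the parental one.
#' Vectorized.
#'
#' @param log2fc_P_vs_R,log2fc_P12_vs_R finite log2 fold changes.
#' @param score_floor positive denominator floor.
#' @return non-negative score.
#' @export
expression_reversion_score <- function(log2fc_P_vs_R, log2fc_P12_vs_R,
                                       score_floor = 1e-8) {
  stopifnot(all(is.finite(log2fc_P_vs_R)), all(is.finite(log2fc_P12_vs_R)))
  a <- abs(log2fc_P_vs_R); b <- abs(log2fc_P12_vs_R)
  s <- pmax(a, b) / pmax(pmin(a, b), score_floor)
  s[log2fc_P_vs_R * log2fc_P12_vs_R < 0] <- 0
  s[a < 1] <- 0
  s
}

#' Fraction of DMRs whose P5 methylation is between resistant and P12
#'
#' For each DMR, checks per line whether the P5 mean lies in the closed
#' interval spanned by the resistant and P12 means; the DMR counts only if
#' every line agrees. In the study the P5 state showed an intermediate
#' resistance phenotype, and its methylation at reverting DMRs was always
#' between the resistant and P12 levels.
#'
#' @param dmrs data.frame with `mean_<line>_<state>` columns including P5.
#' @return list: `fraction` (of DMRs with intermediate P5 in all lines)
#'   and `per_dmr` (logical vector).
#' @export
p5_intermediacy <- function(dmrs) {
  if (nrow(dmrs) == 0) return(list(fraction = NaN, per_dmr = logical(0)))
  cols <- grep("^mean_", names(dmrs), value = TRUE)
  lines <- unique(sub("^mean_(.*)_(parental|resistant|P5|P12)$", "\\1", cols))
  per_line <- sapply(lines, function(ln) {
    r <- dmrs[[paste0("mean_", ln, "_resistant")]]
    p5 <- dmrs[[paste0("mean_", ln, "_P5")]]
    p12 <- dmrs[[paste0("mean_", ln, "_P12")]]
    if (is.null(p5)) stop(sprintf("missing P5 means for line %s", ln))
    p5 >= pmin(r, p12) & p5 <= pmax(r, p12)
  })
  if (nrow(dmrs) == 1) per_line <- matrix(per_line, 1)
  ok <- rowSums(per_line) == ncol(per_line)
  list(fraction = mean(ok), per_dmr = ok)
}
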