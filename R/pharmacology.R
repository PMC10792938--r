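# Dose-response fitting (three-parameter log-logistic, Hill slope 1) and
# Loewe-additivity synergy surfaces.

#' Predict viability from a fitted dose-response curve
#'
#' `R(d) = bottom + (top - bottom) / (1 + d / ic50)` (Hill slope 1, the
#' "log(inhibitor) vs response, three parameters" model).
#'
#' @param curve a `dose_response_curve` (or any list with ic50, top,
#'   bottom).
#' @param dose dose vector (>= 0).
#' @return predicted viability (%).
#' @export
predict_viability <- function(curve, dose) {
  hill3(dose, curve$ic50, curve$top, curve$bottom)
}

#' Fit a three-parameter log-logistic dose-response curve
#'
#' Least-squares fit of (ic50, top, bottom) with the Hill slope fixed at
#' 1; the IC50 is optimized on the log scale. Starting values come from
#' the response range and the dose nearest half-maximal response.
#'
#' @param doses positive dose vector (>= 4 points spanning the
#'   transition).
#' @param responses DMSO-normalized viabilities (%).
#' @param drug label stored on the curve.
#' @return object of class `dose_response_curve`: drug, ic50, top,
#'   bottom, doses, responses, fitted, residual_sd.
#' @export
fit_ic50 <- function(doses, responses, drug = "drug") {
  stopifnot(length(doses) == length(responses), length(doses) >= 4,
            all(doses > 0))
  if (stats::sd(responses) < 1e-8)
    stop("fit failure: responses are constant (no dose-response transition)")
  top0 <- max(responses); bot0 <- min(responses)
  half <- (top0 + bot0) / 2
  ic0 <- doses[which.min(abs(responses - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ bottom + (top - bottom) / (1 + doses / exp(lic50)),
      start = list(lic50 = log(ic0), top = top0, bottom = bot0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failure: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  ic50 <- unname(exp(cf["lic50"]))
  if (ic50 > max(doses) * 100 || ic50 < min(doses) / 100)
    stop(sprintf("fit failure: IC50 %.3g outside the dose range x100", ic50))
  if (cf["top"] <= cf["bottom"])
    stop("fit failure: fitted top does not exceed bottom")
  structure(list(drug = drug, ic50 = ic50, top = unname(cf["top"]),
                 bottom = unname(cf["bottom"]), doses = doses,
                 responses = responses, fitted = stats::fitted(fit),
                 residual_sd = stats::sd(stats::residuals(fit))),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s: IC50 = %.4g, top = %.3g, bottom = %.3g\n",
              x$drug, x$ic50, x$top, x$bottom))
  invisible(x)
}

#' Loewe-additivity expected viability of a dose combination
#'
#' Solves `doseA / A(E) + doseB / B(E) = 1` for the effect E, where A(E)
#' and B(E) are the single-agent doses producing viability E. Under a
#' shared Hill slope of 1 and shared plateaus this has the closed form
#' `E = (bottom * S + top) / (1 + S)` with `S = doseA/ic50A +
#' doseB/ic50B`; with differing plateaus the interaction index equation
#' is solved by bisection over the attainable viability range. Either
#' dose equal to 0 reduces to the other single-agent curve. Symmetric in
#' the two drugs. Vectorized over dose pairs.
#'
#' @param curve_a,curve_b fitted `dose_response_curve`s.
#' @param dose_a,dose_b doses (>= 0).
#' @return expected viability (%), clamped (with a warning) to the
#'   jointly attainable range when the equation has no solution inside
#'   it.
#' @export
loewe_expected <- function(curve_a, curve_b, dose_a, dose_b) {
  stopifnot(all(dose_a >= 0), all(dose_b >= 0))
  n <- max(length(dose_a), length(dose_b))
  dose_a <- rep_len(dose_a, n); dose_b <- rep_len(dose_b, n)
  out <- numeric(n)
  same_plateaus <- isTRUE(all.equal(curve_a$top, curve_b$top)) &&
    isTRUE(all.equal(curve_a$bottom, curve_b$bottom))
  for (i in seq_len(n)) {
    da <- dose_a[i]; db <- dose_b[i]
    if (da == 0 && db == 0) { out[i] <- curve_a$top; next }
    if (db == 0) { out[i] <- predict_viability(curve_a, da); next }
    if (da == 0) { out[i] <- predict_viability(curve_b, db); next }
    if (same_plateaus) {
      s <- da / curve_a$ic50 + db / curve_b$ic50
      out[i] <- (curve_a$bottom * s + curve_a$top) / (1 + s)
    } else {
      # inverse dose d(E) = ic50 * (top - E) / (E - bottom)
      lo <- max(curve_a$bottom, curve_b$bottom)
      hi <- min(curve_a$top, curve_b$top)
      if (hi <= lo) {
        warning("curves have no common attainable viability range; clamping")
        out[i] <- (lo + hi) / 2
        next
      }
      f <- function(E) {
        ia <- da / (curve_a$ic50 * (curve_a$top - E) / (E - curve_a$bottom))
        ib <- db / (curve_b$ic50 * (curve_b$top - E) / (E - curve_b$bottom))
        ia + ib - 1
      }
      eps <- (hi - lo) * 1e-9
      flo <- f(lo + eps); fhi <- f(hi - eps)
      if (is.nan(flo) || is.nan(fhi) || flo * fhi > 0) {
        warning("Loewe effect outside attainable range; clamping")
        out[i] <- if (!is.nan(fhi) && fhi > 0) lo else hi
      } else {
        out[i] <- stats::uniroot(f, c(lo + eps, hi - eps),
                                 tol = 1e-10)$root
      }
    }
  }
  out
}

#' Synergy surface of an observed combination grid
#'
#' Per grid cell, synergy = observed viability - Loewe-expected
#' viability (negative = synergistic viability reduction). Cells where
#' either dose is 0 are the single-agent margins; their synergy is 0 by
#' definition of the reference model.
#'
#' @param combo data.frame with dose_a, dose_b, viability covering a
#'   complete grid.
#' @param curve_a,curve_b fitted single-agent `dose_response_curve`s.
#' @return list of class `synergy_surface`: `grid` (dose_a, dose_b,
#'   observed, loewe_expected, synergy) and `mean_synergy` (over cells
#'   with both doses > 0).
#' @export
synergy_matrix <- function(combo, curve_a, curve_b) {
  stopifnot(all(c("dose_a", "dose_b", "viability") %in% names(combo)))
  full <- expand.grid(dose_a = sort(unique(combo$dose_a)),
                      dose_b = sort(unique(combo$dose_b)))
  key <- paste(combo$dose_a, combo$dose_b)
  miss <- !(paste(full$dose_a, full$dose_b) %in% key)
  if (any(miss))
    stop("incomplete dose grid; missing cells: ",
         paste(sprintf("(%g, %g)", full$dose_a[miss], full$dose_b[miss])[
           seq_len(min(5, sum(miss)))], collapse = ", "))
  expected <- loewe_expected(curve_a, curve_b, combo$dose_a, combo$dose_b)
  synergy <- combo$viability - expected
  margin <- combo$dose_a == 0 | combo$dose_b == 0
  synergy[margin] <- 0
  grid <- data.frame(dose_a = combo$dose_a, dose_b = combo$dose_b,
                     observed = combo$viability,
                     loewe_expected = expected, synergy = synergy)
  structure(list(grid = grid,
                 mean_synergy = mean(synergy[!margin])),
            class = "synergy_surface")
}
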