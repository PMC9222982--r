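#' Harrell's concordance index with the censored-earlier discard rule
#'
#' A patient pair contributes when the order of their event times is
#' usable: pairs whose earlier time is censored are discarded. Concretely,
#' an ordered pair (i, j) is permissible iff `t_i < t_j` and `e_i = 1`, or
#' `t_i = t_j` with `e_i = 1, e_j = 0` (the event counts as earlier than a
#' censoring at the same time); pairs tied in time with two events are not
#' counted. A permissible pair is concordant when the earlier patient has
#' the higher risk score; score ties are credited 0.5.
#'
#' @param risk risk scores (higher = predicted earlier event).
#' @param time event/censoring times.
#' @param status status indicators (1 = event).
#' @return a [ConcordanceResult-class].
#' @examples
#' cIndex(concordanceIndex(c(2, 1), c(1, 2), c(1, 1)))  # perfect: 1
#' @export
concordanceIndex <- function(risk, time, status) {
  n <- length(risk)
  if (length(time) != n || length(status) != n)
    .roiStop("roicox_shape_error", "risk, time, status must have equal length")
  Ti <- matrix(time, n, n)
  Tj <- t(Ti)
  Ei <- matrix(status, n, n)
  Ej <- t(Ei)
  # i strictly earlier than j, with the earlier member an event
  permissible <- (Ti < Tj & Ei == 1) | (Ti == Tj & Ei == 1 & Ej == 0)
  Ri <- matrix(risk, n, n)
  Rj <- t(Ri)
  conc <- sum(permissible & Ri > Rj)
  disc <- sum(permissible & Ri < Rj)
  tied <- sum(permissible & Ri == Rj)
  total <- conc + disc + tied
  if (total == 0)
    .roiStop("roicox_metric_error",
             "concordance undefined: no permissible pairs")
  new("ConcordanceResult", cIndex = (conc + 0.5 * tied) / total,
      nConcordant = conc, nDiscordant = disc, nTiedScore = tied,
      nPermissiblePairs = total)
}

#' @describeIn concordanceIndex extract the concordance index.
#' @param object a [ConcordanceResult-class].
#' @export
setMethod("cIndex", "ConcordanceResult", function(object) object@cIndex)

setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf(
    "C-index %.4f over %d permissible pairs (%d concordant, %d discordant, %d tied)\n",
    object@cIndex, object@nPermissiblePairs, object@nConcordant,
    object@nDiscordant, object@nTiedScore))
})

# Exact null distribution of the Wilcoxon signed-rank statistic W+ over
# the 2^n sign assignments, by dynamic programming over doubled midranks
# (doubling makes tied midranks integer, so the distribution stays exact
# under rank ties, which the classical exact formula does not handle).
.signrankExactP <- function(ranks, wObs, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # pmf over 2*W+ as a probability vector indexed 0..total
  pmf <- numeric(total + 1L)
  pmf[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), pmf[seq_len(total + 1L - r)])
    pmf <- 0.5 * (pmf + shifted)
  }
  w2 <- round(2 * wObs)
  idx <- seq_along(pmf) - 1L
  if (tail == "ge") sum(pmf[idx >= w2 - 1e-9]) else sum(pmf[idx <= w2 + 1e-9])
}

#' One-sided paired model comparison (Wilcoxon signed-rank test)
#'
#' Tests whether model B's per-task concordance indices exceed model A's,
#' paired by task. Zero differences are dropped before ranking (classical
#' treatment). For 25 or fewer nonzero differences the exact distribution
#' of the signed-rank statistic is used (exact under rank ties via midrank
#' enumeration); above that, the normal approximation with continuity and
#' tie correction.
#'
#' @param cA per-task C-indices of the baseline model A.
#' @param cB per-task C-indices of the comparison model B (same tasks, same
#'   order).
#' @param alternative "greater" (default): B exceeds A; or "less".
#' @return the one-sided p-value, with attributes `statistic` (W+ of the
#'   differences) and `nZeroDropped`.
#' @export
pairedModelComparison <- function(cA, cB, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(cA) != length(cB))
    .roiStop("roicox_shape_error", "cA and cB must have equal length")
  if (length(cA) < 5L)
    .roiStop("roicox_config_error", "at least 5 paired tasks are required")
  d <- cB - cA
  zeros <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d))
    .roiStop("roicox_degenerate_test_error",
             "all paired differences are zero; test degenerate")
  ranks <- rank(abs(d))
  wPlus <- sum(ranks[d > 0])
  n <- length(d)
  if (n <= 25L) {
    p <- .signrankExactP(ranks, wPlus,
                         tail = if (alternative == "greater") "ge" else "le")
  } else {
    mu <- n * (n + 1) / 4
    tieTab <- table(ranks)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tieTab^3 - tieTab) / 48
    z <- if (alternative == "greater") (wPlus - mu - 0.5) / sqrt(sig2)
         else (wPlus - mu + 0.5) / sqrt(sig2)
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
  }
  structure(p, statistic = wPlus, nZeroDropped = zeros)
}
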