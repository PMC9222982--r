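#' Linear log-relative-hazard
#'
#' Computes `h_i = sum_j beta_j X_ij + b` for every patient i.
#'
#' @param X numeric matrix (n x p).
#' @param beta coefficient vector of length p.
#' @param bias scalar intercept.
#' @return numeric vector of length n.
#' @export
linearHazard <- function(X, beta, bias = 0) {
  X <- as.matrix(X)
  if (ncol(X) != length(beta))
    .roiStop("roicox_shape_error", "X has %d columns but beta has length %d",
             ncol(X), length(beta))
  drop(X %*% beta) + bias
}

# Negative log partial likelihood with Breslow handling of tied event
# times, plus (optionally) its gradient with respect to h. Risk set is
# R(T_i) = {j : t_j >= t_i}. Numerically stabilized by shifting h by its
# maximum before exponentiation; with descending-time ordering the risk-set
# sums are cumulative sums, and tied times share the cumulative sum taken
# at the end of their tie block.
.coxNll <- function(h, time, status, gradient = FALSE) {
  n <- length(h)
  if (length(time) != n || length(status) != n)
    .roiStop("roicox_shape_error", "h, time and status must have equal length")
  if (sum(status) < 1)
    .roiStop("roicox_likelihood_error",
             "partial likelihood undefined: no observed events")
  ord <- order(time, decreasing = TRUE)
  hs <- h[ord]; ts <- time[ord]; es <- status[ord]
  mx <- max(hs)
  eh <- exp(hs - mx)
  cs <- cumsum(eh)
  runs <- rle(ts)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  blk <- rep.int(seq_along(ends), runs$lengths)
  denom <- cs[ends][blk]                       # sum over {j : t_j >= t_i}
  value <- -sum(es * (hs - (mx + log(denom))))
  if (!gradient) return(list(value = value))
  # d(-logPL)/dh_k = -e_k + exp(h_k) * sum_{events i : t_i <= t_k} 1/S_i,
  # computed in the shifted scale (the exp(mx) factors cancel).
  r <- es / denom
  revcs <- rev(cumsum(rev(r)))
  A <- revcs[starts][blk]
  g <- numeric(n)
  g[ord] <- -es + eh * A
  list(value = value, grad = g)
}

#' Negative log partial likelihood
#'
#' Cox's negative log partial likelihood
#' `-sum_{i: e_i = 1} [h_i - log sum_{j in R(T_i)} exp(h_j)]` with risk set
#' `R(T_i) = {j : t_j >= t_i}` and the Breslow convention for tied event
#' times (tied events share one denominator). The computation uses a
#' stabilized log-sum-exp, and the value is invariant to adding a constant
#' to all of `h` (any intercept cancels).
#'
#' @param h vector of log relative hazards.
#' @param time event/censoring times.
#' @param status status indicators (1 = event); at least one event required.
#' @return scalar negative log partial likelihood.
#' @examples
#' negLogPartialLikelihood(c(0, 0, 0), c(1, 2, 3), c(1, 1, 1))  # log(6)
#' @export
negLogPartialLikelihood <- function(h, time, status) {
  .coxNll(h, time, status)$value
}

#' Regularized linear Cox objective
#'
#' `negLogPartialLikelihood(X beta + b) + l2Weight * (sum(beta^2) + b^2)`.
#' Note the penalty includes the bias, which is what pins the otherwise
#' likelihood-neutral intercept at zero.
#'
#' @param beta coefficient vector.
#' @param bias scalar intercept.
#' @param task a [SurvivalTask-class].
#' @param l2Weight penalty weight (default 1e-4).
#' @return scalar objective value.
#' @export
cphLoss <- function(beta, bias, task, l2Weight = 1e-4) {
  h <- linearHazard(features(task), beta, bias)
  negLogPartialLikelihood(h, eventTime(task), eventStatus(task)) +
    l2Weight * (sum(beta^2) + bias^2)
}

#' Joint related-outcome Cox objective
#'
#' The weighted combination of two regularized Cox objectives over the same
#' features, one per outcome, with a single shared bias:
#' `(1 - roiWeight) * [nll_primary(beta1, b) + l2 * (|beta1|^2 + b^2)] +
#'  roiWeight * [nll_aux(beta2, b) + l2 * (|beta2|^2 + b^2)]`.
#'
#' @param beta1 primary-outcome coefficients.
#' @param beta2 auxiliary-outcome coefficients.
#' @param bias shared scalar intercept.
#' @param paired a [PairedSurvivalTask-class].
#' @param roiWeight mixing weight lambda in \[0, 1\] (default 0.2).
#' @param l2Weight L2 penalty weight (default 1e-4).
#' @return scalar objective value.
#' @export
roiLoss <- function(beta1, beta2, bias, paired, roiWeight = 0.2,
                    l2Weight = 1e-4) {
  if (roiWeight < 0 || roiWeight > 1)
    .roiStop("roicox_config_error", "roiWeight must lie in [0, 1]")
  X <- features(paired)
  .term <- function(beta, tm, st, label) {
    if (sum(st) < 1)
      .roiStop("roicox_likelihood_error",
               "%s outcome has no observed events", label)
    negLogPartialLikelihood(linearHazard(X, beta, bias), tm, st) +
      l2Weight * (sum(beta^2) + bias^2)
  }
  p1 <- .term(beta1, eventTime(paired), eventStatus(paired), "primary")
  p2 <- .term(beta2, auxTime(paired), auxStatus(paired), "auxiliary")
  # exact at the lambda-limits: 0 * p and 1 * p are exact in floating point
  (1 - roiWeight) * p1 + roiWeight * p2
}
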