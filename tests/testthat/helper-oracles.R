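# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the vectorized implementations they check.

# Negative log partial likelihood by direct risk-set enumeration (no
# log-sum-exp, Breslow ties via the shared {t_j >= t_i} denominator).
bruteNll <- function(h, time, status) {
  s <- 0
  for (i in seq_along(h)) {
    if (status[i] == 1) {
      R <- which(time >= time[i])
      s <- s + h[i] - log(sum(exp(h[R])))
    }
  }
  -s
}

# Concordance by exhaustive ordered-pair enumeration with the
# censored-earlier discard rule and Harrell tie handling.
bruteCIndex <- function(risk, time, status) {
  conc <- disc <- tied <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      earlier <- (time[i] < time[j]) ||
        (time[i] == time[j] && status[i] == 1 && status[j] == 0)
      if (!earlier || status[i] != 1) next
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] < risk[j]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  total <- conc + disc + tied
  list(c = if (total > 0) (conc + 0.5 * tied) / total else NA_real_,
       n = total, conc = conc, disc = disc, tied = tied)
}

# Exact one-sided signed-rank p-value by enumerating all 2^n sign
# assignments (midranks for ties).
bruteSignrankP <- function(d, alternative = "greater") {
  d <- d[d != 0]
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- drop(signs %*% r)
  if (alternative == "greater") mean(W >= w - 1e-9) else mean(W <= w + 1e-9)
}

numGrad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- eps
    (f(x + e) - f(x - e)) / (2 * eps)
  }, numeric(1))
}

numHess <- function(f, x, eps = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    e <- numeric(p); e[i] <- eps
    H[, i] <- (numGrad(f, x + e) - numGrad(f, x - e)) / (2 * eps)
  }
  (H + t(H)) / 2
}

# Second, independent minimizer of the regularized Cox objective: damped
# Newton on the brute-force likelihood with numerical derivatives.
newtonCoxOracle <- function(task, l2 = 1e-4, iters = 60) {
  X <- features(task)
  p <- ncol(X)
  f <- function(par) {
    bruteNll(drop(X %*% par[seq_len(p)]) + par[p + 1], eventTime(task),
             eventStatus(task)) + l2 * sum(par^2)
  }
  par <- numeric(p + 1)
  for (it in seq_len(iters)) {
    g <- numGrad(f, par)
    if (sqrt(sum(g^2)) < 1e-9) break
    step <- solve(numHess(f, par), g)
    while (f(par - step) > f(par)) step <- step / 2
    par <- par - step
  }
  par
}

# Small random survival task with exponential Cox times and random
# censoring; beta = 0 gives a pure-noise task.
makeTask <- function(n = 40, p = 3, seed = 1, beta = NULL,
                     censorFrac = 0.3) {
  set.seed(seed)
  X <- matrix(runif(n * p, -1, 1), n, p)
  if (is.null(beta)) beta <- runif(p, -1, 1)
  latent <- rexp(n, 1 / 100) / exp(drop(X %*% beta))
  status <- rep(1, n)
  cens <- sample(n, round(censorFrac * n))
  status[cens] <- 0
  time <- latent
  time[cens] <- latent[cens] * runif(length(cens), 0.3, 1)
  survivalTask(X, time, status)
}

makePairedTask <- function(n = 40, p = 3, seed = 1) {
  base <- makeTask(n, p, seed)
  set.seed(seed + 1000)
  aux <- makeTask(n, p, seed + 1000)
  pairedSurvivalTask(features(base), eventTime(base), eventStatus(base),
                     eventTime(aux), eventStatus(aux))
}

smallGenConfig <- function(seed = 1) {
  generatorConfig(nPatients = 80L, nFeatures = 10L, nEventsTarget = 50L,
                  seed = seed)
}
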