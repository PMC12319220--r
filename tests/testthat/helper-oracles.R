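# Independent oracles, deliberately written with naive enumeration so they
# share no code path with the package implementations they check.

# Hand-written Cox partial log-likelihood (Efron tie handling). x is a single
# numeric covariate.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_D <- sum(exp(beta * x[D]))
    sum_R <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_R - (l / d) * sum_D)
    }
  }
  ll
}

# Grid scan over [-5, 5] followed by local refinement of the hand-written
# partial likelihood.
oracle_cox_beta <- function(time, event, x, lower = -5, upper = 5) {
  grid <- seq(lower, upper, by = 1e-3)
  vals <- vapply(grid, oracle_cox_loglik, numeric(1),
                 time = time, event = event, x = x)
  b0 <- grid[which.max(vals)]
  stats::optimize(oracle_cox_loglik,
                  interval = c(b0 - 2e-3, b0 + 2e-3), maximum = TRUE,
                  time = time, event = event, x = x,
                  tol = 1e-9)$maximum
}

# Exhaustive pairwise concordance: loop over all pairs, usable iff the
# shorter follow-up time belongs to a patient with an event (ties in time
# unusable); score ties count 1/2.
oracle_concordance <- function(score, time, event) {
  conc <- disc <- tied <- 0
  n <- length(score)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      early <- if (time[i] < time[j]) i else j
      late <- if (time[i] < time[j]) j else i
      if (event[early] != 1) next
      if (score[early] > score[late]) conc <- conc + 1
      else if (score[early] < score[late]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  total <- conc + disc + tied
  list(c = (conc + 0.5 * tied) / total, concordant = conc,
       discordant = disc, tied_score = tied, usable = total)
}

# Generalized-least-squares BLUP for one subject at fixed (alpha, G, sigma2),
# via the joint-normal conditional mean written out with explicit inverses.
oracle_blup <- function(visits, y, alpha, G, sigma2) {
  Z <- cbind(1, visits)
  V <- Z %*% G %*% t(Z) + sigma2 * diag(length(visits))
  # Cov(b, y) = G Z'; E[b | y] = Cov(b, y) V^{-1} (y - X alpha)
  as.numeric(G %*% t(Z) %*% solve(V) %*% (y - Z %*% alpha))
}

# Hand product-limit estimator over unique event times.
oracle_km <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    d <- sum(time == t & event == 1)
    n_risk <- sum(time >= t)
    s <- s * (1 - d / n_risk)
  }
  s
}
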