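# Independent oracles used to cross-check the package's least-squares fits.
# These deliberately use different estimation principles (maximum likelihood
# on the raw, unbinned data) from the log-survival / binned-density
# least-squares paths they validate.

# Survival of the two-component exponential mixture.
oracle_mix_survival <- function(t, alpha, tau1, tau2) {
  alpha * exp(-t / tau1) + (1 - alpha) * exp(-t / tau2)
}

# Maximum-likelihood fit of the frame-discretized exponential mixture.
# Recorded dwells d = k * dt (k >= 1) have probability
# [S(d) - S(d + dt)] / S(dt) under conditioning on >= 2 observed frames.
oracle_dwell_mle <- function(durations, dt) {
  tab <- table(durations)
  d <- as.numeric(names(tab))
  w <- as.numeric(tab)
  nll <- function(p) {
    a <- plogis(p[1]); tau1 <- exp(p[2]); tau2 <- tau1 * (1 + exp(p[3]))
    pr <- (oracle_mix_survival(d, a, tau1, tau2) -
             oracle_mix_survival(d + dt, a, tau1, tau2)) /
      oracle_mix_survival(dt, a, tau1, tau2)
    -sum(w * log(pmax(pr, 1e-300)))
  }
  best <- NULL
  for (a0 in c(0.3, 0.7)) for (t0 in c(0.5, 1) * mean(durations)) {
    op <- tryCatch(optim(c(qlogis(a0), log(t0), log(3)), nll,
                         method = "BFGS", control = list(maxit = 500)),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  a <- plogis(best$par[1]); tau1 <- exp(best$par[2])
  tau2 <- tau1 * (1 + exp(best$par[3]))
  list(alpha = a, tau1 = tau1, tau2 = tau2)
}

# EM algorithm for a two-component Rayleigh mixture on raw step sizes.
# Component j has density r / (2 Dj tau) exp(-r^2 / (4 Dj tau)).
oracle_rayleigh_em <- function(r, tau, n_iter = 300) {
  r2 <- r^2
  D1 <- quantile(r2, 0.25) / (4 * tau)
  D2 <- quantile(r2, 0.75) / (4 * tau)
  a <- 0.5
  dens <- function(D) r / (2 * D * tau) * exp(-r2 / (4 * D * tau))
  for (it in seq_len(n_iter)) {
    f1 <- a * dens(D1); f2 <- (1 - a) * dens(D2)
    g <- f1 / (f1 + f2)
    a <- mean(g)
    D1 <- sum(g * r2) / (4 * tau * sum(g))
    D2 <- sum((1 - g) * r2) / (4 * tau * sum(1 - g))
  }
  if (D1 > D2) { tmp <- D1; D1 <- D2; D2 <- tmp; a <- 1 - a }
  list(alpha = unname(a), D1 = unname(D1), D2 = unname(D2))
}

# Expected recorded dwell under frame discretization with a 2-frame minimum,
# by direct summation: E[(K-1) dt | K >= 2] for K = floor(T/dt) + 1,
# T ~ Exp(tau).  P(K = m) = S((m-1)dt) - S(m dt).
oracle_discretized_mean_dwell <- function(tau, dt, kmax = 100000) {
  m <- 2:kmax
  pk <- exp(-(m - 1) * dt / tau) - exp(-m * dt / tau)
  sum((m - 1) * dt * pk) / sum(pk)
}
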