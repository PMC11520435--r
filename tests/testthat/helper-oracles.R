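# Independent oracles used across the suite.  These deliberately avoid
# the code paths they are checking.

# Inverse-CDF draws from the standardized asymmetric Laplace law, via
# the piecewise-exponential closed form written out directly.
r_ald_invcdf <- function(n, tau) {
  u <- runif(n)
  ifelse(u <= tau,
         log(u / tau) / (1 - tau),
         -log((1 - u) / (1 - tau)) / tau)
}

# Closed-form inverse-Gaussian CDF (mean mu, shape lambda).
p_invgauss <- function(q, mu, lambda) {
  s <- sqrt(lambda / q)
  pnorm(s * (q / mu - 1)) + exp(2 * lambda / mu) * pnorm(-s * (q / mu + 1))
}

# Closed-form inverse-Gaussian density.
d_invgauss <- function(x, mu, lambda) {
  sqrt(lambda / (2 * pi * x^3)) * exp(-lambda * (x - mu)^2 / (2 * mu^2 * x))
}

# GIG(1/2, a, b) CDF through the reciprocal inverse-Gaussian identity.
p_gig_half <- function(q, a, b) {
  1 - p_invgauss(1 / q, mu = b / a, lambda = b^2)
}

# Brute-force type-7 percentile: sort and linearly interpolate.
percentile_bruteforce <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Direct numerical minimizer of the check-loss objective (Nelder-Mead
# from the least-squares start) -- the frequentist oracle the sampler
# is compared against.
checkloss_minimizer <- function(y, X, tau) {
  obj <- function(b) sum(check_loss(y - drop(X %*% b), tau))
  start <- qr.coef(qr(X), y)
  optim(start, obj, method = "Nelder-Mead",
        control = list(maxit = 5000, reltol = 1e-10))$par
}

# Small regression dataset with ALD noise at level tau (truth = beta
# exactly at that tau since the noise has tau-quantile zero).
simulate_ald_data <- function(n, tau, beta = c(15.3, 1, -0.5),
                              noise_scale = 0.5, seed = 1) {
  set.seed(seed)
  x1 <- runif(n, -1, 1)
  x2 <- rbinom(n, 1, 0.5)
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  y <- drop(X %*% beta) +
    noise_scale * sample_ald_via_mixture(n, tau, seed = seed + 7)
  encoded_dataset(y, X)
}

# One-sample Kolmogorov-Smirnov critical value at the 1% level.
ks_crit_1pct <- function(n) 1.6276 / sqrt(n)
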