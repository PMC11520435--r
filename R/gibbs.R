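#' Assemble an encoded dataset for quantile regression
#'
#' Bundles the outcome vector with a design matrix whose first column is
#' the intercept.  Validates the invariants the sampler relies on: no
#' missing values, full column rank, and more observations than
#' coefficients.
#'
#' @param outcome numeric outcome vector of length n (here BMI, kg/m^2).
#' @param design n x p numeric matrix; first column must be all ones.
#' @param column_labels optional character vector of p coefficient
#'   labels; defaults to the design's column names.
#' @return object of class `bqr_data` with elements `outcome`, `design`,
#'   `column_labels`, `n`, `p`.
#' @export
encoded_dataset <- function(outcome, design, column_labels = colnames(design)) {
  design <- as.matrix(design)
  if (anyNA(outcome) || anyNA(design)) {
    stop("encoded dataset must not contain missing values", call. = FALSE)
  }
  n <- length(outcome)
  p <- ncol(design)
  if (nrow(design) != n) stop("outcome and design sizes differ", call. = FALSE)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  if (any(design[, 1L] != 1)) {
    stop("first design column must be the intercept (all ones)", call. = FALSE)
  }
  if (qr(design)$rank < p) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  if (is.null(column_labels)) {
    column_labels <- c("(Intercept)", paste0("V", seq_len(p - 1L)))
  }
  stopifnot(length(column_labels) == p)
  colnames(design) <- column_labels
  structure(list(outcome = as.numeric(outcome), design = design,
                 column_labels = column_labels, n = n, p = p),
            class = "bqr_data")
}

#' Multivariate normal prior on the regression coefficients
#'
#' @param beta_mean prior mean vector (recycled to length p at fit time
#'   if scalar).
#' @param beta_cov prior covariance: a p x p symmetric positive-definite
#'   matrix, or a positive scalar v meaning v * I.  The default 100 * I
#'   is diffuse on the BMI scale.
#' @return object of class `bqr_prior`.
#' @export
prior_spec <- function(beta_mean = 0, beta_cov = 100) {
  if (is.matrix(beta_cov)) {
    if (!isSymmetric(unname(beta_cov)) ||
        any(eigen(beta_cov, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
      stop("beta_cov must be symmetric positive definite", call. = FALSE)
    }
  } else if (length(beta_cov) != 1L || beta_cov <= 0) {
    stop("scalar beta_cov must be positive", call. = FALSE)
  }
  structure(list(beta_mean = beta_mean, beta_cov = beta_cov),
            class = "bqr_prior")
}

#' MCMC schedule for the Gibbs sampler
#'
#' Defaults follow the analysis schedule: 10,000 iterations, 1,000
#' burn-in draws discarded, thinning interval 5, leaving
#' floor((10000 - 1000) / 5) = 1800 retained draws.
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in initial iterations discarded; must be < iterations.
#' @param thin keep every thin-th post-burn-in iteration (>= 1).
#' @param seed integer seed controlling the whole chain.
#' @return object of class `bqr_config`.
#' @export
sampler_config <- function(iterations = 10000L, burn_in = 1000L,
                           thin = 5L, seed = 1L) {
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= iterations) stop("burn_in must be < iterations", call. = FALSE)
  if (thin < 1L) stop("thin must be >= 1", call. = FALSE)
  if (burn_in < 0L) stop("burn_in must be >= 0", call. = FALSE)
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed)), class = "bqr_config")
}

# Expand a prior to explicit p-dimensional mean / precision.
expand_prior <- function(prior, p) {
  mean <- rep_len(prior$beta_mean, p)
  if (is.matrix(prior$beta_cov)) {
    stopifnot(nrow(prior$beta_cov) == p)
    prec <- chol2inv(chol(prior$beta_cov))
  } else {
    prec <- diag(1 / prior$beta_cov, p)
  }
  list(mean = mean, precision = prec)
}

#' Gaussian full conditional of the coefficient vector
#'
#' Given the latent mixing variables l, the coefficients have an exact
#' multivariate normal full conditional with
#' precision \eqn{\Omega_0^{-1} + \sum_i x_i x_i' / (h^2 l_i)} and mean
#' \eqn{\Sigma (\Omega_0^{-1} \beta_0 + \sum_i x_i (y_i - \gamma l_i) /
#' (h^2 l_i))}.
#'
#' @param data a `bqr_data` object.
#' @param latents positive vector of length n.
#' @param tau quantile level.
#' @param prior a `bqr_prior` object.
#' @param sigma scale parameter (1 in the default, scale-fixed sampler).
#' @return list with `mean` (length p) and `covariance` (p x p).
#' @export
beta_full_conditional <- function(data, latents, tau, prior, sigma = 1) {
  assert_tau(tau)
  stopifnot(inherits(data, "bqr_data"))
  if (any(latents <= 0) || length(latents) != data$n) {
    stop("latents must be positive and of length n", call. = FALSE)
  }
  mc <- mixture_constants(tau)
  pr <- expand_prior(prior, data$p)
  w <- 1 / (sigma * mc$h^2 * latents)
  X <- data$design
  precision <- pr$precision + crossprod(X * sqrt(w))
  rhs <- drop(pr$precision %*% pr$mean) +
    drop(crossprod(X, (data$outcome - mc$gamma * latents) * w))
  R <- tryCatch(chol(precision), error = function(e) {
    stop("singular precision matrix in coefficient full conditional: ",
         conditionMessage(e), call. = FALSE)
  })
  covariance <- chol2inv(R)
  list(mean = drop(covariance %*% rhs), covariance = covariance)
}

#' GIG parameters of a latent mixing variable's full conditional
#'
#' Each latent l_i given the data and coefficients follows
#' GIG(1/2, delta_i, phi) with \eqn{\delta_i = |y_i - x_i'\beta| / h}
#' and \eqn{\phi = \sqrt{\gamma^2/h^2 + 2}}.  A residual smaller in
#' magnitude than `floor` is floored, because delta = 0 makes the
#' order-1/2 GIG draw improper.
#'
#' @param residual numeric vector of raw residuals y - X beta.
#' @param tau quantile level.
#' @param sigma scale parameter (1 in the default sampler).
#' @param floor lower bound applied to |residual| before scaling.
#' @return list with `order` (1/2), `a` (vector), `b` (scalar).
#' @export
latent_full_conditional <- function(residual, tau, sigma = 1,
                                    floor = 1e-10) {
  assert_tau(tau)
  mc <- mixture_constants(tau)
  a <- pmax(abs(residual), floor) / (mc$h * sqrt(sigma))
  b <- sqrt(mc$gamma^2 / mc$h^2 + 2) / sqrt(sigma)
  list(order = 0.5, a = a, b = b)
}

#' Run the Gibbs sampler for Bayesian quantile regression
#'
#' Alternates exact draws from the Gaussian full conditional of the
#' coefficients and the GIG(1/2) full conditionals of the n latent
#' mixing variables, under the asymmetric-Laplace working likelihood at
#' level tau.  Coefficients start at the least-squares solution and
#' latents at 1; burn-in draws are discarded and every `thin`-th
#' iteration thereafter is retained.
#'
#' The sampler is scale-fixed (sigma = 1) by default, matching the
#' error model in which no free scale appears.  With
#' `estimate_scale = TRUE` an inverse-gamma prior
#' IG(`scale_shape`, `scale_rate`) is placed on sigma and sigma is
#' updated from its conjugate full conditional each sweep.
#'
#' @param data a `bqr_data` object.
#' @param tau quantile level in (0, 1).
#' @param prior a `bqr_prior`; default diffuse N(0, 100 I).
#' @param config a `bqr_config`; default 10000/1000/5 schedule.
#' @param estimate_scale logical; update sigma? Off by default.
#' @param scale_shape,scale_rate inverse-gamma hyperparameters used
#'   only when `estimate_scale` is TRUE.
#' @return object of class `bqr_chain`: `tau`, `draws` (m x p matrix of
#'   retained coefficient draws, column names = coefficient labels),
#'   `sigma_draws` (retained sigma draws or NULL), `latent_last` (final
#'   latent state), `config`, `column_labels`.
#' @export
run_gibbs <- function(data, tau, prior = prior_spec(),
                      config = sampler_config(),
                      estimate_scale = FALSE,
                      scale_shape = 0.01, scale_rate = 0.01) {
  assert_tau(tau)
  stopifnot(inherits(data, "bqr_data"), inherits(config, "bqr_config"))
  set.seed(config$seed)

  X <- data$design
  y <- data$outcome
  n <- data$n
  p <- data$p
  mc <- mixture_constants(tau)
  pr <- expand_prior(prior, p)
  prior_rhs <- drop(pr$precision %*% pr$mean)

  m <- (config$iterations - config$burn_in) %/% config$thin
  draws <- matrix(NA_real_, m, p, dimnames = list(NULL, data$column_labels))
  sigma_draws <- if (estimate_scale) numeric(m) else NULL

  beta <- qr.coef(qr(X), y)           # deterministic start at least squares
  l <- rep(1, n)
  sigma <- 1
  b_latent <- sqrt(mc$gamma^2 / mc$h^2 + 2)
  keep <- 0L

  for (iter in seq_len(config$iterations)) {
    # --- beta | y, l, sigma ---
    w <- 1 / (sigma * mc$h^2 * l)
    precision <- pr$precision + crossprod(X * sqrt(w))
    rhs <- prior_rhs + drop(crossprod(X, (y - mc$gamma * l) * w))
    R <- tryCatch(chol(precision), error = function(e) {
      stop("singular precision at iteration ", iter, ": ",
           conditionMessage(e), call. = FALSE)
    })
    mu <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
    beta <- mu + backsolve(R, stats::rnorm(p))

    # --- l | y, beta, sigma : GIG(1/2, |r_i|/(h sqrt(sigma)), phi) ---
    r <- y - drop(X %*% beta)
    a_latent <- pmax(abs(r), 1e-10) / (mc$h * sqrt(sigma))
    l <- sample_gig_half(n, a = a_latent, b = b_latent / sqrt(sigma))
    # guard against floating-point under/overflow in extreme-tau sweeps
    l <- pmin(pmax(l, 1e-12), 1e12)

    # --- sigma | y, beta, l (optional conjugate inverse-gamma) ---
    if (estimate_scale) {
      rate <- scale_rate + sum(l) +
        sum((r - mc$gamma * l)^2 / (2 * mc$h^2 * l))
      sigma <- 1 / stats::rgamma(1L, shape = scale_shape + 1.5 * n,
                                 rate = rate)
    }

    if (!all(is.finite(beta))) {
      stop("non-finite coefficient draw at iteration ", iter, call. = FALSE)
    }
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0L) {
      keep <- keep + 1L
      draws[keep, ] <- beta
      if (estimate_scale) sigma_draws[keep] <- sigma
    }
  }

  structure(list(tau = tau, draws = draws, sigma_draws = sigma_draws,
                 latent_last = l, config = config,
                 column_labels = data$column_labels),
            class = "bqr_chain")
}

#' @export
print.bqr_chain <- function(x, ...) {
  cat("Bayesian quantile regression chain (tau = ", x$tau, ")\n",
      "  retained draws: ", nrow(x$draws), " x ", ncol(x$draws),
      " coefficients\n", sep = "")
  invisible(x)
}

#' Derive the chain seed for one quantile level
#'
#' Deterministic rule combining the master seed with the index of tau in
#' the requested list: `seed + 7919 * (index - 1)`, kept within 32-bit
#' integer range.  Documented so multi-quantile runs are reproducible
#' chain by chain.
#'
#' @param seed master integer seed.
#' @param index 1-based position of tau in the tau list.
#' @return integer seed for that chain.
#' @export
tau_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 7919 * (index - 1)) %% .Machine$integer.max)
}

#' Fit independent chains at several quantile levels
#'
#' One Gibbs chain per tau, with per-tau seeds derived from the master
#' seed by [tau_seed()].
#'
#' @inheritParams run_gibbs
#' @param taus distinct quantile levels; default [default_taus()].
#' @return object of class `bqr_fit`: a named list of `bqr_chain`
#'   objects (names `"tau_<level>"`), with attribute `taus`.
#' @export
fit_multi_quantile <- function(data, taus = default_taus(),
                               prior = prior_spec(),
                               config = sampler_config(), ...) {
  assert_tau(taus)
  if (anyDuplicated(taus)) stop("taus must be distinct", call. = FALSE)
  chains <- vector("list", length(taus))
  for (i in seq_along(taus)) {
    cfg_i <- config
    cfg_i$seed <- tau_seed(config$seed, i)
    chains[[i]] <- run_gibbs(data, taus[i], prior = prior, config = cfg_i, ...)
  }
  names(chains) <- tau_label(taus)
  structure(chains, taus = taus, class = "bqr_fit")
}

#' Write retained draws to CSV
#'
#' One row per retained draw, one column per coefficient, header equal
#' to the coefficient labels — the interchange format for external
#' diagnostic tools.
#'
#' @param chain a `bqr_chain`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "bqr_chain"))
  utils::write.csv(as.data.frame(chain$draws), path, row.names = FALSE)
  invisible(path)
}
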