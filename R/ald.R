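#' Validate a quantile level
#'
#' A quantile level tau must lie strictly inside (0, 1).  The six levels
#' used throughout the analysis default to
#' \code{c(0.05, 0.25, 0.5, 0.75, 0.85, 0.95)}.
#'
#' @param tau numeric scalar (or vector) of quantile levels.
#' @return `tau`, invisibly, after validation.
#' @keywords internal
assert_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) < 1L || anyNA(tau) ||
      any(tau <= 0) || any(tau >= 1)) {
    stop("quantile level tau must lie strictly in (0, 1)", call. = FALSE)
  }
  invisible(tau)
}

#' Default quantile levels for the multi-quantile analysis
#'
#' @return numeric vector `c(0.05, 0.25, 0.5, 0.75, 0.85, 0.95)`.
#' @export
default_taus <- function() c(0.05, 0.25, 0.50, 0.75, 0.85, 0.95)

#' Canonical text label for a quantile level
#'
#' Element-wise formatting (so 0.5 is `"0.5"`, never padded to
#' `"0.50"` by vector formatting), used consistently in chain names,
#' truth maps and output columns.
#'
#' @param tau numeric vector of quantile levels.
#' @param prefix prepended to each label.
#' @return character vector.
#' @export
tau_label <- function(tau, prefix = "tau_") {
  paste0(prefix, vapply(tau, function(t) format(t, trim = TRUE), ""))
}

#' Check (pinball) loss
#'
#' The asymmetric absolute loss whose expected-loss minimizer is the
#' tau-quantile: \eqn{\rho_\tau(w) = w(\tau - I(w < 0))}, i.e. \eqn{w\tau}
#' for \eqn{w \ge 0} and \eqn{w(\tau - 1)} for \eqn{w < 0}.
#'
#' @param w numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @return nonnegative numeric vector, same length as `w`.
#' @examples
#' check_loss(c(-1, 0, 1), 0.3)  # 0.7, 0, 0.3
#' @export
check_loss <- function(w, tau) {
  assert_tau(tau)
  stopifnot(is.numeric(w))
  w * (tau - (w < 0))
}

#' Exponential-normal mixture constants of the asymmetric Laplace law
#'
#' The ALD error can be represented as \eqn{\epsilon = \gamma l + h m
#' \sqrt{l}} with \eqn{l \sim Exp(1)}, \eqn{m \sim N(0,1)} independent,
#' where \eqn{\gamma = (1 - 2\tau) / (\tau(1-\tau))} and
#' \eqn{h = \sqrt{2 / (\tau(1-\tau))}}.
#'
#' @param tau quantile level in (0, 1).
#' @return list with components `gamma` (drift) and `h` (scale), and the
#'   `tau` they belong to.
#' @export
mixture_constants <- function(tau) {
  assert_tau(tau)
  if (length(tau) != 1L) stop("tau must be a scalar", call. = FALSE)
  tq <- tau * (1 - tau)
  list(gamma = (1 - 2 * tau) / tq, h = sqrt(2 / tq), tau = tau)
}

#' Asymmetric Laplace density
#'
#' Density of the ALD with location mu, scale sigma and asymmetry tau,
#' written through the check loss:
#' \deqn{f(y) = \frac{\tau(1-\tau)}{\sigma}
#'       \exp\{-\rho_\tau((y - \mu)/\sigma)\}.}
#' The tau-quantile of this distribution is exactly `location`.
#'
#' @param y numeric vector of evaluation points.
#' @param tau quantile level in (0, 1).
#' @param location location parameter (the tau-quantile).
#' @param scale positive scale parameter.
#' @return nonnegative numeric vector of densities.
#' @export
ald_density <- function(y, tau, location = 0, scale = 1) {
  assert_tau(tau)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("scale must be a positive scalar", call. = FALSE)
  }
  w <- (y - location) / scale
  tau * (1 - tau) / scale * exp(-check_loss(w, tau))
}

#' Asymmetric Laplace cumulative distribution function
#'
#' Piecewise-exponential closed form: for the standardized residual
#' \eqn{w = (y - \mu)/\sigma}, \eqn{F(w) = \tau e^{(1-\tau)w}} when
#' \eqn{w \le 0} and \eqn{1 - (1-\tau) e^{-\tau w}} otherwise.  Satisfies
#' \eqn{F(\mu) = \tau}.
#'
#' @inheritParams ald_density
#' @return probabilities in [0, 1].
#' @export
ald_cdf <- function(y, tau, location = 0, scale = 1) {
  assert_tau(tau)
  stopifnot(scale > 0)
  w <- (y - location) / scale
  ifelse(w <= 0, tau * exp((1 - tau) * w), 1 - (1 - tau) * exp(-tau * w))
}

#' Asymmetric Laplace quantile function
#'
#' Inverse of [ald_cdf()], used for inverse-CDF sampling and as the
#' closed-form reference distribution in distributional tests.
#'
#' @param p probabilities in (0, 1).
#' @inheritParams ald_density
#' @return numeric vector of quantiles.
#' @export
ald_quantile <- function(p, tau, location = 0, scale = 1) {
  assert_tau(tau)
  stopifnot(scale > 0, all(p > 0), all(p < 1))
  w <- ifelse(p <= tau,
              log(p / tau) / (1 - tau),
              -log((1 - p) / (1 - tau)) / tau)
  location + scale * w
}

#' Sample from the asymmetric Laplace law via its scale mixture
#'
#' Draws \eqn{\epsilon = \gamma l + h m \sqrt{l}} with \eqn{l \sim
#' Exp(1)} and \eqn{m \sim N(0,1)}, then applies location and scale.
#' This is the same representation the Gibbs sampler augments, so the
#' draws exercise exactly the mixture the model relies on.
#'
#' @param n number of draws (>= 1).
#' @param tau quantile level in (0, 1).
#' @param location location (the tau-quantile of the output draws).
#' @param scale positive scale.
#' @param seed integer seed; the stream is reproducible given the seed.
#' @return numeric vector of n draws.
#' @export
sample_ald_via_mixture <- function(n, tau, location = 0, scale = 1,
                                   seed = NULL) {
  assert_tau(tau)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  stopifnot(scale > 0)
  if (!is.null(seed)) set.seed(seed)
  mc <- mixture_constants(tau)
  l <- stats::rexp(n)
  m <- stats::rnorm(n)
  location + scale * (mc$gamma * l + mc$h * m * sqrt(l))
}
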