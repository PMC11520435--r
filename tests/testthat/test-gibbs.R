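test_that("encoded dataset enforces its invariants", {
  expect_error(encoded_dataset(c(1, NA, 3), cbind(1, 1:3)), "missing")
  expect_error(encoded_dataset(1:3, cbind(2, 1:3)), "intercept")
  expect_error(encoded_dataset(1:4, cbind(1, c(1, 2, 1, 2), c(2, 4, 2, 4))),
               "rank deficient")
  expect_error(encoded_dataset(1:2, cbind(1, 1:2)), "more observations")
  d <- encoded_dataset(1:5, cbind(1, 1:5), c("(Intercept)", "x"))
  expect_s3_class(d, "bqr_data")
  expect_equal(d$p, 2)
})

test_that("coefficient full conditional reduces to least squares under flat prior", {
  set.seed(21)
  X <- cbind(1, runif(100), rnorm(100))
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(100)
  d <- encoded_dataset(y, X, c("(Intercept)", "x1", "x2"))
  fc <- beta_full_conditional(d, latents = rep(1, 100), tau = 0.5,
                              prior = prior_spec(0, 1e8))
  ols <- qr.coef(qr(X), y)
  expect_equal(unname(fc$mean), unname(ols), tolerance = 1e-6)
  expect_true(isSymmetric(fc$covariance, tol = 1e-10))
  expect_true(all(eigen(fc$covariance, only.values = TRUE)$values > 0))
})

test_that("coefficient full conditional collapses to the prior when it dominates", {
  set.seed(22)
  X <- cbind(1, rnorm(50))
  y <- rnorm(50, 10)
  d <- encoded_dataset(y, X, c("(Intercept)", "x"))
  fc <- beta_full_conditional(d, rep(1, 50), 0.5,
                              prior = prior_spec(c(3, -2), 1e-8))
  expect_equal(unname(fc$mean), c(3, -2), tolerance = 1e-6)
})

test_that("two-point intercept-only hand case gives the average", {
  d <- encoded_dataset(c(1, 3), matrix(1, 2, 1), "(Intercept)")
  fc <- beta_full_conditional(d, c(1, 1), 0.5, prior = prior_spec(0, 1e8))
  expect_equal(unname(fc$mean), 2, tolerance = 1e-6)
  expect_error(beta_full_conditional(d, c(1, -1), 0.5, prior_spec()),
               "positive")
})

test_that("latent full conditional has the stated GIG parameters", {
  g <- latent_full_conditional(0, 0.5)
  expect_equal(g$order, 0.5)
  expect_equal(g$a, 1e-10 / sqrt(8))   # residual floored at the median
  expect_equal(g$b, sqrt(2))
  # b^2 = gamma^2/h^2 + 2 computed two independent ways
  mc <- mixture_constants(0.25)
  expect_equal(latent_full_conditional(1, 0.25)$b^2,
               mc$gamma^2 / mc$h^2 + 2)
  expect_equal(latent_full_conditional(1, 0.25)$b^2,
               ((1 - 2 * 0.25)^2 / (0.25 * 0.75)) / 2 + 2)
  # sign of the residual is irrelevant
  expect_equal(latent_full_conditional(-2.4, 0.85)$a,
               latent_full_conditional(2.4, 0.85)$a)
})

test_that("default schedule retains exactly 1800 draws", {
  set.seed(23)
  X <- cbind(1, runif(60))
  y <- drop(X %*% c(1, 2)) + rnorm(60, sd = 0.3)
  d <- encoded_dataset(y, X, c("(Intercept)", "x"))
  ch <- run_gibbs(d, 0.5, config = sampler_config(seed = 2))
  expect_equal(nrow(ch$draws), 1800)
  expect_equal((10000 - 1000) %/% 5, 1800)
  expect_equal(colnames(ch$draws), c("(Intercept)", "x"))
  expect_length(ch$latent_last, 60)
  expect_true(all(ch$latent_last > 0))
})

test_that("intercept-only posterior mean tracks the sample median", {
  set.seed(24)
  y <- rnorm(500)
  d <- encoded_dataset(y, matrix(1, 500, 1), "(Intercept)")
  ch <- run_gibbs(d, 0.5, config = sampler_config(seed = 3))
  expect_lt(abs(mean(ch$draws[, 1]) - median(y)), 0.1)
})

test_that("chains are bit-identical under the same seed", {
  d <- simulate_ald_data(120, 0.5, seed = 4)
  cfg <- sampler_config(1000, 100, 2, seed = 99)
  ch1 <- run_gibbs(d, 0.25, config = cfg)
  ch2 <- run_gibbs(d, 0.25, config = cfg)
  expect_identical(ch1$draws, ch2$draws)
  expect_identical(ch1$latent_last, ch2$latent_last)
})

test_that("multi-quantile fits produce one chain per level with derived seeds", {
  d <- simulate_ald_data(150, 0.5, seed = 5)
  cfg <- sampler_config(800, 100, 2, seed = 17)
  fit <- fit_multi_quantile(d, taus = c(0.25, 0.5, 0.75), config = cfg)
  expect_s3_class(fit, "bqr_fit")
  expect_named(fit, c("tau_0.25", "tau_0.5", "tau_0.75"))
  expect_true(all(vapply(fit, function(ch) nrow(ch$draws), 0) == 350))
  # a single-tau list reduces to run_gibbs with the derived seed
  cfg1 <- cfg; cfg1$seed <- tau_seed(17, 1)
  solo <- run_gibbs(d, 0.25, config = cfg1)
  expect_identical(fit[[1]]$draws, solo$draws)
  expect_error(fit_multi_quantile(d, taus = c(0.5, 0.5), config = cfg),
               "distinct")
})

test_that("fitted intercepts are non-decreasing in tau on a location-shift model", {
  set.seed(26)
  y <- 10 + rnorm(800)
  d <- encoded_dataset(y, matrix(1, 800, 1), "(Intercept)")
  fit <- fit_multi_quantile(d, config = sampler_config(2000, 400, 2,
                                                       seed = 31))
  means <- vapply(fit, function(ch) mean(ch$draws[, 1]), 0)
  expect_true(all(diff(means) > 0))
})

test_that("optional scale estimation yields positive sigma draws and sane fits", {
  set.seed(27)
  X <- cbind(1, runif(300, -1, 1))
  y <- drop(X %*% c(5, 2)) + rnorm(300)
  d <- encoded_dataset(y, X, c("(Intercept)", "x"))
  ch <- run_gibbs(d, 0.5, config = sampler_config(2000, 500, 2, seed = 41),
                  estimate_scale = TRUE)
  expect_length(ch$sigma_draws, nrow(ch$draws))
  expect_true(all(ch$sigma_draws > 0))
  expect_lt(abs(mean(ch$draws[, 2]) - 2), 0.3)
  # default sampler carries no sigma draws
  ch0 <- run_gibbs(d, 0.5, config = sampler_config(500, 100, 2, seed = 42))
  expect_null(ch0$sigma_draws)
})

test_that("chain CSV export is draw-by-draw with labeled header", {
  d <- simulate_ald_data(100, 0.5, seed = 6)
  ch <- run_gibbs(d, 0.5, config = sampler_config(400, 100, 3, seed = 1))
  f <- tempfile(fileext = ".csv")
  write_chain_csv(ch, f)
  got <- read.csv(f, check.names = FALSE)
  expect_equal(names(got), ch$column_labels)
  expect_equal(as.matrix(got), ch$draws, ignore_attr = TRUE)
  unlink(f)
})
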