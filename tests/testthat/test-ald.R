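test_that("check loss follows the two formula branches and vanishes only at zero", {
  expect_equal(check_loss(0, 0.3), 0)
  expect_equal(check_loss(1, 0.3), 0.3)
  expect_equal(check_loss(-1, 0.3), 0.7)
  w <- seq(-3, 3, by = 0.25)
  for (tau in default_taus()) {
    v <- check_loss(w, tau)
    expect_true(all(v >= 0))
    expect_identical(v == 0, w == 0)
  }
  expect_error(check_loss(1, 0), "tau")
  expect_error(check_loss(1, 1.2), "tau")
})

test_that("summed check loss is minimized at the sample quantile (grid oracle)", {
  obs <- c(1, 2, 3, 10)
  grid <- seq(0, 12, by = 0.01)
  total <- vapply(grid, function(b) sum(check_loss(obs - b, 0.5)), 0)
  argmin <- grid[total == min(total)]
  # tau = 0.5 with even n: any point of the median interval [2, 3]
  expect_true(all(argmin >= 2 & argmin <= 3))
  expect_true(min(argmin) == 2 && max(argmin) == 3)
})

test_that("check loss is convex and positively homogeneous", {
  set.seed(42)
  for (i in 1:25) {
    tau <- runif(1, 0.02, 0.98)
    w1 <- runif(1, -5, 5); w2 <- runif(1, -5, 5)
    lam <- runif(1)
    expect_lte(check_loss(lam * w1 + (1 - lam) * w2, tau),
               lam * check_loss(w1, tau) + (1 - lam) * check_loss(w2, tau) +
                 1e-12)
    cc <- runif(1, 0.1, 10)
    expect_equal(check_loss(cc * w1, tau), cc * check_loss(w1, tau))
  }
})

test_that("mixture constants match their closed forms and antisymmetry", {
  mc <- mixture_constants(0.5)
  expect_equal(mc$gamma, 0)
  expect_equal(mc$h, sqrt(8))
  mc05 <- mixture_constants(0.05)
  expect_equal(mc05$gamma, 0.9 / 0.0475)
  expect_equal(mc05$h, sqrt(2 / 0.0475))
  expect_equal(mixture_constants(0.25)$gamma, -mixture_constants(0.75)$gamma)
  expect_error(mixture_constants(1), "tau")
})

test_that("ALD density is a proper density with the right quantile at its location", {
  expect_equal(ald_density(0, tau = 0.5), 0.25)
  for (tau in default_taus()) {
    mass <- integrate(ald_density, -Inf, Inf, tau = tau,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-6)
    below <- integrate(ald_density, -Inf, 0, tau = tau,
                       rel.tol = 1e-10)$value
    expect_equal(below, tau, tolerance = 1e-6)
    # closed-form CDF consistent with quadrature of the density
    expect_equal(ald_cdf(0.7, tau),
                 integrate(ald_density, -Inf, 0.7, tau = tau,
                           rel.tol = 1e-10)$value,
                 tolerance = 1e-6)
  }
  expect_error(ald_density(0, 0.5, scale = -1), "scale")
})

test_that("mixture draws have the advertised quantile and mean", {
  d <- sample_ald_via_mixture(1e5, 0.5, seed = 11)
  expect_lt(abs(median(d)), 0.02)
  d25 <- sample_ald_via_mixture(1e5, 0.25, seed = 12)
  expect_lt(abs(mean(d25 <= 0) - 0.25), 0.005)
  for (tau in c(0.1, 0.5, 0.9)) {
    d <- sample_ald_via_mixture(1e5, tau, seed = 13)
    se <- sd(d) / sqrt(length(d))
    expect_lt(abs(mean(d) - mixture_constants(tau)$gamma), 4 * se)
  }
  expect_error(sample_ald_via_mixture(0, 0.5), "count")
})

test_that("mixture draws match inverse-CDF ALD draws in distribution", {
  n <- 1e4
  for (i in seq_along(default_taus())) {
    tau <- default_taus()[i]
    mix <- sample_ald_via_mixture(n, tau, seed = 100 + i)
    set.seed(200 + i)
    ref <- r_ald_invcdf(n, tau)
    ks <- suppressWarnings(ks.test(mix, ref))
    # two-sample 1% critical value
    expect_lt(unname(ks$statistic), 1.6276 * sqrt(2 / n))
  }
})

test_that("empirical quantiles are invariant under monotone transformation", {
  d <- sample_ald_via_mixture(2e4, 0.75, seed = 31)
  for (tau in default_taus()) {
    expect_equal(unname(quantile(exp(d), tau, type = 1)),
                 exp(unname(quantile(d, tau, type = 1))),
                 tolerance = 1e-10)
  }
})

test_that("location and scale shift draws and density consistently", {
  d <- sample_ald_via_mixture(5e4, 0.25, location = 10, scale = 2, seed = 8)
  expect_lt(abs(mean(d <= 10) - 0.25), 0.01)
  expect_equal(ald_density(10, 0.25, location = 10, scale = 2),
               0.25 * 0.75 / 2)
})
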