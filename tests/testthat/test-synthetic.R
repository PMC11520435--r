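test_that("default schema carries the published marginals and supports", {
  sc <- default_schema()
  expect_equal(sc$categorical$sex$probs, c(2719, 2604) / 5323)
  expect_equal(round(sc$categorical$sex$probs, 3), c(0.511, 0.489))
  expect_equal(round(sc$categorical$residence$probs, 3), c(0.231, 0.769))
  expect_equal(sc$continuous$child_age_months$lower, 0)
  expect_equal(sc$continuous$child_age_months$upper, 59)
  expect_equal(sc$continuous$maternal_age_years$lower, 15)
  expect_equal(sc$continuous$maternal_age_years$upper, 49)
  expect_length(sc$categorical, 13)
  for (v in sc$categorical) expect_lt(abs(sum(v$probs) - 1), 1e-9)
  expect_error(covariate_schema(list(x = list(labels = c("a", "b"),
                                              probs = c(0.6, 0.3),
                                              reference = "a")),
                                list()), "sum to 1")
  expect_error(covariate_schema(list(), list(z = list(lower = 2, upper = 1,
                                                      dist = "uniform"))),
               "ordered")
})

test_that("generated covariates respect every categorical marginal simultaneously", {
  n <- 5323
  tab <- generate_covariates(n, seed = 61)
  sc <- default_schema()
  expect_equal(nrow(tab), n)
  for (nm in names(sc$categorical)) {
    v <- sc$categorical[[nm]]
    obs <- as.numeric(table(tab[[nm]])[v$labels]) / n
    se <- sqrt(v$probs * (1 - v$probs) / n)
    expect_true(all(abs(obs - v$probs) <= 4 * se),
                label = paste("marginal fidelity for", nm))
  }
  expect_true(all(tab$child_age_months %in% 0:59))
  expect_true(all(tab$maternal_age_years %in% 15:49))
})

test_that("covariate generation is reproducible and works at n = 1", {
  one <- generate_covariates(1, seed = 62)
  expect_equal(nrow(one), 1)
  expect_false(anyNA(one))
  expect_identical(generate_covariates(200, seed = 63),
                   generate_covariates(200, seed = 63))
  expect_error(generate_covariates(0), "count")
})

test_that("outcome generator honors its noise models", {
  # degenerate scale: homoscedastic, all taus share the slope truth
  m0 <- outcome_model(c(15, 2), c(1, 0), noise = "gaussian")
  tr <- true_quantile_coefs(m0)
  expect_true(all(tr[2, ] == 2))
  # intercept-only gaussian: empirical 5th percentile near 15 + qnorm(0.05)
  X1 <- matrix(1, 2e4, 1)
  y <- generate_outcome_from_design(X1, outcome_model(15, 1, "gaussian"),
                                    seed = 64)
  expect_equal(unname(quantile(y, 0.05)), 15 + qnorm(0.05), tolerance = 0.005)
  # ALD noise at tau = 0.25: a quarter of residuals fall below the line
  yald <- generate_outcome_from_design(
    X1, outcome_model(15, 1, "ald", tau_for_ald = 0.25), seed = 65)
  expect_lt(abs(mean(yald - 15 < 0) - 0.25), 0.01)
  # non-positive scale predictor errors with the offending row
  Xbad <- cbind(1, c(0, 0, -3))
  expect_error(generate_outcome_from_design(
    Xbad, outcome_model(c(1, 0), c(1, 0.5), "gaussian")), "row 3")
})

test_that("implied true quantile coefficients are monotone for positive scale coefs", {
  m <- outcome_model(c(10, 1, -2), c(1, 0.5, 0.2), noise = "gaussian")
  tr <- true_quantile_coefs(m, default_taus())
  for (j in 1:3) expect_true(all(diff(tr[j, ]) > 0))
  # ALD-noise truth passes through beta_loc at its own tau
  ma <- outcome_model(c(10, 1), c(0.5, 0), noise = "ald", tau_for_ald = 0.25)
  expect_equal(unname(true_quantile_coefs(ma, 0.25)[, 1]), c(10, 1))
})

test_that("fixtures bundle data, truth map, and reproduce under a seed", {
  fx <- make_fixture(n = 400, seed = 66)
  expect_equal(ncol(fx$truth), 6)
  expect_equal(colnames(fx$truth),
               c("tau_0.05", "tau_0.25", "tau_0.5", "tau_0.75",
                 "tau_0.85", "tau_0.95"))
  expect_s3_class(fx$data, "bqr_data")
  expect_equal(fx$data$n, 400)
  fx2 <- make_fixture(n = 400, seed = 66)
  expect_identical(fx$truth, fx2$truth)
  expect_identical(fx$table, fx2$table)
})

test_that("fixture roundtrips through CSV with a truth sidecar", {
  fx <- make_fixture(n = 50, seed = 67)
  stem <- tempfile("fx")
  write_fixture(fx, stem)
  tab <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(tab), 50)
  truth <- yaml::read_yaml(paste0(stem, "_truth.yaml"))
  expect_equal(truth$seed, 67)
  expect_equal(truth$location_coefs, c(15.3, 1.0, -0.5))
  expect_equal(truth$noise, "ald")
  unlink(paste0(stem, c(".csv", "_truth.yaml")))
})
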