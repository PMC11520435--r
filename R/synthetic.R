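#' Build a covariate schema
#'
#' A schema lists, for every categorical variable, its category labels,
#' marginal proportions and reference category (the level absorbed into
#' the intercept), and for every continuous variable its support and
#' sampling distribution.  It drives both the synthetic generator and
#' the design encoding.
#'
#' @param categorical named list; each element a list with `labels`
#'   (character), `probs` (numeric, summing to 1 within 1e-9) and
#'   `reference` (one of the labels).
#' @param continuous named list; each element a list with `lower`,
#'   `upper` (ordered bounds) and `dist` (currently
#'   `"discrete_uniform"` or `"uniform"`).
#' @return object of class `bqr_schema`.
#' @export
covariate_schema <- function(categorical, continuous) {
  for (nm in names(categorical)) {
    v <- categorical[[nm]]
    if (length(v$labels) != length(v$probs)) {
      stop("schema '", nm, "': labels and probs differ in length",
           call. = FALSE)
    }
    if (abs(sum(v$probs) - 1) > 1e-9) {
      stop("schema '", nm, "': proportions must sum to 1", call. = FALSE)
    }
    if (!v$reference %in% v$labels) {
      stop("schema '", nm, "': reference not among labels", call. = FALSE)
    }
  }
  for (nm in names(continuous)) {
    v <- continuous[[nm]]
    if (v$lower >= v$upper) {
      stop("schema '", nm, "': bounds must be ordered", call. = FALSE)
    }
    if (!v$dist %in% c("discrete_uniform", "uniform")) {
      stop("schema '", nm, "': unknown distribution tag", call. = FALSE)
    }
  }
  structure(list(categorical = categorical, continuous = continuous),
            class = "bqr_schema")
}

#' Default EMDHS-like covariate schema
#'
#' All child-level variables of the survey analysis, with categorical
#' marginal proportions taken from the published frequency table
#' (counts over n = 5,323) and the printed continuous supports: child
#' age 0-59 months, maternal age 15-49 years.  Regional shares are not
#' printed in that table; the defaults are plausible Mini-DHS-like
#' shares with the small regions oversampled.  Reference categories
#' match the regression table (male, urban, Tigray, Orthodox, poorest,
#' no formal education, improved facilities, singleton, not married,
#' ever-but-not-currently breastfed, smallest household classes).
#'
#' @return a `bqr_schema`.
#' @export
default_schema <- function() {
  cat <- list(
    sex = list(labels = c("Male", "Female"),
               probs = c(2719, 2604) / 5323, reference = "Male"),
    residence = list(labels = c("Urban", "Rural"),
                     probs = c(1230, 4093) / 5323, reference = "Urban"),
    maternal_education = list(
      labels = c("No formal education", "Primary", "Secondary and above"),
      probs = c(2914, 1672, 737) / 5323,
      reference = "No formal education"),
    marital_status = list(labels = c("Not married", "Married"),
                          probs = c(361, 4962) / 5323,
                          reference = "Not married"),
    wealth_index = list(
      labels = c("Poorest", "Poorer", "Middle", "Richer", "Richest"),
      probs = c(1806, 924, 742, 691, 1160) / 5323, reference = "Poorest"),
    religion = list(labels = c("Orthodox", "Protestant", "Muslim", "Others"),
                    probs = c(1518, 987, 2714, 104) / 5323,
                    reference = "Orthodox"),
    breastfeeding = list(
      labels = c("Ever breastfed, not currently", "Never breastfed",
                 "Still breastfeeding"),
      probs = c(2893, 225, 2205) / 5323,
      reference = "Ever breastfed, not currently"),
    birth_type = list(labels = c("Singleton", "Multiple"),
                      probs = c(5200, 123) / 5323, reference = "Singleton"),
    household_size = list(labels = c("<=4", "5-9", "10+"),
                          probs = c(1454, 3485, 384) / 5323,
                          reference = "<=4"),
    under5_children = list(labels = c("Less than two", "Two",
                                      "Three or more"),
                           probs = c(2023, 2380, 920) / 5323,
                           reference = "Less than two"),
    water_source = list(labels = c("Improved", "Unimproved"),
                        probs = c(3272, 2051) / 5323,
                        reference = "Improved"),
    toilet_facility = list(labels = c("Improved", "Unimproved"),
                           probs = c(1072, 4251) / 5323,
                           reference = "Improved"),
    region = list(
      labels = c("Tigray", "Afar", "Amhara", "Oromia", "Somali",
                 "Benishangul-Gumuz", "SNNPR", "Gambela", "Harari",
                 "Addis Ababa", "Dire Dawa"),
      probs = c(0.08, 0.08, 0.10, 0.14, 0.10, 0.08, 0.13, 0.07, 0.07,
                0.07, 0.08),
      reference = "Tigray")
  )
  cont <- list(
    child_age_months = list(lower = 0, upper = 59,
                            dist = "discrete_uniform"),
    maternal_age_years = list(lower = 15, upper = 49,
                              dist = "discrete_uniform")
  )
  covariate_schema(cat, cont)
}

#' Draw a synthetic child-level covariate table
#'
#' Categorical variables are drawn independently from their schema
#' marginals; continuous variables uniformly (discrete or continuous)
#' over their stated supports.  Independence between covariates is a
#' deliberate simplification: the regression conditions on the design,
#' so between-covariate dependence is not needed for correctness
#' testing.
#'
#' @param n number of rows (>= 1).
#' @param schema a `bqr_schema`; default [default_schema()].
#' @param seed integer seed.
#' @return data.frame with one factor column per categorical variable
#'   (levels in schema order) and one numeric column per continuous
#'   variable.
#' @export
generate_covariates <- function(n, schema = default_schema(), seed = 1L) {
  stopifnot(inherits(schema, "bqr_schema"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  set.seed(seed)
  out <- list()
  for (nm in names(schema$categorical)) {
    v <- schema$categorical[[nm]]
    out[[nm]] <- factor(sample(v$labels, n, replace = TRUE, prob = v$probs),
                        levels = v$labels)
  }
  for (nm in names(schema$continuous)) {
    v <- schema$continuous[[nm]]
    out[[nm]] <- if (v$dist == "discrete_uniform") {
      sample(seq(v$lower, v$upper), n, replace = TRUE)
    } else {
      stats::runif(n, v$lower, v$upper)
    }
  }
  as.data.frame(out, check.names = FALSE)
}

#' Specify a data-generating outcome model
#'
#' The generating truth is a location-scale regression
#' \eqn{y = X\beta_{loc} + (X\beta_{scale}) \cdot z}, with z standard
#' normal or standardized asymmetric Laplace noise.  For gaussian noise
#' the implied true coefficient vector at quantile level tau is
#' \eqn{\beta_{loc} + \beta_{scale} \Phi^{-1}(\tau)}; for ALD noise at
#' level tau0 it is \eqn{\beta_{loc} + \beta_{scale} F^{-1}_{tau0}(\tau)}
#' (so at tau = tau0 the truth is exactly beta_loc, since the ALD noise
#' has tau0-quantile zero).
#'
#' @param location_coefs numeric vector beta_loc (length p of the
#'   intended design).
#' @param scale_coefs numeric vector beta_scale, same length; the scale
#'   linear predictor must be positive over the covariate support
#'   (checked at generation time).
#' @param noise `"gaussian"` or `"ald"`.
#' @param tau_for_ald quantile level of the ALD noise (required when
#'   `noise = "ald"`).
#' @return object of class `bqr_outcome_model`.
#' @export
outcome_model <- function(location_coefs, scale_coefs,
                          noise = c("gaussian", "ald"),
                          tau_for_ald = NULL) {
  noise <- match.arg(noise)
  stopifnot(length(location_coefs) == length(scale_coefs))
  if (noise == "ald") {
    if (is.null(tau_for_ald)) stop("tau_for_ald required for ALD noise",
                                   call. = FALSE)
    assert_tau(tau_for_ald)
  }
  structure(list(location_coefs = location_coefs,
                 scale_coefs = scale_coefs, noise = noise,
                 tau_for_ald = tau_for_ald),
            class = "bqr_outcome_model")
}

#' True quantile-level coefficients implied by an outcome model
#'
#' @param model a `bqr_outcome_model`.
#' @param tau quantile level(s).
#' @return matrix with one column per tau (rows = coefficients).
#' @export
true_quantile_coefs <- function(model, tau = default_taus()) {
  stopifnot(inherits(model, "bqr_outcome_model"))
  assert_tau(tau)
  q <- if (model$noise == "gaussian") {
    stats::qnorm(tau)
  } else {
    ald_quantile(tau, model$tau_for_ald)
  }
  out <- vapply(q, function(qq) model$location_coefs + model$scale_coefs * qq,
                numeric(length(model$location_coefs)))
  colnames(out) <- tau_label(tau)
  out
}

#' Generate outcomes from a design matrix under a generating model
#'
#' @param design n x p numeric matrix (intercept included).
#' @param model a `bqr_outcome_model` with coefficients of length p.
#' @param seed integer seed.
#' @return numeric outcome vector of length n.
#' @export
generate_outcome_from_design <- function(design, model, seed = 1L) {
  stopifnot(inherits(model, "bqr_outcome_model"),
            ncol(design) == length(model$location_coefs))
  loc <- drop(design %*% model$location_coefs)
  scl <- drop(design %*% model$scale_coefs)
  bad <- which(scl < 0 | (scl == 0 & any(model$scale_coefs != 0)))
  if (length(bad) > 0 && any(scl[bad] < 0)) {
    stop("non-positive scale linear predictor at row ",
         which(scl < 0)[1L], call. = FALSE)
  }
  set.seed(seed)
  z <- if (model$noise == "gaussian") {
    stats::rnorm(nrow(design))
  } else {
    sample_ald_via_mixture(nrow(design), model$tau_for_ald)
  }
  loc + scl * z
}

#' Generate a BMI outcome for a covariate table
#'
#' Encodes the covariates against the schema (intercept + reference
#' dummies, continuous pass-through) and applies the generating model.
#'
#' @param covariates table from [generate_covariates()].
#' @param model a `bqr_outcome_model` whose coefficient length matches
#'   the encoded design width.
#' @param schema the schema used for encoding.
#' @param seed integer seed.
#' @return numeric BMI vector.
#' @export
generate_outcome <- function(covariates, model, schema = default_schema(),
                             seed = 1L) {
  design <- encode_design(covariates, schema)$design
  generate_outcome_from_design(design, model, seed = seed)
}

#' Make a complete synthetic test fixture
#'
#' One call yields a child-level table with a BMI column, the encoded
#' dataset ready for fitting, the generating model, and the exact true
#' coefficient map at the six default quantile levels.  The default
#' truth places the median BMI near 15.3 kg/m^2, echoing the scale of
#' the survey's percentile table without claiming to reproduce it.
#'
#' The fixture design is deliberately small (intercept, a centered
#' child-age score on [-1, 1], and a sex dummy) so that recovery tests
#' are sharp at moderate n.
#'
#' @param n number of children.
#' @param seed integer seed (drives covariates and noise).
#' @param noise `"ald"` (default, homoscedastic standardized ALD with
#'   scale 0.5) or `"gaussian"` (mildly heteroscedastic location-scale).
#' @param tau_for_ald quantile level of the ALD noise.
#' @return list with `table` (data.frame incl. `bmi`), `data`
#'   (`bqr_data`), `model`, `truth` (matrix from
#'   [true_quantile_coefs()]), `seed`.
#' @export
make_fixture <- function(n = 2000L, seed = 1L,
                         noise = c("ald", "gaussian"),
                         tau_for_ald = 0.5) {
  noise <- match.arg(noise)
  set.seed(seed)
  age_score <- stats::runif(n, -1, 1)
  sex <- factor(sample(c("Male", "Female"), n, replace = TRUE,
                       prob = c(0.511, 0.489)), levels = c("Male", "Female"))
  design <- cbind("(Intercept)" = 1, age_score = age_score,
                  "sex:Female" = as.numeric(sex == "Female"))
  model <- if (noise == "ald") {
    outcome_model(location_coefs = c(15.3, 1.0, -0.5),
                  scale_coefs = c(0.5, 0, 0),
                  noise = "ald", tau_for_ald = tau_for_ald)
  } else {
    outcome_model(location_coefs = c(15.3, 1.0, -0.5),
                  scale_coefs = c(0.5, 0.25, 0),
                  noise = "gaussian")
  }
  bmi <- generate_outcome_from_design(design, model,
                                      seed = tau_seed(seed, 2L))
  tab <- data.frame(age_score = age_score, sex = sex, bmi = bmi)
  data <- encoded_dataset(bmi, design)
  list(table = tab, data = data, model = model,
       truth = true_quantile_coefs(model), seed = seed)
}

#' Write a fixture to disk as CSV plus a truth sidecar
#'
#' The table goes to `<stem>.csv`; the generating truth (coefficients,
#' noise model, seed) to `<stem>_truth.yaml`.
#'
#' @param fixture list from [make_fixture()].
#' @param stem output path stem (no extension).
#' @return invisibly, the two paths written.
#' @export
write_fixture <- function(fixture, stem) {
  csv <- paste0(stem, ".csv")
  truth <- paste0(stem, "_truth.yaml")
  utils::write.csv(fixture$table, csv, row.names = FALSE)
  yaml::write_yaml(list(
    location_coefs = as.numeric(fixture$model$location_coefs),
    scale_coefs = as.numeric(fixture$model$scale_coefs),
    noise = fixture$model$noise,
    tau_for_ald = fixture$model$tau_for_ald,
    seed = fixture$seed,
    true_quantile_coefs = lapply(
      as.data.frame(fixture$truth), as.numeric)
  ), truth)
  invisible(c(csv, truth))
}
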