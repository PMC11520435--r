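#' Round half away from zero
#'
#' Published survey tables round 5s upward (12.25 -> 12.3), unlike R's
#' banker's rounding; this helper reproduces that convention.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Body mass index
#'
#' Weight in kilograms divided by squared height in meters.
#'
#' @param weight_kg positive weight(s), kg.
#' @param height_m positive height(s), m.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(10, 0.8)  # 15.625
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight_kg / height_m^2
}

#' Frequency table with printed-style percentages
#'
#' Counts per category with percentages 100 * count / n, rounded half
#' up to one decimal — the convention of the survey's descriptive
#' table.
#'
#' @param column categorical vector (factor or character), or a named
#'   numeric vector of pre-tabulated counts.
#' @return data.frame with columns `category`, `count`, `percentage`.
#' @export
frequency_table <- function(column) {
  if (length(column) == 0L) stop("empty input", call. = FALSE)
  counts <- if (is.numeric(column) && !is.null(names(column))) {
    column
  } else {
    tab <- table(column)
    stats::setNames(as.numeric(tab), names(tab))
  }
  n <- sum(counts)
  data.frame(category = names(counts),
             count = as.numeric(counts),
             percentage = round_half_up(100 * as.numeric(counts) / n, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage of a part over a whole, printed-style
#'
#' @param part,whole nonnegative scalars, whole > 0.
#' @param digits decimal places of the half-up rounding (0 gives the
#'   integer percentage used for e.g. the household response rate).
#' @return rounded percentage.
#' @examples
#' percentage(8663, 8794, digits = 0)  # 99
#' @export
percentage <- function(part, whole, digits = 0) {
  stopifnot(whole > 0, part >= 0)
  round_half_up(100 * part / whole, digits)
}

#' Empirical percentile table at the six reporting levels
#'
#' Percentiles 5, 25, 50, 75, 85, 95 under the sorted-order linear
#' interpolation convention (quantile type 7), the dominant software
#' default; reproduces the conventional median 50.5 for 1..100.
#'
#' @param values numeric vector, length >= 2.
#' @param levels percentile levels in (0, 100).
#' @return data.frame of class `bqr_percentiles` with columns `level`,
#'   `value` (non-decreasing in level).
#' @export
percentile_table <- function(values, levels = c(5, 25, 50, 75, 85, 95)) {
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  if (anyNA(values)) stop("values must not contain NA", call. = FALSE)
  v <- stats::quantile(values, probs = levels / 100, type = 7, names = FALSE)
  out <- data.frame(level = levels, value = v)
  class(out) <- c("bqr_percentiles", "data.frame")
  out
}

#' Within-sample weight-status classification
#'
#' Classifies each BMI value against the sample's own 5th, 85th and
#' 95th percentiles: underweight below the 5th; normal from the 5th up
#' to (not including) the 85th; overweight from the 85th up to (not
#' including) the 95th; obese at or above the 95th.  The three cutoffs
#' may also be supplied directly (e.g. the published 12.92 / 17.06 /
#' 18.27 kg/m^2).
#'
#' @param values numeric BMI vector (length >= 20 unless cutoffs are
#'   supplied).
#' @param cutoffs optional numeric vector c(p5, p85, p95).
#' @return list with `status` (factor underweight/normal/overweight/
#'   obese, one level per value) and `cutoffs` (named numeric vector).
#' @export
classify_weight_status <- function(values, cutoffs = NULL) {
  if (is.null(cutoffs)) {
    if (length(values) < 20L) {
      stop("need at least 20 values for within-sample percentiles",
           call. = FALSE)
    }
    pt <- percentile_table(values, levels = c(5, 85, 95))
    cutoffs <- pt$value
  }
  stopifnot(length(cutoffs) == 3L, !is.unsorted(cutoffs))
  names(cutoffs) <- c("p5", "p85", "p95")
  status <- cut(values,
                breaks = c(-Inf, cutoffs, Inf),
                labels = c("underweight", "normal", "overweight", "obese"),
                right = FALSE)
  list(status = status, cutoffs = cutoffs)
}

#' Data behind a normality check of the outcome
#'
#' Exports what is needed to redraw a histogram and a normal Q-Q plot,
#' plus the standard moment estimator of skewness
#' \eqn{m_3 / m_2^{3/2}}.
#'
#' @param values numeric vector, length >= 20, nonzero variance.
#' @return list with `histogram` (data.frame mid/count), `qq`
#'   (data.frame theoretical/sample), `skewness` (scalar).
#' @export
normality_report <- function(values) {
  if (length(values) < 20L) stop("need at least 20 values", call. = FALSE)
  if (stats::var(values) == 0) stop("zero-variance input", call. = FALSE)
  h <- graphics::hist(values, plot = FALSE)
  qq <- stats::qqnorm(values, plot.it = FALSE)
  ord <- order(qq$x)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  list(histogram = data.frame(mid = h$mids, count = h$counts),
       qq = data.frame(theoretical = qq$x[ord], sample = qq$y[ord]),
       skewness = m3 / m2^1.5)
}
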