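#' Summarize a posterior chain into a coefficient table
#'
#' Posterior mean and equal-tailed credible interval per coefficient,
#' with a significance flag set when the interval excludes zero — the
#' reporting convention of the multi-quantile coefficient table.
#'
#' @param chain a `bqr_chain`.
#' @param level credible level in (0, 1); default 0.95.
#' @return data.frame of class `bqr_summary` with columns `label`,
#'   `posterior_mean`, `ci_low`, `ci_high`, `significant`, plus
#'   attribute `tau`.
#' @export
summarize_chain <- function(chain, level = 0.95) {
  stopifnot(inherits(chain, "bqr_chain"))
  if (nrow(chain$draws) < 2L) stop("chain is empty or degenerate",
                                   call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  alpha <- (1 - level) / 2
  qs <- apply(chain$draws, 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  lo <- qs[1L, ]; hi <- qs[2L, ]
  if (any(lo >= hi)) {
    stop("degenerate credible interval (constant chain?)", call. = FALSE)
  }
  out <- data.frame(label = chain$column_labels,
                    posterior_mean = colMeans(chain$draws),
                    ci_low = lo, ci_high = hi,
                    significant = lo > 0 | hi < 0,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tau") <- chain$tau
  class(out) <- c("bqr_summary", "data.frame")
  out
}

#' Empirical autocorrelation function
#'
#' Standard sample autocorrelation with overall-mean centering and the
#' 1/n denominator; value at lag 0 is exactly 1.
#'
#' @param series numeric vector, longer than `max_lag`.
#' @param max_lag largest lag to report.
#' @return numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
autocorrelation <- function(series, max_lag = 20L) {
  n <- length(series)
  if (n <= max_lag) stop("series must be longer than max_lag", call. = FALSE)
  if (stats::var(series) == 0) {
    stop("autocorrelation undefined for a zero-variance series",
         call. = FALSE)
  }
  drop(stats::acf(series, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf)
}

#' Heuristic convergence report
#'
#' Two numeric indicators per coefficient — autocorrelation decay
#' (|acf| at the reporting lag) and the split-chain standardized mean
#' difference (first vs second half).  Advisory only: nothing gates on
#' it; the intended assessment remains visual inspection of the trace,
#' density and autocorrelation plots.
#'
#' @param chain a `bqr_chain`.
#' @param lag lag at which residual autocorrelation is reported.
#' @return data.frame with columns `label`, `acf_at_lag`,
#'   `split_mean_z`.
#' @export
convergence_heuristics <- function(chain, lag = 10L) {
  stopifnot(inherits(chain, "bqr_chain"))
  m <- nrow(chain$draws)
  half <- m %/% 2L
  out <- lapply(seq_len(ncol(chain$draws)), function(j) {
    x <- chain$draws[, j]
    a <- autocorrelation(x, max_lag = lag)[lag + 1L]
    z <- (mean(x[seq_len(half)]) - mean(x[(half + 1L):m])) /
      (stats::sd(x) / sqrt(half))
    data.frame(label = chain$column_labels[j], acf_at_lag = a,
               split_mean_z = z, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# sanitize a coefficient label for use inside a filename
label_slug <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Export per-coefficient diagnostic data and plots
#'
#' For every coefficient of the chain, writes three CSV payloads —
#' trace (iteration, value), Gaussian-kernel density curve
#' (rule-of-thumb bandwidth), and autocorrelation (lag, acf) — plus one
#' PNG per family (trace, density, autocorrelation).  Filenames encode
#' the quantile level and coefficient label.
#'
#' @param chain a `bqr_chain`.
#' @param out_dir writable output directory (created if absent).
#' @param max_lag autocorrelation lags exported.
#' @param plots logical; also render PNG images (default TRUE).
#' @return invisibly, character vector of files written.
#' @export
export_diagnostics <- function(chain, out_dir, max_lag = 30L,
                               plots = TRUE) {
  stopifnot(inherits(chain, "bqr_chain"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir,
                                 call. = FALSE)
  tau_tag <- paste0("tau", gsub("\\.", "p", format(chain$tau, trim = TRUE)))
  files <- character(0)
  for (j in seq_len(ncol(chain$draws))) {
    x <- chain$draws[, j]
    slug <- paste0(tau_tag, "_", label_slug(chain$column_labels[j]))

    f_trace <- file.path(out_dir, paste0("trace_", slug, ".csv"))
    utils::write.csv(data.frame(iteration = seq_along(x), value = x),
                     f_trace, row.names = FALSE)

    dens <- stats::density(x, bw = "nrd0", kernel = "gaussian")
    f_dens <- file.path(out_dir, paste0("density_", slug, ".csv"))
    utils::write.csv(data.frame(value = dens$x, density = dens$y),
                     f_dens, row.names = FALSE)

    a <- autocorrelation(x, max_lag = min(max_lag, length(x) - 1L))
    f_acf <- file.path(out_dir, paste0("acf_", slug, ".csv"))
    utils::write.csv(data.frame(lag = seq_along(a) - 1L, acf = a),
                     f_acf, row.names = FALSE)

    files <- c(files, f_trace, f_dens, f_acf)

    if (plots) {
      lbl <- chain$column_labels[j]
      f_png <- file.path(out_dir, paste0("diag_", slug, ".png"))
      grDevices::png(f_png, width = 1200, height = 400)
      op <- graphics::par(mfrow = c(1, 3))
      graphics::plot(x, type = "l", xlab = "retained draw", ylab = lbl,
                     main = paste0("Trace (tau=", chain$tau, ")"))
      graphics::plot(dens, main = "Posterior density", xlab = lbl)
      graphics::plot(seq_along(a) - 1L, a, type = "h", xlab = "lag",
                     ylab = "ACF", ylim = c(-0.2, 1),
                     main = "Autocorrelation")
      graphics::abline(h = 0)
      graphics::par(op)
      grDevices::dev.off()
      files <- c(files, f_png)
    }
  }
  invisible(files)
}
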