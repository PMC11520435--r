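#' Encode a child-level table into a regression design
#'
#' Builds the design matrix the quantile regression uses: intercept
#' first, continuous variables passed through unscaled, then one dummy
#' per non-reference category, labeled `"variable:Category"`.  Rows
#' with missing values in any schema variable (or the outcome, when
#' present) are dropped and counted.
#'
#' @param table data.frame containing every schema variable (and
#'   optionally an outcome column).
#' @param schema a `bqr_schema`.
#' @param outcome_col name of the outcome column; used when present.
#' @return list with `design` (n x p matrix), `column_labels`,
#'   `outcome` (numeric or NULL), `dropped` (row count removed), and
#'   `data` (a `bqr_data`, when the outcome column is present).
#' @export
encode_design <- function(table, schema = default_schema(),
                          outcome_col = "bmi") {
  stopifnot(inherits(schema, "bqr_schema"))
  vars <- c(names(schema$continuous), names(schema$categorical))
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars) > 0) {
    stop("table lacks schema variables: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  has_outcome <- outcome_col %in% names(table)
  check_cols <- c(vars, if (has_outcome) outcome_col)
  complete <- stats::complete.cases(table[check_cols])
  dropped <- sum(!complete)
  tab <- table[complete, , drop = FALSE]

  cols <- list("(Intercept)" = rep(1, nrow(tab)))
  for (nm in names(schema$continuous)) {
    cols[[nm]] <- as.numeric(tab[[nm]])
  }
  for (nm in names(schema$categorical)) {
    v <- schema$categorical[[nm]]
    obs <- as.character(tab[[nm]])
    unknown <- which(!obs %in% v$labels)
    if (length(unknown) > 0) {
      stop("unknown category '", obs[unknown[1L]], "' in variable '", nm,
           "' at row ", unknown[1L], call. = FALSE)
    }
    for (lab in setdiff(v$labels, v$reference)) {
      cols[[paste0(nm, ":", lab)]] <- as.numeric(obs == lab)
    }
  }
  design <- do.call(cbind, cols)
  colnames(design) <- names(cols)
  out <- list(design = design, column_labels = colnames(design),
              outcome = if (has_outcome) as.numeric(tab[[outcome_col]]),
              dropped = dropped)
  if (has_outcome) {
    out$data <- encoded_dataset(out$outcome, design)
  }
  out
}

#' Assemble and validate a run configuration
#'
#' Exactly one of `input` (a CSV path) or `synthesis` (a list with at
#' least `n`, plus optional `seed`, `model`) must be given.
#'
#' @param input optional path to a child-level CSV.
#' @param synthesis optional list: `n`, `seed` (default 1), and
#'   optionally an `outcome_model` for the BMI column.
#' @param taus quantile levels; default the six analysis levels.
#' @param prior a `bqr_prior`.
#' @param sampler a `bqr_config`.
#' @param out_dir output directory for the report bundle.
#' @param schema covariate schema.
#' @param level credible level for the coefficient table.
#' @param diagnostics_coefs how many leading coefficients get
#'   diagnostic exports per tau (0 disables them).
#' @param verbose print progress messages?
#' @return object of class `bqr_run_config`.
#' @export
run_config <- function(input = NULL, synthesis = NULL,
                       taus = default_taus(), prior = prior_spec(),
                       sampler = sampler_config(), out_dir,
                       schema = default_schema(), level = 0.95,
                       diagnostics_coefs = 3L, verbose = FALSE) {
  if (is.null(input) == is.null(synthesis)) {
    stop("exactly one of 'input' and 'synthesis' must be given",
         call. = FALSE)
  }
  if (length(taus) < 1L) stop("tau list must be nonempty", call. = FALSE)
  assert_tau(taus)
  if (!is.null(synthesis) && is.null(synthesis$n)) {
    stop("synthesis block needs n", call. = FALSE)
  }
  structure(list(input = input, synthesis = synthesis, taus = taus,
                 prior = prior, sampler = sampler, out_dir = out_dir,
                 schema = schema, level = level,
                 diagnostics_coefs = as.integer(diagnostics_coefs),
                 verbose = isTRUE(verbose)),
            class = "bqr_run_config")
}

#' Format the multi-quantile coefficient matrix
#'
#' One row per coefficient, one column per quantile level, each cell
#' `"mean [low, high]"` with a trailing `*` when the credible interval
#' excludes zero.
#'
#' @param fit a `bqr_fit` from [fit_multi_quantile()].
#' @param level credible level.
#' @param digits cell rounding.
#' @return data.frame; first column `parameter`.
#' @export
coefficient_matrix <- function(fit, level = 0.95, digits = 3) {
  stopifnot(inherits(fit, "bqr_fit"))
  sums <- lapply(fit, summarize_chain, level = level)
  out <- data.frame(parameter = sums[[1L]]$label,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sums)) {
    s <- sums[[i]]
    out[[tau_label(attr(s, "tau"))]] <-
      sprintf(paste0("%.", digits, "f [%.", digits, "f, %.", digits,
                     "f]%s"),
              s$posterior_mean, s$ci_low, s$ci_high,
              ifelse(s$significant, "*", ""))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Ingests or synthesizes a child-level table, computes the descriptive
#' layer (frequency tables, percentile table, normality data), fits all
#' requested quantile levels by Gibbs sampling, and writes a report
#' bundle: frequency and percentile CSVs, histogram/Q-Q data, the
#' multi-quantile coefficient matrix with significance markers, per-tau
#' posterior summaries, diagnostic exports, and a structured YAML log
#' with every seed and setting needed to regenerate the bundle.  Any
#' stage failure removes the partial outputs and aborts with the stage
#' name.
#'
#' @param config a `bqr_run_config`.
#' @return invisibly, a list with `table`, `fit`, `summaries`,
#'   `coefficient_matrix`, `percentiles`, `files`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "bqr_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (config$verbose) message(...)
  stage <- "setup"
  fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "ingest"
    if (!is.null(config$input)) {
      if (!file.exists(config$input)) {
        stop("input file not found: ", config$input)
      }
      tab <- utils::read.csv(config$input, stringsAsFactors = FALSE)
    } else {
      syn <- config$synthesis
      seed <- if (is.null(syn$seed)) 1L else as.integer(syn$seed)
      tab <- generate_covariates(syn$n, config$schema, seed = seed)
      model <- syn$model
      if (is.null(model)) {
        # default truth: median BMI near 15.3, mild covariate effects
        p <- ncol(encode_design(tab[1:2, , drop = FALSE],
                                config$schema)$design)
        loc <- numeric(p); names(loc) <- NULL
        loc[1] <- 15.3
        scl <- numeric(p); scl[1] <- 1.2
        model <- outcome_model(loc, scl, noise = "gaussian")
      }
      tab$bmi <- generate_outcome(tab, model, config$schema,
                                  seed = tau_seed(seed, 97L))
    }
    say("rows ingested: ", nrow(tab))

    stage <- "encode"
    enc <- encode_design(tab, config$schema)
    if (is.null(enc$data)) stop("no 'bmi' outcome column present")
    say("dropped ", enc$dropped, " incomplete rows; design is ",
        enc$data$n, " x ", enc$data$p)

    stage <- "descriptives"
    freq <- do.call(rbind, lapply(names(config$schema$categorical),
      function(nm) {
        ft <- frequency_table(tab[[nm]])
        cbind(variable = nm, ft)
      }))
    f_freq <- file.path(config$out_dir, "frequency_table.csv")
    utils::write.csv(freq, f_freq, row.names = FALSE)
    cont_cols <- intersect(c("bmi", names(config$schema$continuous)),
                           names(tab))
    pct <- do.call(rbind, lapply(cont_cols, function(nm) {
      cbind(variable = nm, percentile_table(tab[[nm]]))
    }))
    f_pct <- file.path(config$out_dir, "percentile_table.csv")
    utils::write.csv(pct, f_pct, row.names = FALSE)
    norm <- normality_report(enc$outcome)
    f_hist <- file.path(config$out_dir, "bmi_histogram.csv")
    f_qq <- file.path(config$out_dir, "bmi_qq.csv")
    utils::write.csv(norm$histogram, f_hist, row.names = FALSE)
    utils::write.csv(norm$qq, f_qq, row.names = FALSE)
    written <- c(written, f_freq, f_pct, f_hist, f_qq)

    stage <- "fit"
    fit <- fit_multi_quantile(enc$data, taus = config$taus,
                              prior = config$prior,
                              config = config$sampler)
    summaries <- lapply(fit, summarize_chain, level = config$level)
    for (i in seq_along(fit)) {
      f <- file.path(config$out_dir,
                     paste0("summary_", names(fit)[i], ".csv"))
      utils::write.csv(summaries[[i]], f, row.names = FALSE)
      written <- c(written, f)
      say("chain ", names(fit)[i], ": seed ", fit[[i]]$config$seed,
          ", retained ", nrow(fit[[i]]$draws), " draws")
    }
    cm <- coefficient_matrix(fit, level = config$level)
    f_cm <- file.path(config$out_dir, "coefficient_matrix.csv")
    utils::write.csv(cm, f_cm, row.names = FALSE)
    written <- c(written, f_cm)

    stage <- "diagnostics"
    if (config$diagnostics_coefs > 0L) {
      for (i in seq_along(fit)) {
        ch <- fit[[i]]
        sub <- ch
        keep <- seq_len(min(config$diagnostics_coefs, ncol(ch$draws)))
        sub$draws <- ch$draws[, keep, drop = FALSE]
        sub$column_labels <- ch$column_labels[keep]
        written <- c(written,
                     export_diagnostics(sub,
                       file.path(config$out_dir, "diagnostics")))
      }
    }

    stage <- "log"
    f_log <- file.path(config$out_dir, "run_log.yaml")
    yaml::write_yaml(list(
      input = config$input,
      synthesis = if (!is.null(config$synthesis))
        list(n = config$synthesis$n,
             seed = if (is.null(config$synthesis$seed)) 1L
                    else config$synthesis$seed),
      n_rows = nrow(tab), dropped = enc$dropped,
      p = enc$data$p, taus = as.numeric(config$taus),
      sampler = list(iterations = config$sampler$iterations,
                     burn_in = config$sampler$burn_in,
                     thin = config$sampler$thin,
                     master_seed = config$sampler$seed,
                     chain_seeds = vapply(seq_along(config$taus),
                       function(i) tau_seed(config$sampler$seed, i),
                       integer(1)),
                     retained_per_chain = nrow(fit[[1L]]$draws)),
      level = config$level), f_log)
    written <- c(written, f_log)

    invisible(list(table = tab, fit = fit, summaries = summaries,
                   coefficient_matrix = cm, percentiles = pct,
                   files = written))
  }, error = fail)
}
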