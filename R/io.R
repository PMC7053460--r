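#' Read a one-column sample of lifetimes
#'
#' Parses a plain-text or CSV file with one observation per line (or one
#' CSV column selected by name or index). Blank lines are skipped and a
#' single non-numeric header line is tolerated. With
#' `positive = TRUE` (the default, appropriate for lifetime models) a
#' nonpositive observation is an error naming the offending line.
#'
#' @param path file to read.
#' @param column optional CSV column name or index; `NULL` treats the
#'   file as a single column.
#' @param positive require all observations to be > 0.
#' @return numeric vector.
#' @export
read_sample <- function(path, column = NULL, positive = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!is.null(column)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (is.character(column) && !column %in% names(df)) {
      stop("column '", column, "' not found in ", path, call. = FALSE)
    }
    x <- suppressWarnings(as.numeric(df[[column]]))
    bad <- which(is.na(x))
    if (length(bad)) {
      stop("non-numeric value in column at data row ", bad[1], call. = FALSE)
    }
    lines_of <- bad
  } else {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    if (!length(keep)) stop("empty file: ", path, call. = FALSE)
    vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
    if (is.na(vals[1]) && length(keep) > 1) {   # single header line
      keep <- keep[-1]
      vals <- vals[-1]
    }
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop("non-numeric token at line ", keep[bad[1]], ": '",
           trimws(lines[keep[bad[1]]]), "'", call. = FALSE)
    }
    if (!length(vals)) stop("no observations in ", path, call. = FALSE)
    x <- vals
    if (positive && any(x <= 0)) {
      b <- which(x <= 0)[1]
      stop("nonpositive observation at line ", keep[b],
           " (lifetime models need strictly positive data)", call. = FALSE)
    }
    return(x)
  }
  if (positive && any(x <= 0)) {
    stop("nonpositive observation at data row ", which(x <= 0)[1],
         " (lifetime models need strictly positive data)", call. = FALSE)
  }
  x
}

#' Command-style drivers: fit, compare, simulate
#'
#' Thin wrappers around [fit_mle()], [compare_models()] and
#' [run_mc_study()] that read a sample from disk where relevant, write
#' CSV and JSON reports, and return the result invisibly. These are the
#' functions behind the `frlx-cli.R` script shipped in `inst/cli/`; they
#' are exported so the same entry points are scriptable from R. Every
#' stochastic run records its seed in the JSON report so it can be
#' regenerated.
#'
#' @param input path to a sample file (see [read_sample()]).
#' @param model registry model name; `models` a character vector of them.
#' @param models character vector of registry model names.
#' @param out output path stem; `<out>.csv` and `<out>.json` are
#'   written when non-`NULL`.
#' @param config a [fit_config()].
#' @return `cmd_fit`: the `frlx_fit`; `cmd_compare`: the comparison
#'   table; `cmd_simulate`: the `frlx_mc_summary` (all invisibly).
#' @name frlx-cmd
NULL

#' @rdname frlx-cmd
#' @export
cmd_fit <- function(input, model, out = NULL, config = fit_config()) {
  x <- read_sample(input)
  fit <- fit_mle(x, model, config)
  if (!is.null(out)) {
    row <- data.frame(model = fit$model, n = fit$n_obs,
                      parameter = names(fit$estimates),
                      estimate = unname(fit$estimates),
                      se = unname(fit$se),
                      loglik = fit$loglik, converged = fit$converged,
                      stringsAsFactors = FALSE)
    utils::write.csv(row, paste0(out, ".csv"), row.names = FALSE)
    jsonlite::write_json(
      list(model = fit$model, n = fit$n_obs,
           estimates = as.list(fit$estimates), se = as.list(fit$se),
           loglik = fit$loglik, converged = fit$converged),
      paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}

#' @rdname frlx-cmd
#' @export
cmd_compare <- function(input, models, out = NULL, config = fit_config()) {
  x <- read_sample(input)
  tab <- compare_models(x, models, config)
  if (!is.null(out)) {
    utils::write.csv(tab, paste0(out, ".csv"), row.names = FALSE)
    jsonlite::write_json(tab, paste0(out, ".json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(tab)
}

#' @rdname frlx-cmd
#' @param true_params named vector of true parameter values.
#' @param n vector of sample sizes.
#' @param reps replications per sample size.
#' @param seed master seed (required: simulation reports must be
#'   regenerable).
#' @export
cmd_simulate <- function(true_params, n, reps, seed, model = "frlw",
                         out = NULL) {
  cfg <- mc_config(true_params, n = n, reps = reps, seed = seed,
                   model = model)
  summ <- run_mc_study(cfg)
  if (!is.null(out)) {
    mc_table(summ, file = paste0(out, ".csv"))
    jsonlite::write_json(
      list(model = model, seed = seed, reps = reps,
           true_params = as.list(cfg$true_params),
           table = mc_table(summ)),
      paste0(out, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(summ)
}
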