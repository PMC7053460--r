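#' Log-likelihood of a registered model
#'
#' For an FRL-X model the log-likelihood of a sample
#' \eqn{x_1, \dots, x_n} is
#' \deqn{\ell(\sigma,\xi) = n\log\sigma - n\log\log(1+\sigma) +
#'   \sum_i \log f(x_i;\xi) - \sum_i \log(1+\sigma-\sigma F(x_i;\xi)),}
#' i.e. exactly \eqn{\sum_i \log g(x_i)}; the \eqn{-\log\log(1+\sigma)}
#' term is a per-observation constant and is multiplied by n. For
#' competitor models the standard sum of log densities is used. An
#' observation with zero density yields `-Inf` (not an error), which the
#' optimizer treats as an infeasible point.
#'
#' @param data numeric sample, all observations inside the support.
#' @param par named or positional parameter vector in the model's
#'   parameter order.
#' @param model a registry name (see [frlx_models()]) or registry entry.
#' @return the log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(data, par, model) {
  model <- .resolve_model(model)
  if (any(!is.finite(par)) || any(par <= 0)) return(-Inf)
  lp <- model$logpdf(data, unname(par))
  if (any(!is.finite(lp))) return(-Inf)
  sum(lp)
}

#' Score (gradient of the log-likelihood)
#'
#' Uses the model's analytic score where the registry provides one
#' (FRL-Weibull, Weibull, exponential); otherwise central finite
#' differences of [log_likelihood()]. For the FRL-Weibull the sigma
#' component is
#' \deqn{\frac{n}{\sigma} - \frac{n}{(1+\sigma)\log(1+\sigma)} -
#'   \sum_i \frac{1 - F(x_i;\xi)}{1+\sigma-\sigma F(x_i;\xi)}.}
#'
#' @inheritParams log_likelihood
#' @param numeric force finite differences even when an analytic score
#'   exists (used for cross-checking).
#' @return named gradient vector.
#' @export
score <- function(data, par, model, numeric = FALSE) {
  model <- .resolve_model(model)
  if (any(par <= model$lower)) {
    stop("score requested at a boundary point", call. = FALSE)
  }
  if (!numeric && !is.null(model$score)) {
    g <- model$score(data, unname(par))
    return(stats::setNames(g, model$par_names))
  }
  p <- unname(par)
  g <- vapply(seq_along(p), function(j) {
    h <- max(1e-6 * abs(p[j]), 1e-8)
    pp <- p; pp[j] <- p[j] + h
    pm <- p; pm[j] <- p[j] - h
    (log_likelihood(data, pp, model) - log_likelihood(data, pm, model)) /
      (2 * h)
  }, numeric(1))
  stats::setNames(g, model$par_names)
}

#' Fitting configuration
#'
#' @param start optional named/positional start vector; `NULL` uses the
#'   model's default rule (Weibull method-of-moments for the Weibull-type
#'   shape/rate, 1 for transform parameters).
#' @param lower box lower bounds (default the registry's, 1e-8).
#' @param multistart number of additional jittered starts; the best
#'   converged fit wins. Jitter is deterministic given `jitter_seed`.
#' @param jitter_seed seed for the multistart jitter.
#' @param maxit maximum L-BFGS-B iterations.
#' @param factr L-BFGS-B convergence tolerance factor.
#' @param se compute observed-information standard errors after the fit
#'   (disable for large simulation loops where only point estimates are
#'   needed).
#' @return a list of class `frlx_fit_config`.
#' @export
fit_config <- function(start = NULL, lower = NULL, multistart = 5L,
                       jitter_seed = 101L, maxit = 500L, factr = 1e7,
                       se = TRUE) {
  structure(list(start = start, lower = lower,
                 multistart = as.integer(multistart),
                 jitter_seed = as.integer(jitter_seed),
                 maxit = as.integer(maxit), factr = factr,
                 se = isTRUE(se)),
            class = "frlx_fit_config")
}

#' Maximum-likelihood fit of a registered model
#'
#' Maximises [log_likelihood()] with the box-constrained quasi-Newton
#' L-BFGS-B algorithm ([stats::optim()]); lower bounds keep all
#' parameters strictly positive and there are no upper bounds.
#' Non-finite likelihood values during the search are replaced by a
#' large penalty so the optimizer stays inside the feasible set. With
#' `multistart > 0`, deterministically jittered starts are tried as well
#' and the best converged solution returned. Non-convergence is reported
#' in the result (`converged = FALSE`), never as an exception.
#'
#' @inheritParams log_likelihood
#' @param config a [fit_config()].
#' @return an object of class `frlx_fit`: `estimates`, `se` (filled by
#'   [standard_errors()]), `loglik`, `converged`, `n_obs`, `model`,
#'   `message`.
#' @examples
#' x <- frlw_rvs(300, 0.7, 1.3, 0.4, seed = 1)
#' fit <- fit_mle(x, "frlw")
#' fit$estimates
#' @export
fit_mle <- function(data, model, config = fit_config()) {
  model <- .resolve_model(model)
  npar <- length(model$par_names)
  if (length(data) < npar) {
    stop("need at least ", npar, " observations to fit '", model$name, "'",
         call. = FALSE)
  }
  lower <- if (is.null(config$lower)) model$lower else config$lower
  start <- if (is.null(config$start)) model$start(data) else
    unname(config$start)
  start <- pmax(unname(start), lower * 2)

  negll <- function(p) {
    v <- log_likelihood(data, p, model)
    if (!is.finite(v)) 1e10 else -v
  }
  neggr <- if (!is.null(model$score)) {
    function(p) {
      v <- log_likelihood(data, p, model)
      if (!is.finite(v)) return(rep(0, npar))
      g <- model$score(data, p)
      ifelse(is.finite(g), -g, 0)
    }
  } else NULL

  starts <- list(start)
  if (config$multistart > 0L) {
    jit <- local({
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit({
        if (is.null(old)) {
          if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
      })
      set.seed(config$jitter_seed)
      replicate(config$multistart,
                start * exp(stats::rnorm(npar, sd = 0.3)),
                simplify = FALSE)
    })
    starts <- c(starts, jit)
  }

  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      stats::optim(pmax(s0, lower * 2), negll, gr = neggr,
                   method = "L-BFGS-B", lower = lower,
                   control = list(maxit = config$maxit,
                                  factr = config$factr)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
    if (is.null(best) || res$value < best$value) best <- res
  }

  if (is.null(best)) {
    return(structure(
      list(estimates = stats::setNames(rep(NA_real_, npar), model$par_names),
           se = stats::setNames(rep(NA_real_, npar), model$par_names),
           loglik = NA_real_, converged = FALSE, n_obs = length(data),
           model = model$name, message = "all starts failed"),
      class = "frlx_fit"))
  }

  fit <- structure(
    list(estimates = stats::setNames(best$par, model$par_names),
         se = stats::setNames(rep(NA_real_, npar), model$par_names),
         loglik = -best$value, converged = best$convergence == 0,
         n_obs = length(data), model = model$name,
         message = if (best$convergence == 0) "converged" else
           paste0("optim code ", best$convergence, ": ", best$message)),
    class = "frlx_fit")
  if (config$se) {
    fit$se <- tryCatch(standard_errors(data, fit, model),
                       warning = function(w) fit$se,
                       error = function(e) fit$se)
  }
  fit
}

#' Standard errors from the observed information
#'
#' Square roots of the diagonal of the inverse of the numerically
#' differentiated observed information (negative Hessian of the
#' log-likelihood) at the fitted maximum, via [stats::optimHess()].
#' A non-positive-definite information matrix yields `NA` values with a
#' warning rather than an error.
#'
#' @param data the fitted sample.
#' @param fit an `frlx_fit` object.
#' @param model registry name or entry (defaults to the fit's model).
#' @return named vector of standard errors.
#' @export
standard_errors <- function(data, fit, model = fit$model) {
  model <- .resolve_model(model)
  npar <- length(model$par_names)
  bad <- stats::setNames(rep(NA_real_, npar), model$par_names)
  if (!isTRUE(fit$converged) || any(!is.finite(fit$estimates))) {
    warning("standard errors requested for a non-converged fit")
    return(bad)
  }
  H <- tryCatch(
    stats::optimHess(unname(fit$estimates), function(p) {
      v <- log_likelihood(data, p, model)
      if (!is.finite(v)) 1e10 else -v
    }),
    error = function(e) NULL
  )
  if (is.null(H) || any(!is.finite(H))) {
    warning("observed information could not be computed")
    return(bad)
  }
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    warning("observed information is not positive definite")
    return(bad)
  }
  stats::setNames(sqrt(diag(solve(H))), model$par_names)
}

#' @export
print.frlx_fit <- function(x, ...) {
  cat("<frlx_fit>", x$model, "on n =", x$n_obs, "observations\n")
  tab <- rbind(estimate = x$estimates, se = x$se)
  print(round(tab, 5))
  cat("loglik:", format(x$loglik), " converged:", x$converged, "\n")
  invisible(x)
}

.resolve_model <- function(model) {
  if (is.character(model)) return(frlx_model(model))
  if (is.list(model) && !is.null(model$logpdf)) return(model)
  stop("'model' must be a registry name or entry", call. = FALSE)
}
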