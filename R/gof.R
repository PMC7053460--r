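#' Goodness-of-fit statistics for a fitted cdf
#'
#' Classical EDF statistics computed on the probability-integral
#' transforms \eqn{z_i = G(x_{(i)})} of the sorted sample (clamped to
#' `[1e-12, 1 - 1e-12]` so the Anderson-Darling statistic stays finite):
#'
#' * Anderson-Darling:
#'   \eqn{A^2 = -n - \frac{1}{n}\sum_i (2i-1)[\log z_i +
#'   \log(1 - z_{n-i+1})]}
#' * Cramer-von Mises:
#'   \eqn{W^2 = \frac{1}{12n} + \sum_i [z_i - (2i-1)/(2n)]^2}
#' * Kolmogorov-Smirnov:
#'   \eqn{D = \max_i \max(i/n - z_i,\ z_i - (i-1)/n)}
#'
#' All three depend on the data only through the \eqn{z_i}, so they are
#' invariant under strictly monotone transforms applied jointly to the
#' data and the model, and to the input ordering.
#'
#' @param data numeric sample (any order; sorted internally).
#' @param cdf either a vectorised function `x -> G(x)`, or a registry
#'   model name combined with `par`.
#' @param par parameter vector when `cdf` is a model name.
#' @return the statistic (a single number).
#' @name gof-statistics
NULL

# probability-integral transforms of the sorted sample
.gof_z <- function(data, cdf, par = NULL) {
  G <- if (is.function(cdf)) cdf else {
    model <- .resolve_model(cdf)
    function(x) model$cdf(x, unname(par))
  }
  z <- G(sort(data))
  pmin(pmax(z, 1e-12), 1 - 1e-12)
}

#' @rdname gof-statistics
#' @export
ad_statistic <- function(data, cdf, par = NULL) {
  n <- length(data)
  if (n < 2L) stop("Anderson-Darling needs at least 2 observations",
                   call. = FALSE)
  z <- .gof_z(data, cdf, par)
  i <- seq_len(n)
  -n - sum((2 * i - 1) * (log(z) + log(1 - z[n - i + 1]))) / n
}

#' @rdname gof-statistics
#' @export
cm_statistic <- function(data, cdf, par = NULL) {
  n <- length(data)
  if (n < 1L) stop("empty sample", call. = FALSE)
  z <- .gof_z(data, cdf, par)
  i <- seq_len(n)
  1 / (12 * n) + sum((z - (2 * i - 1) / (2 * n))^2)
}

#' @rdname gof-statistics
#' @export
ks_statistic <- function(data, cdf, par = NULL) {
  n <- length(data)
  if (n < 1L) stop("empty sample", call. = FALSE)
  z <- .gof_z(data, cdf, par)
  i <- seq_len(n)
  max(pmax(i / n - z, z - (i - 1) / n))
}

#' Asymptotic Kolmogorov-Smirnov p-value
#'
#' Tail probability of the Kolmogorov distribution,
#' \eqn{P(\sqrt{n} D > \sqrt{n} d) \approx 2\sum_{k\ge 1} (-1)^{k-1}
#' e^{-2 k^2 n d^2}}. No correction for estimated parameters is applied
#' (the asymptotic p-value is anticonservative when the cdf was fitted
#' to the same data; see the package vignette).
#'
#' @param ks the KS statistic D.
#' @param n sample size.
#' @return p-value in \eqn{[0, 1]}.
#' @export
ks_pvalue <- function(ks, n) {
  stopifnot(ks >= 0, n >= 1)
  if (ks == 0) return(1)
  lambda <- sqrt(n) * ks
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Goodness-of-fit report for one fitted model
#'
#' @inheritParams gof-statistics
#' @param model_name label recorded in the report.
#' @return a one-row data frame with columns `model`, `cm`, `ad`, `ks`,
#'   `ks_pvalue`, `n`.
#' @export
gof_report <- function(data, cdf, par = NULL, model_name = "model") {
  ks <- ks_statistic(data, cdf, par)
  data.frame(
    model = model_name,
    cm = cm_statistic(data, cdf, par),
    ad = ad_statistic(data, cdf, par),
    ks = ks,
    ks_pvalue = ks_pvalue(ks, length(data)),
    n = length(data),
    stringsAsFactors = FALSE
  )
}

#' Scaled total-time-on-test coordinates
#'
#' Returns the empirical scaled-TTT transform
#' \deqn{\left(\frac{i}{n},\ \frac{\sum_{j \le i} x_{(j)} +
#'   (n-i) x_{(i)}}{\sum_j x_j}\right), \quad i = 1, \dots, n,}
#' whose curvature diagnoses the hazard shape (diagonal for constant
#' hazard, concave for increasing, S-shaped for unimodal). The last
#' coordinate is exactly (1, 1).
#'
#' @param data positive sample, at least 2 observations.
#' @return data frame with columns `p` (= i/n) and `ttt`.
#' @export
ttt_coordinates <- function(data) {
  n <- length(data)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (any(data <= 0)) stop("TTT transform requires positive observations",
                           call. = FALSE)
  xs <- sort(data)
  i <- seq_len(n)
  tot <- sum(xs)
  data.frame(p = i / n, ttt = (cumsum(xs) + (n - i) * xs) / tot)
}

#' Fit and rank several models on one sample
#'
#' Fits each requested model by [fit_mle()], computes the three EDF
#' statistics and the asymptotic KS p-value for each, and ranks models
#' by (KS, AD, CM) ascending — lower values indicate the better fit. A
#' model that fails to converge keeps its row with `converged = FALSE`
#' and `NA` statistics; it is ranked last, never dropped silently.
#'
#' @param data positive numeric sample.
#' @param models character vector of registry names (at least 1).
#' @param config a [fit_config()] shared by all fits.
#' @return a data frame sorted by rank with columns `model`, `cm`, `ad`,
#'   `ks`, `ks_pvalue`, `n`, `converged`, `loglik` and the estimates in
#'   an attribute `"fits"`.
#' @examples
#' x <- frlw_rvs(200, 0.7, 1.3, 0.4, seed = 3)
#' compare_models(x, c("frlw", "weibull"))
#' @export
compare_models <- function(data, models, config = fit_config()) {
  stopifnot(length(models) >= 1L)
  fits <- lapply(models, function(m) fit_mle(data, m, config))
  rows <- Map(function(m, f) {
    if (isTRUE(f$converged)) {
      r <- gof_report(data, m, unname(f$estimates), model_name = m)
      r$converged <- TRUE
      r$loglik <- f$loglik
    } else {
      r <- data.frame(model = m, cm = NA_real_, ad = NA_real_,
                      ks = NA_real_, ks_pvalue = NA_real_,
                      n = length(data), converged = FALSE,
                      loglik = NA_real_, stringsAsFactors = FALSE)
    }
    r
  }, models, fits)
  tab <- do.call(rbind, rows)
  ord <- order(!tab$converged, tab$ks, tab$ad, tab$cm)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- stats::setNames(fits, models)
  tab
}
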