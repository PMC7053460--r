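#' The FRL-Weibull distribution
#'
#' The FRL-X transform applied to the Weibull baseline
#' \eqn{F(x) = 1 - e^{-\gamma x^\alpha}} gives the three-parameter
#' FRL-Weibull (FRL-W) lifetime distribution with cdf
#' \deqn{G(x) = 1 - \frac{\log(1 + \sigma - \sigma(1 - e^{-\gamma
#'   x^\alpha}))}{\log(1+\sigma)}, \quad x \ge 0.}
#' These closed forms agree with the generic transform
#' ([frlx_cdf()] with [baseline_weibull()]) to machine precision; the
#' specialised versions exist for speed in fitting and simulation.
#'
#' @param x numeric vector of nonnegative evaluation points (values below
#'   0 give cdf 0 / pdf 0, the lifetime support convention).
#' @param alpha Weibull shape, > 0.
#' @param sigma FRL-X parameter, > 0.
#' @param gamma Weibull rate-like parameter multiplying \eqn{x^\alpha}, > 0.
#' @return probabilities / densities / quantiles / draws, matching the
#'   usual d/p/q/r layout.
#' @examples
#' frlw_cdf(log(2), alpha = 1, sigma = 1, gamma = 1)  # 1 - log(1.5)/log(2)
#' @name frlw
NULL

.check_pos <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop("all parameters must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname frlw
#' @export
frlw_cdf <- function(x, alpha, sigma, gamma) {
  .check_pos(alpha, sigma, gamma)
  E <- ifelse(x <= 0, 1, exp(-gamma * pmax(x, 0)^alpha))
  1 - log1p(sigma * E) / log1p(sigma)
}

#' @rdname frlw
#' @export
frlw_pdf <- function(x, alpha, sigma, gamma) {
  .check_pos(alpha, sigma, gamma)
  out <- numeric(length(x))
  pos <- x > 0
  xp <- x[pos]
  E <- exp(-gamma * xp^alpha)
  out[pos] <- alpha * sigma * gamma * xp^(alpha - 1) * E /
    (log1p(sigma) * (1 + sigma * E))
  out
}

#' @rdname frlw
#' @export
frlw_logpdf <- function(x, alpha, sigma, gamma) {
  .check_pos(alpha, sigma, gamma)
  out <- rep(-Inf, length(x))
  pos <- x > 0
  xp <- x[pos]
  gx <- gamma * xp^alpha
  out[pos] <- log(alpha) + log(sigma) + log(gamma) +
    (alpha - 1) * log(xp) - gx -
    log(log1p(sigma)) - log1p(sigma * exp(-gx))
  out
}

#' @rdname frlw
#' @param u probabilities in (0, 1).
#' @export
frlw_quantile <- function(u, alpha, sigma, gamma) {
  .check_pos(alpha, sigma, gamma)
  if (any(u <= 0 | u >= 1, na.rm = TRUE)) {
    stop("'u' must lie in (0, 1)", call. = FALSE)
  }
  # baseline survival at the quantile: expm1((1-u) log(1+sigma)) / sigma
  sb <- expm1((1 - u) * log1p(sigma)) / sigma
  ((-log(sb)) / gamma)^(1 / alpha)
}

#' @rdname frlw
#' @param n number of draws.
#' @param seed optional integer seed (see [frlx_rvs()]).
#' @export
frlw_rvs <- function(n, alpha, sigma, gamma, seed = NULL) {
  frlx_rvs(n, frlx_params(sigma, c(alpha = alpha, gamma = gamma)),
           baseline_weibull(), seed = seed)
}

# ---- competitor models -----------------------------------------------------

#' Competitor lifetime distributions
#'
#' The reference models used when benchmarking the FRL-Weibull fit:
#' the two-parameter Weibull \eqn{G = 1 - e^{-\gamma x^\alpha}}, the
#' alpha-power-transformed Weibull (APTW)
#' \eqn{G = (\alpha_1^{1 - e^{-\gamma x^\alpha}} - 1)/(\alpha_1 - 1)}
#' with \eqn{\alpha_1 > 0,\ \alpha_1 \ne 1}, and the Marshall-Olkin
#' Weibull (MOW)
#' \eqn{G = F / (\sigma + (1-\sigma) F)} with \eqn{F = 1 - e^{-\gamma
#' x^\alpha}}. All share the rate-like Weibull parameterisation so fitted
#' parameters are directly comparable across models. The removable
#' singularity of APTW at \eqn{\alpha_1 = 1} is not special-cased:
#' \eqn{\alpha_1 = 1} is a domain error (the limit is the plain Weibull).
#'
#' @param x numeric vector of evaluation points.
#' @param alpha,gamma Weibull shape and rate-like parameters, > 0.
#' @param alpha1 APTW transform parameter, > 0 and != 1.
#' @param sigma MOW tilt parameter, > 0 (`sigma = 1` recovers Weibull).
#' @name competitors
NULL

#' @rdname competitors
#' @export
aptw_cdf <- function(x, alpha1, alpha, gamma) {
  .check_pos(alpha1, alpha, gamma)
  if (alpha1 == 1) stop("'alpha1' must differ from 1", call. = FALSE)
  Fb <- ifelse(x <= 0, 0, -expm1(-gamma * pmax(x, 0)^alpha))
  (alpha1^Fb - 1) / (alpha1 - 1)
}

#' @rdname competitors
#' @export
aptw_pdf <- function(x, alpha1, alpha, gamma) {
  .check_pos(alpha1, alpha, gamma)
  if (alpha1 == 1) stop("'alpha1' must differ from 1", call. = FALSE)
  out <- numeric(length(x))
  pos <- x > 0
  xp <- x[pos]
  Fb <- -expm1(-gamma * xp^alpha)
  fb <- alpha * gamma * xp^(alpha - 1) * exp(-gamma * xp^alpha)
  out[pos] <- log(alpha1) * alpha1^Fb * fb / (alpha1 - 1)
  out
}

#' @rdname competitors
#' @export
mow_cdf <- function(x, alpha, gamma, sigma) {
  .check_pos(alpha, gamma, sigma)
  Fb <- ifelse(x <= 0, 0, -expm1(-gamma * pmax(x, 0)^alpha))
  Fb / (sigma + (1 - sigma) * Fb)
}

#' @rdname competitors
#' @export
mow_pdf <- function(x, alpha, gamma, sigma) {
  .check_pos(alpha, gamma, sigma)
  out <- numeric(length(x))
  pos <- x > 0
  xp <- x[pos]
  Fb <- -expm1(-gamma * xp^alpha)
  fb <- alpha * gamma * xp^(alpha - 1) * exp(-gamma * xp^alpha)
  out[pos] <- sigma * fb / (sigma + (1 - sigma) * Fb)^2
  out
}

# ---- extended families -----------------------------------------------------

#' Extended FRL-X families
#'
#' Two extra shape parameters generalise the FRL-X transform:
#' \deqn{G(x) = 1 - \left[\frac{\log(1 + \sigma - \sigma
#'   F(x;\xi)^\theta)}{\log(1+\sigma)}\right]^\eta,}
#' where \eqn{\theta > 0} exponentiates the baseline (FRLE-X when
#' \eqn{\eta = 1}) and \eqn{\eta > 0} exponentiates the outer ratio
#' (EFRL-X when \eqn{\theta = 1}); both together give the EFRLE-X
#' family, and \eqn{\theta = \eta = 1} reduces exactly to the plain
#' FRL-X cdf. Densities are analytic (chain rule).
#'
#' @param x numeric vector of evaluation points.
#' @param params an [extended_params()] object.
#' @param base a [baseline_model()] object.
#' @export
extended_cdf <- function(x, params, base) {
  stopifnot(inherits(params, "frlx_extended_params"))
  s <- params$sigma
  Fb <- .clamp01(base$cdf(x, params$xi))
  ratio <- log1p(s * (1 - Fb^params$theta)) / log1p(s)
  1 - ratio^params$eta
}

#' @rdname extended_cdf
#' @export
extended_pdf <- function(x, params, base) {
  stopifnot(inherits(params, "frlx_extended_params"))
  s <- params$sigma; th <- params$theta; et <- params$eta
  Fb <- .clamp01(base$cdf(x, params$xi))
  fb <- base$pdf(x, params$xi)
  L <- log1p(s)
  inner <- 1 + s * (1 - Fb^th)
  ratio <- log(inner) / L
  # F^(theta-1) at F=0 with theta<1 would blow up; density 0 where f=0
  core <- s * th * ifelse(fb > 0, Fb^(th - 1) * fb, 0) / (L * inner)
  out <- ifelse(fb > 0, et * ratio^(et - 1) * core, 0)
  # ratio -> 0 at the upper support end: the 0 * Inf products there are 0
  out[!is.finite(out) & (Fb >= 1 - 1e-14)] <- 0
  out
}

#' Parameters of the extended FRL-X families
#'
#' @param sigma FRL-X parameter, > 0.
#' @param xi baseline parameter vector.
#' @param theta inner (exponentiation) shape, > 0; 1 disables it.
#' @param eta outer shape, > 0; 1 disables it.
#' @return an object of class `frlx_extended_params`.
#' @export
extended_params <- function(sigma, xi, theta = 1, eta = 1) {
  .check_pos(sigma, theta, eta)
  structure(list(sigma = sigma, xi = xi, theta = theta, eta = eta),
            class = "frlx_extended_params")
}

# ---- model registry --------------------------------------------------------

# Each registry entry carries everything fitting / gof / simulation need:
# parameter names, box lower bounds, vectorised logpdf/pdf/cdf/quantile,
# a default start rule, and (where available) an analytic score.
.frlx_registry <- local({
  weib_start <- function(data) {
    # method-of-moments Weibull start: shape from the CV, rate from the mean
    m <- mean(data); s <- stats::sd(data)
    a <- if (is.finite(s) && s > 0) max((s / m)^(-1.086), 0.05) else 1
    lam <- m / gamma(1 + 1 / a)
    c(alpha = a, gamma = lam^(-a))
  }

  reg <- list()

  reg$frlw <- list(
    name = "frlw", par_names = c("alpha", "sigma", "gamma"),
    lower = c(1e-8, 1e-8, 1e-8),
    logpdf = function(x, par) frlw_logpdf(x, par[1], par[2], par[3]),
    pdf = function(x, par) frlw_pdf(x, par[1], par[2], par[3]),
    cdf = function(x, par) frlw_cdf(x, par[1], par[2], par[3]),
    quantile = function(u, par) frlw_quantile(u, par[1], par[2], par[3]),
    start = function(data) {
      ws <- weib_start(data)
      c(alpha = unname(ws["alpha"]), sigma = 1, gamma = unname(ws["gamma"]))
    },
    score = function(x, par) {
      a <- par[1]; s <- par[2]; g <- par[3]
      n <- length(x)
      xa <- x^a; lx <- log(x); E <- exp(-g * xa); A <- 1 + s * E
      c(alpha = sum(1 / a + lx - g * xa * lx + s * g * xa * lx * E / A),
        sigma = n / s - n / ((1 + s) * log1p(s)) - sum(E / A),
        gamma = sum(1 / g - xa + s * xa * E / A))
    }
  )

  reg$weibull <- list(
    name = "weibull", par_names = c("alpha", "gamma"),
    lower = c(1e-8, 1e-8),
    logpdf = function(x, par) {
      ifelse(x > 0,
             log(par[1]) + log(par[2]) + (par[1] - 1) * log(pmax(x, 1e-300)) -
               par[2] * pmax(x, 0)^par[1],
             -Inf)
    },
    pdf = function(x, par) {
      ifelse(x > 0, par[1] * par[2] * x^(par[1] - 1) * exp(-par[2] * x^par[1]), 0)
    },
    cdf = function(x, par) ifelse(x <= 0, 0, -expm1(-par[2] * pmax(x, 0)^par[1])),
    quantile = function(u, par) (-log1p(-u) / par[2])^(1 / par[1]),
    start = function(data) weib_start(data),
    score = function(x, par) {
      a <- par[1]; g <- par[2]
      xa <- x^a; lx <- log(x)
      c(alpha = sum(1 / a + lx - g * xa * lx),
        gamma = sum(1 / g - xa))
    }
  )

  reg$exponential <- list(
    name = "exponential", par_names = "gamma",
    lower = 1e-8,
    logpdf = function(x, par) ifelse(x > 0, log(par[1]) - par[1] * x, -Inf),
    pdf = function(x, par) ifelse(x > 0, par[1] * exp(-par[1] * x), 0),
    cdf = function(x, par) ifelse(x <= 0, 0, -expm1(-par[1] * pmax(x, 0))),
    quantile = function(u, par) -log1p(-u) / par[1],
    start = function(data) c(gamma = 1 / mean(data)),
    score = function(x, par) c(gamma = length(x) / par[1] - sum(x))
  )

  reg$aptw <- list(
    name = "aptw", par_names = c("alpha1", "alpha", "gamma"),
    lower = c(1e-8, 1e-8, 1e-8),
    logpdf = function(x, par) {
      v <- aptw_pdf(x, par[1], par[2], par[3])
      ifelse(v > 0, log(v), -Inf)
    },
    pdf = function(x, par) aptw_pdf(x, par[1], par[2], par[3]),
    cdf = function(x, par) aptw_cdf(x, par[1], par[2], par[3]),
    quantile = function(u, par) {
      Fb <- log(u * (par[1] - 1) + 1) / log(par[1])
      (-log1p(-Fb) / par[3])^(1 / par[2])
    },
    start = function(data) {
      ws <- weib_start(data)
      c(alpha1 = 1.5, alpha = unname(ws["alpha"]), gamma = unname(ws["gamma"]))
    },
    score = NULL
  )

  reg$mow <- list(
    name = "mow", par_names = c("alpha", "gamma", "sigma"),
    lower = c(1e-8, 1e-8, 1e-8),
    logpdf = function(x, par) {
      v <- mow_pdf(x, par[1], par[2], par[3])
      ifelse(v > 0, log(v), -Inf)
    },
    pdf = function(x, par) mow_pdf(x, par[1], par[2], par[3]),
    cdf = function(x, par) mow_cdf(x, par[1], par[2], par[3]),
    quantile = function(u, par) {
      Fb <- u * par[3] / (1 - u * (1 - par[3]))
      (-log1p(-Fb) / par[2])^(1 / par[1])
    },
    start = function(data) {
      ws <- weib_start(data)
      c(alpha = unname(ws["alpha"]), gamma = unname(ws["gamma"]), sigma = 1)
    },
    score = NULL
  )

  ext_entry <- function(name, theta_free, eta_free) {
    pn <- c("alpha", "sigma", "gamma",
            if (theta_free) "theta", if (eta_free) "eta")
    mk <- function(par) {
      extended_params(
        sigma = par[2], xi = c(alpha = par[1], gamma = par[3]),
        theta = if (theta_free) par[4] else 1,
        eta = if (eta_free) par[length(par)] else 1
      )
    }
    list(
      name = name, par_names = pn, lower = rep(1e-8, length(pn)),
      logpdf = function(x, par) {
        v <- extended_pdf(x, mk(par), baseline_weibull())
        ifelse(v > 0, log(v), -Inf)
      },
      pdf = function(x, par) extended_pdf(x, mk(par), baseline_weibull()),
      cdf = function(x, par) extended_cdf(x, mk(par), baseline_weibull()),
      quantile = function(u, par) {
        p <- mk(par); s <- p$sigma
        # invert the outer power, the log ratio, then the exponentiated F
        pb <- .clamp01((1 + s - exp((1 - u)^(1 / p$eta) * log1p(s))) / s)
        Fb <- pb^(1 / p$theta)
        (-log1p(-Fb) / p$xi[["gamma"]])^(1 / p$xi[["alpha"]])
      },
      start = function(data) {
        ws <- weib_start(data)
        stats::setNames(c(unname(ws["alpha"]), 1, unname(ws["gamma"]),
                          if (theta_free) 1, if (eta_free) 1), pn)
      },
      score = NULL
    )
  }
  reg$`frle-w` <- ext_entry("frle-w", TRUE, FALSE)
  reg$`efrl-w` <- ext_entry("efrl-w", FALSE, TRUE)
  reg$`efrle-w` <- ext_entry("efrle-w", TRUE, TRUE)

  reg
})

#' Model registry
#'
#' `frlx_models()` lists the registered model names; `frlx_model(name)`
#' returns the registry entry (parameter names, bounds, vectorised
#' logpdf/pdf/cdf/quantile, default start rule, analytic score where
#' available). The registry makes fitting, goodness of fit and the CLI
#' model-agnostic.
#'
#' @param name registry key, e.g. `"frlw"`, `"weibull"`, `"aptw"`,
#'   `"mow"`, `"exponential"`, `"frle-w"`, `"efrl-w"`, `"efrle-w"`.
#' @return `frlx_models()`: character vector; `frlx_model()`: a list.
#' @export
frlx_models <- function() names(.frlx_registry)

#' @rdname frlx_models
#' @export
frlx_model <- function(name) {
  if (!name %in% names(.frlx_registry)) {
    stop("unknown model '", name, "'; registered models: ",
         paste(names(.frlx_registry), collapse = ", "), call. = FALSE)
  }
  .frlx_registry[[name]]
}
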