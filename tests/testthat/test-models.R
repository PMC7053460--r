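test_that("FRL-W closed forms equal the generic transform to machine precision", {
  x <- seq(0.01, 12, length.out = 100)
  pars <- random_frlw_params(4, seed = 5)
  for (i in seq_len(nrow(pars))) {
    a <- pars$alpha[i]; s <- pars$sigma[i]; g <- pars$gamma[i]
    p <- frlx_params(s, c(alpha = a, gamma = g))
    expect_equal(frlw_cdf(x, a, s, g), frlx_cdf(x, p, wb),
                 tolerance = 1e-14)
    expect_equal(frlw_pdf(x, a, s, g), frlx_pdf(x, p, wb),
                 tolerance = 1e-14)
    dens <- frlx_pdf(x, p, wb)
    keep <- dens > 1e-300      # below this the generic path underflows first
    expect_equal(frlw_logpdf(x[keep], a, s, g), log(dens[keep]),
                 tolerance = 1e-10)
  }
  expect_equal(frlw_cdf(0, 0.7, 1.3, 0.4), 0)
  expect_equal(frlw_cdf(log(2), 1, 1, 1), 1 - log(1.5) / log(2),
               tolerance = 1e-15)
  u <- seq(0.02, 0.98, by = 0.02)
  expect_lt(max(abs(frlw_cdf(frlw_quantile(u, 0.7, 1.3, 0.4),
                             0.7, 1.3, 0.4) - u)), 1e-12)
})

test_that("competitor cdfs: limits, endpoints and pdf consistency", {
  x <- seq(0.05, 8, length.out = 40)
  # MOW with sigma = 1 collapses to the plain Weibull
  expect_equal(mow_cdf(x, 1.2, 0.5, 1),
               frlx_model("weibull")$cdf(x, c(1.2, 0.5)), tolerance = 1e-14)
  # APTW at alpha1 -> 1 approaches the Weibull; alpha1 = 1 itself errors
  expect_lt(max(abs(aptw_cdf(x, 1 + 1e-8, 1.2, 0.5) -
                      frlx_model("weibull")$cdf(x, c(1.2, 0.5)))), 1e-6)
  expect_error(aptw_cdf(x, 1, 1.2, 0.5), "differ")
  # proper cdfs: 0 at the origin, 1 in the limit, monotone, pdf integrates to 1
  cdfs <- list(function(z) aptw_cdf(z, 2, 1.3, 0.6),
               function(z) mow_cdf(z, 1.3, 0.6, 2.5))
  pdfs <- list(function(z) aptw_pdf(z, 2, 1.3, 0.6),
               function(z) mow_pdf(z, 1.3, 0.6, 2.5))
  for (k in 1:2) {
    expect_equal(cdfs[[k]](0), 0)
    expect_equal(cdfs[[k]](1e8), 1, tolerance = 1e-10)
    expect_true(all(diff(cdfs[[k]](x)) > 0))
    expect_equal(integrate_pdf(pdfs[[k]]), 1, tolerance = 1e-6)
    h <- 1e-5
    fd <- (cdfs[[k]](2 + h) - cdfs[[k]](2 - h)) / (2 * h)
    expect_equal(pdfs[[k]](2), fd, tolerance = 1e-6)
  }
})

test_that("extended families reduce exactly on the theta/eta = 1 lattice", {
  x <- seq(0.05, 10, length.out = 60)
  xi <- c(alpha = 0.9, gamma = 0.7)
  s <- 1.4
  base_cdf <- frlx_cdf(x, frlx_params(s, xi), wb)
  # theta = eta = 1 gives the plain family
  expect_identical(extended_cdf(x, extended_params(s, xi), wb), base_cdf)
  # eta = 1 leaves only the inner exponentiation; theta = 1 only the outer
  e_th <- extended_cdf(x, extended_params(s, xi, theta = 2), wb)
  e_et <- extended_cdf(x, extended_params(s, xi, eta = 2), wb)
  e_both <- extended_cdf(x, extended_params(s, xi, theta = 2, eta = 2), wb)
  Fb <- wb$cdf(x, xi)
  expect_equal(e_th, 1 - log1p(s * (1 - Fb^2)) / log1p(s), tolerance = 1e-14)
  expect_equal(e_et, 1 - (log1p(s * (1 - Fb)) / log1p(s))^2, tolerance = 1e-14)
  # the doubly extended cdf restricted to one active parameter matches each
  expect_identical(extended_cdf(x, extended_params(s, xi, theta = 2, eta = 1), wb),
                   e_th)
  expect_identical(extended_cdf(x, extended_params(s, xi, theta = 1, eta = 2), wb),
                   e_et)
  expect_true(all(diff(e_both) > 0))
  expect_equal(extended_cdf(1e9, extended_params(s, xi, theta = 2), wb), 1,
               tolerance = 1e-12)
})

test_that("extended pdfs are the cdf derivative and integrate to 1", {
  set.seed(42)
  for (k in 1:5) {
    prm <- extended_params(runif(1, 0.5, 3), c(alpha = runif(1, 0.6, 2.5),
                                               gamma = runif(1, 0.3, 2)),
                           theta = runif(1, 0.5, 3), eta = runif(1, 0.5, 3))
    expect_equal(integrate_pdf(function(x) extended_pdf(x, prm, wb)), 1,
                 tolerance = 1e-6)
    h <- 1e-5
    for (x0 in c(0.4, 1.1)) {
      fd <- (extended_cdf(x0 + h, prm, wb) -
               extended_cdf(x0 - h, prm, wb)) / (2 * h)
      expect_equal(extended_pdf(x0, prm, wb), fd, tolerance = 1e-5)
    }
  }
})

test_that("the registry is model-agnostic: quantile inverts cdf for all entries", {
  u <- seq(0.05, 0.95, by = 0.05)
  pars <- list(frlw = c(0.7, 1.3, 0.4), weibull = c(1.2, 0.5),
               exponential = 0.8, aptw = c(2, 1.2, 0.5),
               mow = c(1.2, 0.5, 2), `frle-w` = c(0.9, 1.3, 0.6, 1.7),
               `efrl-w` = c(0.9, 1.3, 0.6, 1.7),
               `efrle-w` = c(0.9, 1.3, 0.6, 1.4, 1.7))
  expect_setequal(names(pars), frlx_models())
  for (nm in names(pars)) {
    m <- frlx_model(nm)
    expect_length(m$par_names, length(pars[[nm]]))
    q <- m$quantile(u, pars[[nm]])
    expect_lt(max(abs(m$cdf(q, pars[[nm]]) - u)), 1e-9)
    expect_equal(exp(m$logpdf(q, pars[[nm]])), m$pdf(q, pars[[nm]]),
                 tolerance = 1e-12)
  }
  expect_error(frlx_model("nope"), "unknown model")
})
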