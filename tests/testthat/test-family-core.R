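test_that("cdf endpoints, closed-form value and sf complementarity", {
  # F = 0 and F = 1 map to 0 and 1 for any sigma
  for (s in c(0.3, 1, 2.7)) {
    p <- frlx_params(s, c(alpha = 1, gamma = 1))
    expect_equal(frlx_cdf(-1, p, wb), 0)
    expect_equal(frlx_cdf(Inf, p, wb), 1)
  }
  # sigma = 1, baseline F = 1/2 at x = log 2 (unit exponential)
  p1 <- frlx_params(1, c(alpha = 1, gamma = 1))
  expect_equal(frlx_cdf(log(2), p1, wb), 1 - log(1.5) / log(2),
               tolerance = 1e-14)
  x <- c(0.1, 0.5, 1, 2, 5)
  expect_equal(frlx_sf(x, p_set1, wb) + frlx_cdf(x, p_set1, wb),
               rep(1, length(x)), tolerance = 1e-14)
  # nondecreasing
  g <- frlx_cdf(seq(0.01, 10, length.out = 200), p_set1, wb)
  expect_true(all(diff(g) >= 0))
})

test_that("sigma = 1 reduces to the logarithmic-transformed family exactly", {
  x <- seq(0.05, 6, length.out = 50)
  p1 <- frlx_params(1, c(alpha = 0.7, gamma = 0.4))
  Fb <- wb$cdf(x, p1$xi)
  expect_equal(frlx_cdf(x, p1, wb), 1 - log(2 - Fb) / log(2),
               tolerance = 1e-15)
})

test_that("sigma -> 0 recovers the baseline cdf", {
  x <- seq(0.05, 8, length.out = 60)
  p0 <- frlx_params(1e-8, c(alpha = 0.7, gamma = 0.4))
  expect_lt(max(abs(frlx_cdf(x, p0, wb) - wb$cdf(x, p0$xi))), 1e-6)
})

test_that("pdf is the cdf derivative and integrates to 1", {
  pars <- random_frlw_params(5)
  for (i in seq_len(nrow(pars))) {
    p <- frlx_params(pars$sigma[i], c(pars$alpha[i], pars$gamma[i]))
    expect_equal(integrate_pdf(function(x) frlx_pdf(x, p, wb)), 1,
                 tolerance = 1e-6)
  }
  # central difference of the cdf at interior points
  h <- 1e-5
  for (x in c(0.3, 1, 2.5)) {
    fd <- (frlx_cdf(x + h, p_set1, wb) - frlx_cdf(x - h, p_set1, wb)) / (2 * h)
    expect_equal(frlx_pdf(x, p_set1, wb), fd, tolerance = 1e-6)
  }
  expect_equal(frlx_pdf(-2, p_set1, wb), 0)
})

test_that("hazard equals pdf/sf and integrates to the cumulative hazard", {
  x <- c(0.2, 0.9, 3)
  expect_equal(frlx_hazard(x, p_set1, wb),
               frlx_pdf(x, p_set1, wb) / frlx_sf(x, p_set1, wb),
               tolerance = 1e-12)
  for (xx in c(0.8, 2.5)) {
    ch <- stats::integrate(function(u) frlx_hazard(u, p_set1, wb),
                           0, xx, rel.tol = 1e-10)$value
    expect_equal(ch, -log(frlx_sf(xx, p_set1, wb)), tolerance = 1e-6)
  }
})

test_that("quantile inverts the cdf to 1e-9 and maps endpoints to support", {
  u <- seq(0.01, 0.99, by = 0.01)
  pars <- random_frlw_params(4, seed = 77)
  for (i in seq_len(nrow(pars))) {
    p <- frlx_params(pars$sigma[i], c(pars$alpha[i], pars$gamma[i]))
    q <- frlx_quantile(u, p, wb)
    expect_lt(max(abs(frlx_cdf(q, p, wb) - u)), 1e-9)
  }
  expect_equal(frlx_quantile(0.37, p_set1, wb) |>
                 frlx_cdf(p_set1, wb), 0.37, tolerance = 1e-9)
  expect_identical(frlx_quantile(c(0, 1), p_set1, wb), c(0, Inf))
  expect_error(frlx_quantile(1.2, p_set1, wb), "must lie")
  expect_error(frlx_params(-1, c(1, 1)), "positive")
})

test_that("inverse-transform sampling is reproducible and matches the law", {
  x1 <- frlx_rvs(50, p_set1, wb, seed = 11)
  x2 <- frlx_rvs(50, p_set1, wb, seed = 11)
  expect_identical(x1, x2)
  expect_error(frlx_rvs(0, p_set1, wb), "positive")

  x <- frlx_rvs(1e5, p_set1, wb, seed = 2)
  ks <- ks_statistic(x, function(q) frlx_cdf(q, p_set1, wb))
  expect_gt(ks_pvalue(ks, length(x)), 0.01)
  m1 <- frlx_moment(1, p_set1, wb)
  m2 <- frlx_moment(2, p_set1, wb)
  se <- sqrt((m2 - m1^2) / length(x))
  expect_lt(abs(mean(x) - m1), 3 * se)
})

test_that("series and quadrature moments agree; r=0 normalises; variance >= 0", {
  expect_equal(frlx_moment(0, p_set1, wb), 1, tolerance = 1e-10)
  for (r in 1:3) {
    ms <- frlx_moment(r, p_set1, wb, method = "series")
    mq <- frlx_moment(r, p_set1, wb, method = "quadrature")
    expect_equal(ms, mq, tolerance = 1e-6)
  }
  expect_gte(frlx_moment(2, p_set1, wb) - frlx_moment(1, p_set1, wb)^2, 0)
})

test_that("mgf normalises at 0, matches quadrature, and flags divergence", {
  expect_identical(frlx_mgf(0, p_set1, wb), 1)
  # light-tailed baseline so the mgf exists at positive t
  p2 <- frlx_params(1.3, c(alpha = 2, gamma = 0.4))
  for (t in c(-0.5, 0.3)) {
    direct <- integrate_pdf(function(x) {
      lp <- log(frlx_pdf(x, p2, wb))   # log-space: avoids Inf * 0 in the tail
      ifelse(is.finite(lp), exp(t * x + lp), 0)
    })
    expect_equal(frlx_mgf(t, p2, wb), direct, tolerance = 1e-6)
  }
  # Taylor limit: (M(t) - 1)/t -> E[X]
  t <- 1e-4
  expect_equal((frlx_mgf(t, p2, wb) - 1) / t, frlx_moment(1, p2, wb),
               tolerance = 1e-3)
  # heavy-tailed baseline (alpha < 1) has no mgf at t > 0
  expect_error(frlx_mgf(0.5, p_set1, wb), "diverges|finite")
})

test_that("residual life matches the survival ratio and is monotone", {
  t0 <- 0.8
  x <- c(0, 0.3, 1, 2.5)
  direct <- frlx_sf(x + t0, p_set1, wb) / frlx_sf(t0, p_set1, wb)
  expect_equal(residual_life_sf(x, t0, p_set1, wb), direct,
               tolerance = 1e-12)
  expect_equal(residual_life_sf(0, t0, p_set1, wb), 1)
  r <- residual_life_sf(seq(0, 5, by = 0.1), t0, p_set1, wb)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r >= 0 & r <= 1))
  # reverse residual life is the survival ratio at the shifted argument
  xr <- c(1, 2, 3)
  expect_equal(reverse_residual_life_sf(xr, t0, p_set1, wb),
               frlx_sf(xr - t0, p_set1, wb) / frlx_sf(t0, p_set1, wb),
               tolerance = 1e-12)
})

test_that("truncated-moment characterization holds and detects a wrong eta", {
  # lower-support closed forms: E[q1 | X >= 0] = sigma/log(1+sigma),
  # E[q2 | X >= 0] = sigma/(2 log(1+sigma)) (tail expectations at F = 0)
  s <- p_set1$sigma
  cc0 <- characterization_check(1e-12, p_set1, wb)
  expect_equal(cc0$lhs, s / (2 * log1p(s)), tolerance = 1e-6)
  expect_equal(cc0$rhs, s / (2 * log1p(s)), tolerance = 1e-6)

  pars <- random_frlw_params(3, seed = 9)
  for (i in seq_len(nrow(pars))) {
    p <- frlx_params(pars$sigma[i], c(pars$alpha[i], pars$gamma[i]))
    xs <- frlx_quantile(runif(10, 0.05, 0.9), p, wb)
    for (x in xs) {
      cc <- characterization_check(x, p, wb)
      expect_lt(abs(cc$diff), 1e-6)
    }
  }
  # negative control: constant eta = 1/2 must fail by a clear margin
  xm <- frlx_quantile(0.5, p_set1, wb)
  bad <- characterization_check(xm, p_set1, wb,
                                eta = function(x, xi) 0.5)
  expect_gt(abs(bad$diff), 1e-3)
})
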