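# shared fixtures: the Weibull baseline and the Set-1 style parameter point
wb <- baseline_weibull()
p_set1 <- frlx_params(1.3, c(alpha = 0.7, gamma = 0.4))

# random valid FRL-W parameter triplets (alpha, sigma, gamma), fixed seed
random_frlw_params <- function(k, seed = 1234) {
  set.seed(seed)
  data.frame(alpha = runif(k, 0.5, 3),
             sigma = runif(k, 0.2, 3),
             gamma = runif(k, 0.2, 3))
}

integrate_pdf <- function(f, lower = 0, upper = Inf) {
  stats::integrate(f, lower, upper, rel.tol = 1e-10,
                   subdivisions = 500L)$value
}
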