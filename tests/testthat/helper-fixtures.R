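# Shared fixtures: small, fast fits reused across test files.

w_comp <- c(0.75, 0.25)

# A modest heterogeneous trial + multivariate fit (2 chains for diagnostics)
fixture_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- dgm_preset("ES3", "binary", rho = 0.2)
      dat <- generate_trial(sp, 300, seed = 42)
      fit <- fit_bmlr(dat, c("y1", "y2"), "treat", covariates = "z",
                      chains = 2, iter = 400, burnin = 100, seed = 43)
      cache <<- list(spec = sp, data = dat, fit = fit)
    }
    cache
  }
})

# Random simplex vector of length Q (for fuzzing)
r_simplex <- function(Q) {
  g <- stats::rgamma(Q, 1)
  g / sum(g)
}
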