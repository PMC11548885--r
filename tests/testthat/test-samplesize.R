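test_that("rectangle probabilities match frozen external oracle values", {
  # Frozen from mvtnorm::pmvnorm (Miwa algorithm) at development time.
  S3 <- matrix(c(1, .3, -.2, .3, 1, .5, -.2, .5, 1), 3, 3)
  expect_equal(bmlr:::pmvnorm_rect(c(0.5, -0.3, 1.2), S3), 0.2929296,
               tolerance = 1e-6)
  S2 <- matrix(c(1, .45, .45, 1), 2, 2)
  expect_equal(bmlr:::pmvnorm_rect(c(1.1, -0.4), S2), 0.3297316,
               tolerance = 1e-6)
  # independence factorizes exactly
  expect_equal(bmlr:::pmvnorm_rect(c(0.7, -0.2), diag(2)),
               pnorm(0.7) * pnorm(-0.2), tolerance = 1e-9)
  expect_error(bmlr:::pmvnorm_rect(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("the compensatory closed form reproduces the textbook case", {
  # theta1w = 0.6, theta0w = 0.5, alpha 0.05 right-sided, power 0.80:
  # n = ceil(0.49 * ((1.6449 + 0.8416) / 0.1)^2) = 303 per arm
  res <- required_n("compensatory", 0.6, 0.5, weights = 1)
  expect_equal(res$n, 303L)
  # independent evaluation of the formula
  n_direct <- ceiling((0.6 * 0.4 + 0.5 * 0.5) *
                        ((qnorm(0.95) + qnorm(0.80)) / 0.1)^2)
  expect_equal(res$n, as.integer(n_direct))
  # halving the effect quadruples n (variance nearly constant)
  res2 <- required_n("compensatory", 0.55, 0.5, weights = 1)
  expect_equal(res2$n / res$n, 4, tolerance = 0.05)
  # weight degeneracy reduces to endpoint 1
  r_w <- required_n("compensatory", c(0.6, 0.9), c(0.5, 0.2),
                    weights = c(1, 0))
  expect_equal(r_w$n, 303L)
  # permutation invariance of (endpoint, weight) pairs
  ra <- required_n("compensatory", c(0.65, 0.55), c(0.5, 0.45),
                   weights = c(0.7, 0.3))
  rb <- required_n("compensatory", c(0.55, 0.65), c(0.45, 0.5),
                   weights = c(0.3, 0.7))
  expect_equal(ra$n, rb$n)
  expect_error(required_n("compensatory", c(0.5, 0.6), c(0.6, 0.5),
                          weights = c(0.5, 0.5)), "No solution")
})

test_that("K = 1 collapses all rules to the univariate two-proportion power", {
  t1 <- 0.65; t0 <- 0.5; n <- 150
  uni <- pnorm((t1 - t0) * sqrt(n) /
                 sqrt(t1 * (1 - t1) + t0 * (1 - t0)) - qnorm(0.95))
  expect_equal(analytic_power("any", n, t1, t0), uni, tolerance = 1e-9)
  expect_equal(analytic_power("all", n, t1, t0), uni, tolerance = 1e-9)
  expect_equal(analytic_power("compensatory", n, t1, t0, weights = 1), uni,
               tolerance = 1e-9)
})

test_that("power rises with n and correlation effects go the stated ways", {
  t1 <- c(0.6, 0.55); t0 <- c(0.5, 0.45)
  grid <- c(50, 100, 200, 400, 800)
  for (rule in c("any", "all")) {
    pw <- vapply(grid, function(n) analytic_power(rule, n, t1, t0, 0.2),
                 numeric(1))
    expect_true(all(diff(pw) > 0))
  }
  # All rule: positive correlation helps at fixed n
  p_all <- vapply(c(-0.4, 0, 0.4), function(r)
    analytic_power("all", 300, t1, t0, r), numeric(1))
  expect_true(all(diff(p_all) > 0))
  # Any and Compensatory: negative correlation means smaller required n
  n_any <- vapply(c(-0.4, 0, 0.4), function(r)
    required_n("any", t1, t0, r)$n, numeric(1))
  expect_true(all(diff(n_any) > 0))
  # doubling effects shrinks n
  expect_lt(required_n("any", c(0.7, 0.65), t0, 0.2)$n,
            required_n("any", t1, t0, 0.2)$n)
  # iterative result is minimal: one less subject misses the target
  r <- required_n("all", t1, t0, 0.2)
  expect_gte(r$achieved_power, 0.80)
  expect_lt(analytic_power("all", r$n - 1, t1, t0, 0.2), 0.80)
  expect_error(required_n("all", c(0.5, 0.5), c(0.5, 0.5), n_max = 1e4),
               "No solution")
})

test_that("two-endpoint All-rule n covers the harder endpoint's K = 1 n", {
  set.seed(63)
  for (i in 1:5) {
    t0 <- runif(2, 0.3, 0.5)
    t1 <- t0 + runif(2, 0.08, 0.2)
    n2 <- required_n("all", t1, t0, 0)$n
    n_each <- vapply(1:2, function(k)
      required_n("all", t1[k], t0[k])$n, numeric(1))
    expect_gte(n2, max(n_each))
  }
})

test_that("Monte-Carlo power at the computed n hits the target band", {
  # Homogeneous positive effect, rho = 0.2; simulate the full pipeline with
  # the Dirichlet analysis at the computed per-rule n. For the All and Any
  # rules the latent-normal approximation is sharp, so the simulated power
  # must land in a tight band. For the Compensatory rule the closed form
  # treats the weighted endpoint as a Bernoulli with mean theta_Tw, which
  # overstates its variance whenever the weights spread over endpoints: the
  # computed n is conservative, so simulated power must reach the target but
  # is allowed to overshoot (see the methods vignette).
  sp <- dgm_spec("binary", theta0_low = c(0.5, 0.5), theta0_high = c(0.5, 0.5),
                 theta1_low = c(0.7, 0.6), theta1_high = c(0.7, 0.6),
                 rho = 0.2, weights = w_comp)
  tr <- sp$truth$average
  mc_power <- function(rule_name, n, rule, reps, seed0) {
    hits <- 0L
    for (r in seq_len(reps)) {
      d <- generate_trial(sp, n, seed = rep_seed(seed0, 1, r))
      e <- fit_mb(d, c("y1", "y2"), "treat", ndraws = 1000,
                  seed = rep_seed(seed0, 2, r))
      hits <- hits + (decide(e, rule)$conclusion == "superior")
    }
    hits / reps
  }
  n_all <- required_n("all", tr$theta1, tr$theta0, 0.2)$n
  p_all <- mc_power("all", n_all, decision_rule("all"), 1000, 64)
  expect_gte(p_all, 0.80 - 0.04)
  expect_lte(p_all, 0.80 + 0.06)

  n_any <- required_n("any", tr$theta1, tr$theta0, 0.2)$n
  p_any <- mc_power("any", n_any, decision_rule("any"), 1000, 66)
  expect_gte(p_any, 0.80 - 0.04)
  expect_lte(p_any, 0.80 + 0.06)

  n_comp <- required_n("compensatory", tr$theta1, tr$theta0, 0.2,
                       weights = w_comp)$n
  p_comp <- mc_power("compensatory", n_comp,
                     decision_rule("compensatory", weights = w_comp), 800, 65)
  expect_gte(p_comp, 0.80 - 0.04)   # never underpowered
  expect_lte(p_comp, 0.95)          # bounded, documented conservatism
})
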