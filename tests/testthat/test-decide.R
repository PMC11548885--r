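test_that("region membership implements the three rules", {
  any_r <- decision_rule("any")
  all_r <- decision_rule("all")
  comp_r <- decision_rule("compensatory", weights = w_comp)

  d <- c(0.1, -0.05)
  expect_equal(region_membership(d, any_r), list(sup = TRUE, inf = TRUE))
  expect_equal(region_membership(d, all_r), list(sup = FALSE, inf = FALSE))
  # weighted difference 0.75*0.1 - 0.25*0.05 = 0.0625 > 0
  expect_equal(region_membership(d, comp_r), list(sup = TRUE, inf = FALSE))

  # strict boundaries: zero belongs to no region
  z <- c(0, 0)
  for (r in list(any_r, all_r, comp_r))
    expect_equal(region_membership(z, r), list(sup = FALSE, inf = FALSE))

  expect_equal(region_membership(c(-0.2, -0.1), all_r),
               list(sup = FALSE, inf = TRUE))
  expect_error(decision_rule("compensatory"), "weights")
})

test_that("left-sided rules flip the favorable direction without recoding", {
  left <- decision_rule("all", side = "left")
  expect_equal(region_membership(c(-0.2, -0.1), left),
               list(sup = TRUE, inf = FALSE))
  expect_equal(region_membership(c(0.2, 0.1), left),
               list(sup = FALSE, inf = TRUE))
})

test_that("rejection-region nesting holds on fuzzed draws", {
  set.seed(61)
  for (i in 1:200) {
    K <- sample(2:4, 1)
    d <- runif(K, -1, 1)
    w <- r_simplex(K)
    in_all <- region_membership(d, decision_rule("all"))$sup
    in_any <- region_membership(d, decision_rule("any"))$sup
    in_comp <- region_membership(
      d, decision_rule("compensatory", weights = w))$sup
    if (in_all) {
      expect_true(in_any)   # min > 0 implies max > 0
      expect_true(in_comp)  # all positive implies any convex combination > 0
    }
  }
})

test_that("thresholds match the rule, sidedness and multiplicity correction", {
  expect_equal(make_threshold("any", "right", 0.05, 2), 0.975)
  expect_equal(make_threshold("all", "right", 0.05, 2), 0.95)
  expect_equal(make_threshold("compensatory", "right", 0.05, 2), 0.95)
  expect_equal(make_threshold("compensatory", "two_sided", 0.05, 2), 0.975)
  expect_equal(make_threshold("all", "two_sided", 0.05, 2), 0.975)
  expect_equal(make_threshold("any", "two_sided", 0.05, 2), 0.9875)
  # p_cut strictly decreasing in alpha
  alphas <- c(0.01, 0.025, 0.05, 0.1)
  cuts <- vapply(alphas, function(a) make_threshold("any", "right", a, 3),
                 numeric(1))
  expect_true(all(diff(cuts) < 0))
  expect_error(make_threshold("any", "right", 0.7, 2), "alpha")
})

test_that("posterior region probabilities match a closed-form normal oracle", {
  H <- config_matrix(1)
  set.seed(62)
  # K = 1: delta draws ~ N(0.1, 0.05^2); P(delta > 0) = pnorm(2)
  th1 <- matrix(pmin(pmax(0.5 + rnorm(40000, 0.1, 0.05), 0.01), 0.99))
  th0 <- matrix(rep(0.5, 40000))
  eff <- bmlr:::effects_from_phi(cbind(th0, 1 - th0), cbind(th1, 1 - th1), H)
  dec <- decide(eff, decision_rule("any"))
  expect_equal(dec$p_superior, pnorm(2), tolerance = 0.01)
  # K = 1: the region probability and the per-endpoint probability coincide
  expect_equal(unname(region_prob(eff, decision_rule("any"))["sup"]),
               dec$p_superior)
  # draw-permutation invariance
  eff2 <- bmlr:::effects_from_phi(cbind(th0, 1 - th0),
                                  cbind(th1, 1 - th1)[sample(40000), ,
                                                      drop = FALSE], H)
  expect_equal(decide(eff2, decision_rule("any"))$p_superior,
               dec$p_superior, tolerance = 0.01)
})

test_that("union-region probability dominates the per-endpoint maximum", {
  # P(any delta_k > 0 | y) >= max_k P(delta_k > 0 | y): thresholding the
  # union probability at 1 - alpha/K would inflate the Type I error, which
  # is why decide() thresholds the per-endpoint probabilities.
  set.seed(66)
  H <- config_matrix(2)
  th1 <- cbind(0.5 + rnorm(5000, 0, 0.05), 0.5 + rnorm(5000, 0, 0.05))
  th1 <- pmin(pmax(th1, 0.01), 0.99)
  phi1 <- t(apply(th1, 1, phi_from_margins, rho = 0))
  phi0 <- matrix(rep(phi_from_margins(c(0.5, 0.5), 0), each = 5000), 5000, 4)
  eff <- bmlr:::effects_from_phi(phi0, phi1, H)
  rp <- region_prob(eff, decision_rule("any"))
  dec <- decide(eff, decision_rule("any"))
  expect_gte(rp[["sup"]], dec$p_superior)
  # intersection region is dominated by the per-endpoint minimum (All rule)
  rp_all <- region_prob(eff, decision_rule("all"))
  dec_all <- decide(eff, decision_rule("all"))
  expect_lte(rp_all[["sup"]], dec_all$p_superior)
})

test_that("decisions compare probabilities strictly with p_cut", {
  H <- config_matrix(2)
  mk <- function(p_sup) {
    # all-positive or all-negative draws in the stated proportion
    n <- 2000
    pos <- round(n * p_sup)
    d1 <- c(rep(0.1, pos), rep(-0.1, n - pos))
    phi1 <- t(vapply(d1, function(d) phi_from_margins(c(0.5 + d, 0.5 + d), 0),
                     numeric(4)))
    phi0 <- matrix(rep(phi_from_margins(c(0.5, 0.5), 0), each = n), n, 4)
    bmlr:::effects_from_phi(phi0, phi1, H)
  }
  all_r <- decision_rule("all")  # p_cut 0.95
  expect_equal(decide(mk(0.99), all_r)$conclusion, "superior")
  expect_equal(decide(mk(0.95), all_r)$conclusion, "inconclusive")  # not >
  two <- decision_rule("all", side = "two_sided")  # p_cut 0.975
  expect_equal(decide(mk(0.02), two)$conclusion, "inferior")
  expect_equal(decide(mk(1), two)$conclusion, "superior")
})
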