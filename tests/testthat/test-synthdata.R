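test_that("margins and correlation convert to joint cells exactly (K = 2)", {
  expect_equal(phi_from_margins(c(0.5, 0.5), 0), rep(0.25, 4))
  expect_equal(phi_from_margins(c(0.5, 0.5), 0.2), c(0.3, 0.2, 0.2, 0.3))
  # margins reproduced for arbitrary feasible input
  set.seed(71)
  H <- config_matrix(2)
  for (i in 1:25) {
    th <- runif(2, 0.2, 0.8)
    rho <- runif(1, -0.15, 0.15)
    phi <- phi_from_margins(th, rho)
    expect_equal(sum(phi), 1, tolerance = 1e-12)
    expect_equal(unname(phi_to_theta(phi, H)), th, tolerance = 1e-12)
    # implied phi coefficient equals the requested correlation
    p11 <- phi[1]
    expect_equal((p11 - prod(th)) / sqrt(prod(th * (1 - th))), rho,
                 tolerance = 1e-12)
  }
  # Frechet bound violations: a strong negative correlation between two
  # common events pushes the joint-success cell below its lower bound, and a
  # strong positive one between a common and a rare event pushes it above
  # min(theta); both must error.
  expect_error(phi_from_margins(c(0.9, 0.9), -0.9), "Infeasible")
  expect_error(phi_from_margins(c(0.9, 0.1), 0.9), "Infeasible")
})

test_that("triple-endpoint cells honor margins and pairwise correlations", {
  H <- config_matrix(3)
  th <- c(0.6, 0.5, 0.4); rho <- 0.15
  phi <- phi_from_margins(th, rho)
  expect_equal(sum(phi), 1, tolerance = 1e-12)
  expect_equal(unname(phi_to_theta(phi, H)), th, tolerance = 1e-12)
  s <- sqrt(th * (1 - th))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    k <- pair[1]; l <- pair[2]
    pkl <- sum(phi[H[, k] == 1 & H[, l] == 1])
    expect_equal((pkl - th[k] * th[l]) / (s[k] * s[l]), rho,
                 tolerance = 1e-12)
  }
  expect_error(phi_from_margins(c(0.9, 0.9, 0.1), -0.5), "Infeasible")
})

test_that("sampled data reproduce the stated margins and correlations", {
  set.seed(72)
  n <- 1e5
  phi <- phi_from_margins(c(0.6, 0.45), 0.2)
  H <- config_matrix(2)
  idx <- sample.int(4, n, replace = TRUE, prob = phi)
  Y <- decode_categories(idx, H)
  expect_lt(max(abs(colMeans(Y) - c(0.6, 0.45))), 0.01)
  expect_lt(abs(cor(Y[, 1], Y[, 2]) - 0.2), 0.02)
})

test_that("cell inversion to coefficients round-trips exactly", {
  set.seed(73)
  for (anchors in list(c(0, 1), c(-1, 1))) {
    cells <- list(phi0_low = phi_from_margins(runif(2, .3, .7), 0.1),
                  phi0_high = phi_from_margins(runif(2, .3, .7), -0.1),
                  phi1_low = phi_from_margins(runif(2, .3, .7), 0.2),
                  phi1_high = phi_from_margins(runif(2, .3, .7), 0))
    beta <- beta_from_cells(cells, anchors)
    grid <- list(c(0, anchors[1], "phi0_low"), c(0, anchors[2], "phi0_high"),
                 c(1, anchors[1], "phi1_low"), c(1, anchors[2], "phi1_high"))
    for (g in grid) {
      arm <- as.numeric(g[1]); a <- as.numeric(g[2])
      x <- c(1, arm, a, a * arm)
      expect_equal(inverse_mlogit(drop(x %*% beta)),
                   cells[[g[3]]], tolerance = 1e-10)
    }
  }
  # homogeneity: identical cells give zero treatment/covariate coefficients
  phi <- phi_from_margins(c(0.55, 0.5), 0.1)
  cells0 <- list(phi0_low = phi, phi0_high = phi, phi1_low = phi,
                 phi1_high = phi)
  b0 <- beta_from_cells(cells0, c(0, 1))
  expect_equal(unname(b0[2:4, ]), matrix(0, 3, 3), tolerance = 1e-10)
  expect_equal(unname(b0[1, ]), log(phi[-4] / phi[4]), tolerance = 1e-10)
  expect_error(beta_from_cells(cells0, c(1, 1)), "must differ")
})

test_that("binary-covariate average effects are the exact half-half mixture", {
  sp <- dgm_preset("ES3", "binary", rho = 0.2)
  mix_phi0 <- 0.5 * sp$cells$phi0_low + 0.5 * sp$cells$phi0_high
  mix_phi1 <- 0.5 * sp$cells$phi1_low + 0.5 * sp$cells$phi1_high
  expect_equal(unname(sp$truth$average$delta),
               unname(phi_to_theta(mix_phi1, sp$H) -
                        phi_to_theta(mix_phi0, sp$H)), tolerance = 1e-12)
  expect_equal(unname(sp$truth$conditional$low$delta), c(0.25, 0.15),
               tolerance = 1e-12)
})

test_that("the heterogeneous null preset cancels to a zero average effect", {
  for (cov_type in c("binary", "normal")) {
    sp <- dgm_preset("ES2", cov_type, rho = 0.1)
    expect_equal(unname(sp$truth$conditional$low$delta), c(0.2, 0.1),
                 tolerance = 1e-9)
    # conditional effects are non-null but the ATE vanishes (exactly for the
    # binary mixture; near-exactly under the symmetric normal law)
    expect_lt(max(abs(sp$truth$average$delta)),
              if (cov_type == "binary") 1e-9 else 0.01)
  }
})

test_that("generated trials are seeded, sized and consistent with the manifest", {
  sp <- dgm_preset("ES3", "normal", rho = -0.2)
  d1 <- generate_trial(sp, 500, seed = 74)
  d2 <- generate_trial(sp, 500, seed = 74)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 1000L)
  expect_equal(sum(d1$treat), 500L)
  # manifest self-consistency: empirical effects from a large draw match the
  # quadrature ground truth
  big <- generate_trial(sp, 5e5, seed = 75)
  emp <- vapply(c("y1", "y2"), function(y)
    mean(big[[y]][big$treat == 1]) - mean(big[[y]][big$treat == 0]),
    numeric(1))
  expect_lt(max(abs(unname(emp) - unname(sp$truth$average$delta))), 0.005)
  # anchor-cell correlations close to the stated rho
  at0 <- abs(big$z + 1) < 0.1 & big$treat == 0
  expect_lt(abs(cor(big$y1[at0], big$y2[at0]) + 0.2), 0.05)
})
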