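test_that("state fractions are conserved and match a direct Boltzmann oracle", {
  set.seed(17)
  RT_of <- function(T_K) R_KCAL * T_K
  for (i in 1:1000) {
    p <- three_state_params(runif(1, -25, -0.5), runif(1, -25, -0.5),
                            runif(1, 0.2, 8), runif(1, 0.2, 8),
                            runif(1))
    x <- runif(1, 0, 6)
    T_K <- runif(1, 273, 330)
    fr <- state_fractions(x, p, T_K)
    expect_lt(abs(sum(fr) - 1), 1e-12)
    # oracle: independent algebraic arrangement of the same Boltzmann
    # weights, normalized against the folded state instead of the
    # intermediate
    RT <- RT_of(T_K)
    A <- -(p$dG1_0 + p$m1 * x) / RT
    B <- -(p$dG2_0 + p$m2 * x) / RT
    fF <- 1 / (1 + exp(-A) + exp(-A - B))
    fI <- exp(-A) * fF
    fU <- exp(-A - B) * fF
    expect_equal(unname(fr[1, ]), c(fF, fI, fU), tolerance = 1e-12)
  }
})

test_that("limit cases of the three-state populations", {
  # both stages at midpoint: all three states equally populated
  p <- three_state_params(-3, -4, 2, 2, 0.5)
  x_iso <- 1.5  # Cm1 = 1.5; pick dG2 so Cm2 = 1.5 too
  p2 <- three_state_params(-3, -3, 2, 2, 0.5)
  fr <- state_fractions(x_iso, p2)
  expect_equal(unname(fr[1, ]), rep(1 / 3, 3), tolerance = 1e-12)
  # strongly folded limit at zero denaturant
  p3 <- three_state_params(-10, -10, 2, 2, 0.5)
  fr3 <- state_fractions(0, p3)
  expect_lt(abs(fr3[1, "fF"] - 1), 1e-7)
  # extreme energies do not overflow
  p4 <- three_state_params(-30, -30, 10, 10, 0.5)
  expect_true(all(is.finite(state_fractions(c(0, 100), p4))))
})

test_that("helical signal reduces to the stated algebraic identities", {
  set.seed(29)
  for (i in 1:50) {
    p <- three_state_params(runif(1, -10, -1), runif(1, -10, -1),
                            runif(1, 0.5, 5), runif(1, 0.5, 5), runif(1))
    x <- seq(0, 5, length.out = 7)
    fr <- state_fractions(x, p)
    y <- helical_signal(x, p)
    # y = fF + gamma fI = 1 - fI - fU + gamma fI
    expect_equal(y, unname(1 - fr[, "fI"] - fr[, "fU"] + p$gamma * fr[, "fI"]),
                 tolerance = 1e-12)
    expect_equal(helical_signal(x, p, unfolded = TRUE), 1 - y)
  }
  p0 <- three_state_params(-4, -5, 2, 2, 0)
  fr0 <- state_fractions(1, p0)
  expect_equal(helical_signal(1, p0), unname(fr0[, "fF"]))
  p1 <- three_state_params(-4, -5, 2, 2, 1)
  fr1 <- state_fractions(1, p1)
  expect_equal(helical_signal(1, p1), unname(1 - fr1[, "fU"]))
})

test_that("midpoints follow the closed form and the population crossing", {
  p <- three_state_params(-3, -4.5, 2, 1.8, 0.5)
  cm <- midpoints(p)
  expect_equal(unname(cm["Cm1"]), 1.5)
  expect_equal(unname(cm["Cm2"]), 2.5)
  # at Cm1 the folded and intermediate populations cross (root-finding oracle)
  root <- uniroot(function(x) {
    fr <- state_fractions(x, p)
    fr[1, "fF"] - fr[1, "fI"]
  }, c(0.1, 2.4), tol = 1e-12)$root
  expect_equal(root, unname(cm["Cm1"]), tolerance = 1e-9)
  # joint scaling of (dG, m) leaves the midpoint unchanged
  p2 <- three_state_params(-6, -9, 4, 3.6, 0.5)
  expect_equal(midpoints(p2), cm)
})

test_that("fU is nondecreasing in denaturant when both m-values are positive", {
  set.seed(41)
  for (i in 1:20) {
    p <- three_state_params(runif(1, -12, -1), runif(1, -12, -1),
                            runif(1, 0.3, 6), runif(1, 0.3, 6), runif(1))
    x <- seq(0, 8, length.out = 100)
    fU <- state_fractions(x, p)[, "fU"]
    expect_true(all(diff(fU) >= -1e-12))
  }
})

test_that("noise-free melts are recovered to high relative accuracy", {
  p <- three_state_params(-3.0, -4.5, 2.0, 1.8, 0.6)
  d <- gen_denaturation(p, x_grid = seq(0, 4, length.out = 30), sigma = 0)
  f <- fit_three_state(d)
  est <- unlist(f$params)
  expect_equal(unname(est), unname(unlist(p)), tolerance = 1e-6)
  expect_equal(f$dG_fold, -7.5, tolerance = 1e-6)
  expect_equal(f$dG_fold, f$params$dG1_0 + f$params$dG2_0)
})

test_that("dG_fold recovery is unbiased at realistic noise (Monte-Carlo)", {
  p <- three_state_params(-3.0, -4.5, 2.0, 1.8, 0.6)
  errs <- numeric(120)
  for (r in seq_along(errs)) {
    d <- gen_denaturation(p, x_grid = seq(0, 4, length.out = 30),
                          sigma = 0.01, seed = 1000 + r)
    f <- fit_three_state(d)
    errs[r] <- f$dG_fold - (-7.5)
  }
  expect_lt(median(abs(errs)), 0.5)
})

test_that("two-state data leave gamma unidentifiable and flagged", {
  # genuinely two-state melt (no populated intermediate): the three-state
  # model can absorb it many ways, so gamma carries no information
  x <- seq(0, 4, length.out = 30)
  RT <- R_KCAL * 298.15
  set.seed(3)
  y <- 1 / (1 + exp((-5 + 2.5 * x) / RT)) + rnorm(30, 0, 0.005)
  f <- suppressWarnings(fit_three_state(data.frame(x_M = x, y_norm = y)))
  expect_true(f$gamma_unidentifiable)
  # a well-determined three-state melt is NOT flagged
  p <- three_state_params(-3, -4.5, 2, 1.8, 0.6)
  d <- gen_denaturation(p, sigma = 0.01, seed = 19)
  f2 <- fit_three_state(d)
  expect_false(f2$gamma_unidentifiable)
})

test_that("baseline normalization maps raw ellipticity onto [0,1]", {
  x <- seq(0, 4, length.out = 40)
  p <- three_state_params(-3, -4.5, 2, 1.8, 0.6)
  y <- helical_signal(x, p)
  raw <- -22000 * y - 1500 - 120 * x   # sloping baselines
  norm <- normalize_baselines(x, raw, pre_window = c(0, 0.4),
                              post_window = c(3.6, 4))
  expect_equal(norm$y_norm, unname(y), tolerance = 0.05)
})

test_that("fit guards: too few points and bad gamma are rejected", {
  p <- three_state_params(-3, -4.5, 2, 1.8, 0.6)
  d <- gen_denaturation(p, x_grid = seq(0, 4, length.out = 5), sigma = 0)
  expect_error(fit_three_state(d), "at least 10")
  expect_error(three_state_params(-3, -4, 2, 2, 1.2), "gamma")
})
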