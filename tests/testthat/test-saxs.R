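test_that("absolute-scale conversion implements the buffer subtraction", {
  q <- seq(0.01, 0.1, by = 0.01)
  consts <- saxs_constants(f = 2)
  # worked arithmetic: (10 - 0.995*2)/2 = 4.005 with cp*v = 0.005
  cp <- 0.005 / consts$v
  s <- saxs_profile(q, rep(10, 10), cp = cp)
  b <- saxs_profile(q, rep(2, 10), is_buffer = TRUE)
  out <- absolute_intensity(s, b, consts)
  expect_equal(out$I, rep((10 - 0.995 * 2) / 2, 10))
  # cp = 0, f = 1: plain subtraction
  s0 <- saxs_profile(q, rep(10, 10), cp = 0)
  out0 <- absolute_intensity(s0, b, saxs_constants(f = 1))
  expect_equal(out0$I, rep(8, 10))
  # doubling f halves the output
  out2 <- absolute_intensity(s, b, saxs_constants(f = 4))
  expect_equal(out2$I * 2, out$I)
  # error propagation in quadrature
  sn <- saxs_profile(q, rep(10, 10), sigma = rep(0.3, 10), cp = cp)
  bn <- saxs_profile(q, rep(2, 10), sigma = rep(0.1, 10), is_buffer = TRUE)
  outn <- absolute_intensity(sn, bn, consts)
  expect_equal(outn$sigma,
               rep(sqrt(0.3^2 + (0.995 * 0.1)^2) / 2, 10))
  # guards
  expect_error(absolute_intensity(s, s0, consts), "not flagged")
  b2 <- saxs_profile(q + 0.001, rep(2, 10), is_buffer = TRUE)
  expect_error(absolute_intensity(s, b2, consts), "grids differ")
})

test_that("Guinier extrapolation is exact on a Gaussian profile", {
  q <- seq(0.01, 0.3, by = 0.005)
  prof <- saxs_profile(q, 5 * exp(-q^2 * 18^2 / 3))
  g <- suppressWarnings(guinier_extrapolate(prof))
  expect_equal(g$I0, 5, tolerance = 1e-10)
  expect_equal(g$Rg, 18, tolerance = 1e-10)
  # window fixed point: all retained points satisfy q*Rg <= 1.3
  expect_true(all(q[q <= g$window[2]] * g$Rg <= 1.3 + 1e-9))
  # fixed point independent of the starting window for exact input
  g2 <- suppressWarnings(guinier_extrapolate(prof, q_max_init = 0.1))
  expect_equal(g2$I0, g$I0, tolerance = 1e-10)
  expect_equal(g2$Rg, g$Rg, tolerance = 1e-10)
  expect_equal(g2$window, g$window)
  # rising profile signals aggregation
  bad <- saxs_profile(q, 5 * exp(q^2 * 10))
  expect_error(suppressWarnings(guinier_extrapolate(bad)), "slope")
})

test_that("Guinier Rg is accurate to ~2% at 1% noise (Monte-Carlo)", {
  q <- seq(0.01, 0.55, by = 0.002)
  rgs <- numeric(200)
  set.seed(55)
  for (r in 1:200) {
    I <- 0.2 * exp(-q^2 * 15^2 / 3) * (1 + rnorm(length(q), 0, 0.01))
    rgs[r] <- guinier_extrapolate(saxs_profile(q, I))$Rg
  }
  expect_lt(abs(mean(rgs) - 15) / 15, 0.02)
})

test_that("virial fit recovers ideal and interacting solutions", {
  consts <- saxs_constants()
  # ideal solution (A2 = 0): slope ~0, M exact
  cp <- c(0.002, 0.005, 0.01, 0.02, 0.04, 0.07)
  I0 <- consts$k * 17200 * cp
  f <- suppressWarnings(fit_virial(data.frame(cp = cp, I0 = I0), consts))
  expect_equal(f$A2, 0, tolerance = 1e-12)
  expect_equal(f$M, 17200, tolerance = 1e-9)
  # generator round-trip at stated truth
  I0b <- consts$k * 17200 * cp / (1 + 2 * 1e-4 * 17200 * cp)
  fb <- suppressWarnings(fit_virial(data.frame(cp = cp, I0 = I0b), consts))
  expect_equal(fb$A2, 1e-4, tolerance = 1e-9)
  expect_equal(fb$M, 17200, tolerance = 1e-6)
  # attractive regime: negative A2 propagates sign
  I0c <- consts$k * 17200 * cp / (1 - 2 * 1e-4 * 17200 * cp)
  fc <- suppressWarnings(fit_virial(data.frame(cp = cp, I0 = I0c), consts))
  expect_lt(fc$A2, 0)
  expect_error(fit_virial(data.frame(cp = cp[1:2], I0 = I0[1:2]), consts),
               "3 distinct")
})

test_that("hard-sphere reference A2 follows the 4v/M law", {
  expect_equal(hard_sphere_A2(17200, 0.7425), 1.727e-4, tolerance = 5e-4)
  expect_equal(hard_sphere_A2(2 * 17200), hard_sphere_A2(17200) / 2)
  expect_gt(hard_sphere_A2(1e5), 0)
})

test_that("raw synthetic series pushed through the full reduction recovers A2 and M", {
  sim <- gen_saxs_series(M = 17200, A2 = 1e-4, Rg = 15,
                         sigma_frac = 0.01, seed = 101)
  consts <- sim$truth$consts
  series <- do.call(rbind, lapply(sim$pairs, function(pr) {
    ab <- absolute_intensity(pr$sample, pr$buffer, consts)
    g <- guinier_extrapolate(ab)
    data.frame(cp = pr$sample$cp, I0 = g$I0)
  }))
  f <- fit_virial(series, consts)
  expect_lt(abs(f$A2 - 1e-4) / 1e-4, 0.15)
  expect_lt(abs(f$M - 17200) / 17200, 0.05)
  # zero-noise round-trip is exact
  sim0 <- gen_saxs_series(M = 17200, A2 = 1e-4, Rg = 15, sigma_frac = 0)
  series0 <- do.call(rbind, lapply(sim0$pairs, function(pr) {
    ab <- absolute_intensity(pr$sample, pr$buffer, consts)
    g <- suppressWarnings(guinier_extrapolate(ab))
    data.frame(cp = pr$sample$cp, I0 = g$I0)
  }))
  f0 <- suppressWarnings(fit_virial(series0, consts))
  expect_equal(f0$A2, 1e-4, tolerance = 1e-6)
  expect_equal(f0$M, 17200, tolerance = 1e-6)
})

test_that("unit conversions are explicit and exact", {
  expect_equal(mg_per_ml_to_g_per_cm3(35), 0.035)
  expect_equal(per_nm_to_per_angstrom(1.5), 0.15)
})

test_that("profile reader handles 3-column text with comments", {
  tf <- tempfile(fileext = ".dat")
  writeLines(c("# q I sigma", "0.01 5.0 0.05", "0.02 4.9 0.05",
               "0.03 4.7 0.05"), tf)
  p <- read_saxs_profile(tf, cp = 0.01)
  expect_equal(p$q, c(0.01, 0.02, 0.03))
  expect_equal(p$sigma, rep(0.05, 3))
  expect_equal(p$cp, 0.01)
})
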