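# Concentration-series SAXS reduction:
#   absolute scale    I(q) = [I_S(q) - (1 - cp*v) I_B(q)] / f
#   Guinier           ln I(q) = ln I(0) - q^2 Rg^2 / 3   (q*Rg <= 1.3)
#   virial series     I(0) = k M cp / (1 + 2 A2 M cp),  k = v^2 (drho)^2 / NA
# Units are strict: q in 1/Angstrom, cp in g/cm^3, absolute I in 1/cm.

AVOGADRO <- 6.02214076e23

#' SAXS reduction constants
#'
#' @param v partial specific volume of the solute, cm^3/g.
#' @param f arbitrary-to-absolute intensity correction factor.
#' @param drho electron density difference between protein and solvent,
#'   cm^-2 (typical value 2.8e10).
#' @return list with `v`, `f`, `drho` and the contrast constant
#'   `k = v^2 drho^2 / NA` (cm^2 mol/g^2).
#' @export
saxs_constants <- function(v = 0.7425, f = 1, drho = 2.8e10) {
  stopifnot(v > 0, f > 0, drho > 0)
  list(v = v, f = f, drho = drho, k = v^2 * drho^2 / AVOGADRO)
}

#' Construct a SAXS profile
#'
#' @param q scattering vector magnitudes, 1/Angstrom, strictly increasing.
#' @param I intensities (arbitrary units before reduction, 1/cm after).
#' @param sigma optional per-point uncertainties (> 0).
#' @param cp protein concentration, g/cm^3 (0 for buffer).
#' @param is_buffer logical flag.
#' @return object of class `saxs_profile`.
#' @export
saxs_profile <- function(q, I, sigma = NULL, cp = 0, is_buffer = FALSE) {
  stopifnot(length(q) == length(I))
  if (any(diff(q) <= 0)) stop("q grid must be strictly increasing")
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    if (any(sigma <= 0)) stop("sigma must be positive where given")
  }
  if (cp < 0) stop("cp must be >= 0")
  structure(list(q = q, I = I, sigma = sigma, cp = cp,
                 is_buffer = isTRUE(is_buffer)),
            class = "saxs_profile")
}

#' Read a 3-column SAXS profile file
#'
#' Whitespace- or comma-separated columns q, I, sigma (sigma optional).
#' Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param cp protein concentration, g/cm^3.
#' @param is_buffer logical flag.
#' @return a [saxs_profile].
#' @export
read_saxs_profile <- function(path, cp = 0, is_buffer = FALSE) {
  d <- read.table(path, header = FALSE, comment.char = "#",
                  sep = "", fill = TRUE)
  if (ncol(d) == 1)
    d <- read.csv(path, header = FALSE, comment.char = "#")
  sigma <- if (ncol(d) >= 3) d[[3]] else NULL
  saxs_profile(d[[1]], d[[2]], sigma, cp = cp, is_buffer = is_buffer)
}

#' Convert a sample + buffer profile pair to absolute scale
#'
#' Applies I(q) = \[I_S(q) - (1 - cp v) I_B(q)\] / f with uncertainties
#' propagated in quadrature using the same coefficients. The two profiles
#' must share a q grid; no implicit resampling is performed.
#'
#' @param sample [saxs_profile] of the protein solution (cp > 0 allowed 0).
#' @param buffer [saxs_profile] with `is_buffer = TRUE`.
#' @param consts a [saxs_constants()] list.
#' @return a [saxs_profile] on absolute scale (1/cm).
#' @export
absolute_intensity <- function(sample, buffer, consts = saxs_constants()) {
  if (!buffer$is_buffer) stop("'buffer' profile is not flagged as buffer")
  if (length(sample$q) != length(buffer$q) ||
      any(abs(sample$q - buffer$q) > 1e-12))
    stop("sample and buffer q grids differ; resample explicitly first")
  w <- 1 - sample$cp * consts$v
  if (w <= 0) stop("cp * v >= 1: unphysical concentration")
  I <- (sample$I - w * buffer$I) / consts$f
  sigma <- NULL
  if (!is.null(sample$sigma) && !is.null(buffer$sigma))
    sigma <- sqrt(sample$sigma^2 + (w * buffer$sigma)^2) / consts$f
  saxs_profile(sample$q, I, sigma, cp = sample$cp, is_buffer = FALSE)
}

#' Guinier extrapolation to zero angle
#'
#' Linear fit of ln I against q^2 inside the Guinier window, with the
#' window chosen self-consistently: starting from the full profile (or
#' `q_max_init`), fit, compute Rg, restrict to q*Rg <= `qrg_max`, and
#' repeat until the window is stable (at most `max_iter` rounds).
#'
#' @param profile a [saxs_profile] on absolute scale.
#' @param qrg_max Guinier window limit, default 1.3 (globular proteins).
#' @param q_max_init initial upper q bound before the first fit.
#' @param max_iter maximum window iterations.
#' @return object of class `guinier_fit`: `I0`, `Rg`, standard errors,
#'   `n_points`, `window` (q range used), `iterations`.
#' @export
guinier_extrapolate <- function(profile, qrg_max = 1.3, q_max_init = Inf,
                                max_iter = 20) {
  q <- profile$q; I <- profile$I
  keep <- I > 0 & q <= q_max_init
  if (sum(keep) < 5) stop("fewer than 5 usable points")
  sel <- keep
  prev <- NULL
  it <- 0
  repeat {
    it <- it + 1
    fit <- lm(log(I[sel]) ~ I(q[sel]^2))
    slope <- unname(coef(fit)[2])
    if (slope >= 0)
      stop("non-negative Guinier slope: aggregation or bad buffer subtraction")
    Rg <- sqrt(-3 * slope)
    new_sel <- keep & (q * Rg <= qrg_max)
    if (sum(new_sel) < 5)
      stop("Guinier window shrank below 5 points")
    # fixed point, or a period-2 oscillation between adjacent windows
    # (possible with noisy data); either counts as converged
    if (identical(new_sel, sel) || identical(new_sel, prev)) {
      sel <- new_sel
      break
    }
    if (it >= max_iter)
      stop("Guinier window did not converge in ", max_iter, " iterations")
    prev <- sel
    sel <- new_sel
  }
  fit <- lm(log(I[sel]) ~ I(q[sel]^2))
  cf <- summary(fit)$coefficients
  slope <- unname(cf[2, 1])
  if (slope >= 0)
    stop("non-negative Guinier slope in final window")
  I0 <- exp(unname(cf[1, 1]))
  Rg <- sqrt(-3 * slope)
  structure(list(
    I0 = I0, Rg = Rg,
    se_I0 = I0 * unname(cf[1, 2]),          # delta method on exp(intercept)
    se_Rg = if (cf[2, 1] < 0) 3 * unname(cf[2, 2]) / (2 * Rg) else NA_real_,
    n_points = sum(sel),
    window = range(q[sel]), iterations = it, qrg_max = qrg_max,
    cp = profile$cp),
    class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> I(0) = %.4g (se %.2g) 1/cm, Rg = %.3f (se %.2g) A, n = %d, q in [%.4f, %.4f]\n",
              x$I0, x$se_I0, x$Rg, x$se_Rg, x$n_points,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Second virial coefficient from a concentration series of I(0)
#'
#' Linearized fit of cp / I(0) = 1/(kM) + (2 A2 / k) cp by least squares.
#' M = 1 / (k * intercept) and A2 = slope * k / 2, with standard errors by
#' first-order propagation.
#'
#' @param series data.frame (or list) with columns `cp` (g/cm^3) and `I0`
#'   (1/cm), one row per concentration.
#' @param consts a [saxs_constants()] list.
#' @return object of class `virial_fit`: `A2` (cm^3 mol/g^2), `M` (g/mol),
#'   standard errors, the per-concentration table, and the underlying lm.
#' @export
fit_virial <- function(series, consts = saxs_constants()) {
  cp <- series$cp; I0 <- series$I0
  if (length(cp) < 3 || length(unique(cp)) < 3)
    stop("need at least 3 distinct concentrations")
  if (any(cp <= 0)) stop("cp must be positive")
  if (any(I0 <= 0)) stop("I0 must be positive")
  y <- cp / I0
  fit <- lm(y ~ cp)
  cf <- summary(fit)$coefficients
  a <- unname(cf[1, 1]); b <- unname(cf[2, 1])
  if (a <= 0)
    stop("non-positive intercept: unphysical molecular weight")
  k <- consts$k
  M <- 1 / (k * a)
  A2 <- b * k / 2
  structure(list(
    A2 = A2, M = M,
    se_A2 = unname(cf[2, 2]) * k / 2,
    se_M = unname(cf[1, 2]) / (k * a^2),   # |dM/da| * se_a
    series = data.frame(cp = cp, I0 = I0),
    k = k, lm = fit),
    class = "virial_fit")
}

#' @export
print.virial_fit <- function(x, ...) {
  cat(sprintf("<virial_fit> A2 = %.4g (se %.2g) cm^3 mol/g^2, M = %.0f (se %.0f) g/mol, %d concentrations\n",
              x$A2, x$se_A2, x$M, x$se_M, nrow(x$series)))
  invisible(x)
}

#' Hard-sphere reference second virial coefficient
#'
#' Excluded-volume A2 of hard spheres on a mass basis: A2_HS = 4 v / M.
#'
#' @param M molecular weight, g/mol.
#' @param v specific volume, cm^3/g.
#' @return A2 in cm^3 mol/g^2.
#' @export
hard_sphere_A2 <- function(M, v = 0.7425) {
  stopifnot(M > 0, v > 0)
  4 * v / M
}

#' Explicit unit conversions used by the SAXS module
#'
#' @param x numeric values.
#' @return converted values.
#' @export
mg_per_ml_to_g_per_cm3 <- function(x) x / 1000

#' @rdname mg_per_ml_to_g_per_cm3
#' @export
per_nm_to_per_angstrom <- function(x) x / 10
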