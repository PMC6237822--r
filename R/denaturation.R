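# Three-state chemical denaturation, F <=> I <=> U, with linear
# free-energy dependence on denaturant x:
#   dG1(x) = dG1_0 + m1 x   (folded relative to intermediate)
#   dG2(x) = dG2_0 + m2 x   (intermediate relative to unfolded)
# With A = -dG1(x)/RT and B = -dG2(x)/RT the state fractions are
#   fI = 1/(1 + e^A + e^-B),  fF = e^A fI,  fU = e^-B fI
# and the normalized helical signal is y = fF + gamma * fI, gamma being
# the intermediate's helical content relative to the folded state.

#' Three-state parameter set
#'
#' @param dG1_0,dG2_0 stage free energies at zero denaturant, kcal/mol
#'   (negative for a protein folded in water).
#' @param m1,m2 denaturant m-values, kcal/mol/M (positive).
#' @param gamma intermediate helical content relative to folded, in \[0,1\].
#' @return a named list of class `three_state_params`.
#' @export
three_state_params <- function(dG1_0, dG2_0, m1, m2, gamma) {
  p <- list(dG1_0 = dG1_0, dG2_0 = dG2_0, m1 = m1, m2 = m2, gamma = gamma)
  if (any(!vapply(p, is.finite, TRUE))) stop("non-finite parameter")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  structure(p, class = "three_state_params")
}

#' Equilibrium state fractions of the three-state model
#'
#' Overflow-safe: the three Boltzmann weights are normalized after
#' subtracting their common maximum exponent, so extreme free energies do
#' not overflow. Fractions sum to 1 to within 1e-12 by construction.
#'
#' @param x denaturant concentration(s), M.
#' @param p a [three_state_params()].
#' @param T_K temperature, K.
#' @return matrix with columns `fF`, `fI`, `fU` (one row per `x`).
#' @export
state_fractions <- function(x, p, T_K = 298.15) {
  stopifnot(T_K > 0)
  RT <- R_KCAL * T_K
  A <- -(p$dG1_0 + p$m1 * x) / RT
  B <- -(p$dG2_0 + p$m2 * x) / RT
  # log-weights relative to the intermediate: F = A, I = 0, U = -B
  lw <- cbind(fF = A, fI = 0 * A, fU = -B)
  m <- apply(lw, 1L, max)
  w <- exp(lw - m)
  w / rowSums(w)
}

#' Normalized helical CD signal of the three-state model
#'
#' y = fF + gamma * fI. The complementary unfolded-style trace 1 - y is
#' available via `unfolded = TRUE` for plotting denaturation profiles.
#'
#' @inheritParams state_fractions
#' @param unfolded if `TRUE`, return 1 - y.
#' @return numeric vector of signals.
#' @export
helical_signal <- function(x, p, T_K = 298.15, unfolded = FALSE) {
  if (p$gamma < 0 || p$gamma > 1) stop("gamma must lie in [0, 1]")
  fr <- state_fractions(x, p, T_K)
  y <- unname(fr[, "fF"] + p$gamma * fr[, "fI"])
  if (unfolded) 1 - y else y
}

#' Denaturation midpoints of the two stages
#'
#' Cm_i = -dGi_0 / m_i, the denaturant concentration at which stage i is
#' half-converted.
#'
#' @param p a [three_state_params()].
#' @return named numeric `c(Cm1, Cm2)` in M.
#' @export
midpoints <- function(p) {
  if (p$m1 == 0 || p$m2 == 0) stop("zero m-value: midpoint undefined")
  c(Cm1 = -p$dG1_0 / p$m1, Cm2 = -p$dG2_0 / p$m2)
}

# two-state pre-fit used only for initialization: y = 1/(1 + exp((dG + m x)/RT))
two_state_init <- function(x, y, RT) {
  # midpoint: signal closest to 0.5; slope from a coarse logistic grid
  cm0 <- x[which.min(abs(y - 0.5))]
  best <- c(dG = -2, m = 2); best_ss <- Inf
  for (m in c(0.5, 1, 1.5, 2, 3, 4, 6)) {
    dG <- -m * cm0
    yy <- 1 / (1 + exp((dG + m * x) / RT))
    ss <- sum((y - yy)^2)
    if (ss < best_ss) { best_ss <- ss; best <- c(dG = dG, m = m) }
  }
  opt <- try(stats::optim(best, function(par) {
    yy <- 1 / (1 + exp((par[1] + par[2] * x) / RT))
    sum((y - yy)^2)
  }), silent = TRUE)
  if (!inherits(opt, "try-error")) best <- opt$par
  best
}

#' Fit the three-state denaturation model to a normalized melt
#'
#' Nonlinear least squares of the helical signal against the observed
#' normalized CD trace over (dG1_0, dG2_0, m1, m2, gamma), using
#' Levenberg-Marquardt with box bounds (gamma in \[0,1\], dGi_0 in
#' \[-30, 0\], mi in (0, 10\]). Initialization comes from a two-state
#' pre-fit whose total dG and m are split 40/60 between the stages, with
#' gamma started at 0.5. Bound-pinned gamma and rank-deficient Jacobians
#' are flagged, not silently accepted.
#'
#' @param data data.frame with columns `x_M` (denaturant, M) and `y_norm`
#'   (normalized signal); optional `sigma` column enables weighted LS.
#' @param T_K temperature, K.
#' @param init optional [three_state_params()] overriding the default
#'   initialization.
#' @return object of class `three_state_fit`: `params`, `dG_fold`
#'   (= dG1_0 + dG2_0), `se` (named vector or NULL when the Jacobian is
#'   rank-deficient), `se_dG_fold`, `residual_norm`, `gamma_at_bound`,
#'   `gamma_unidentifiable` (bound pin, or 2-se interval touching a bound,
#'   or no usable covariance), `midpoints`, and the underlying nls object.
#' @export
fit_three_state <- function(data, T_K = 298.15, init = NULL) {
  x <- data$x_M; y <- data$y_norm
  if (length(x) < 10)
    stop("need at least 10 points spanning both transitions")
  RT <- R_KCAL * T_K
  starts <- list()
  if (!is.null(init)) {
    starts[[1]] <- list(dG1 = init$dG1_0, dG2 = init$dG2_0,
                        m1 = init$m1, m2 = init$m2, gamma = init$gamma)
  } else {
    # primary start: two-state pre-fit, dG and m split 40/60, gamma 0.5
    ts <- two_state_init(x, y, RT)
    dG <- min(max(ts[["dG"]], -29), -0.5)
    m <- min(max(ts[["m"]], 0.2), 9)
    starts[[1]] <- list(dG1 = 0.4 * dG, dG2 = 0.6 * dG,
                        m1 = 0.4 * m, m2 = 0.6 * m, gamma = 0.5)
    # fallback starts from crude midpoint reads of the curve, guarding
    # against the local optimum in which one stage collapses (m -> 0,
    # gamma pinned); deterministic, so the fit stays reproducible
    cm1 <- x[which.min(abs(y - 0.75))]
    cm2 <- x[which.min(abs(y - 0.25))]
    cm1 <- max(cm1, 0.1); cm2 <- max(cm2, cm1 + 0.1)
    for (m0 in c(1.5, 3, 6)) {
      for (g0 in c(0.3, 0.5, 0.7)) {
        starts[[length(starts) + 1L]] <-
          list(dG1 = max(-m0 * cm1, -29), dG2 = max(-m0 * cm2, -29),
               m1 = m0, m2 = m0, gamma = g0)
      }
    }
  }
  lower <- c(dG1 = -30, dG2 = -30, m1 = 1e-6, m2 = 1e-6, gamma = 0)
  upper <- c(dG1 = 0, dG2 = 0, m1 = 10, m2 = 10, gamma = 1)
  model <- function(dG1, dG2, m1, m2, gamma, x) {
    A <- -(dG1 + m1 * x) / RT
    B <- -(dG2 + m2 * x) / RT
    mx <- pmax(A, pmax(0, -B))
    (gamma * exp(-mx) + exp(A - mx)) /
      (exp(-mx) + exp(A - mx) + exp(-B - mx))
  }
  args <- list(
    formula = y ~ model(dG1, dG2, m1, m2, gamma, x),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!is.null(data$sigma)) args$weights <- 1 / data$sigma^2
  fit <- NULL; best_ss <- Inf
  for (st in starts) {
    cand <- try(do.call(minpack.lm::nlsLM, c(args, list(start = st))),
                silent = TRUE)
    if (inherits(cand, "try-error")) next
    ss <- sum(stats::residuals(cand)^2)
    if (ss < best_ss) { best_ss <- ss; fit <- cand }
  }
  if (is.null(fit))
    stop("three-state fit failed from every starting point")
  est <- coef(fit)
  params <- three_state_params(est[["dG1"]], est[["dG2"]],
                               est[["m1"]], est[["m2"]], est[["gamma"]])
  gamma_at_bound <- est[["gamma"]] <= 1e-6 || est[["gamma"]] >= 1 - 1e-6
  if (gamma_at_bound)
    warning("gamma pinned at a bound: intermediate helical content ",
            "not identifiable from these data")
  sm <- try(summary(fit), silent = TRUE)
  se <- NULL; se_dG_fold <- NA_real_
  rank_deficient <- inherits(sm, "try-error")
  if (!rank_deficient) {
    vc <- try(stats::vcov(fit), silent = TRUE)
    if (inherits(vc, "try-error") || any(!is.finite(diag(vc)))) {
      rank_deficient <- TRUE
    } else {
      se <- sqrt(diag(vc))
      se_dG_fold <- sqrt(vc["dG1", "dG1"] + vc["dG2", "dG2"] +
                           2 * vc["dG1", "dG2"])
    }
  }
  # gamma counts as unidentifiable when pinned, when its 2-se interval
  # touches a bound, or when no usable se exists (two-state-like data)
  g <- est[["gamma"]]
  gamma_unidentifiable <- gamma_at_bound || rank_deficient ||
    (!is.null(se) && (se[["gamma"]] > 0.5 ||
                        g - 2 * se[["gamma"]] <= 0 ||
                        g + 2 * se[["gamma"]] >= 1))
  structure(list(
    params = params,
    dG_fold = params$dG1_0 + params$dG2_0,
    se = se, se_dG_fold = se_dG_fold,
    rank_deficient = rank_deficient,
    gamma_at_bound = gamma_at_bound,
    gamma_unidentifiable = gamma_unidentifiable,
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    midpoints = midpoints(params),
    T_K = T_K, n_points = length(x), nls = fit),
    class = "three_state_fit")
}

#' @export
print.three_state_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<three_state_fit> dG1_0 = %.3f, dG2_0 = %.3f kcal/mol; m1 = %.3f, m2 = %.3f kcal/mol/M; gamma = %.3f\n",
              p$dG1_0, p$dG2_0, p$m1, p$m2, p$gamma))
  cat(sprintf("  dG_fold = %.3f kcal/mol (se %.3g), Cm = %.2f / %.2f M, n = %d%s\n",
              x$dG_fold, x$se_dG_fold, x$midpoints[1], x$midpoints[2],
              x$n_points,
              if (x$gamma_at_bound) " [gamma at bound]" else ""))
  invisible(x)
}

#' Linear-baseline normalization helper for raw ellipticity melts
#'
#' Fits linear pre- and post-transition baselines over the given denaturant
#' windows and maps the raw signal onto \[0, 1\] as
#' (raw - post) / (pre - post) evaluated pointwise. The published melts are
#' assumed already normalized; this helper covers raw 222 nm traces.
#'
#' @param x denaturant concentrations, M.
#' @param raw raw ellipticity values.
#' @param pre_window,post_window ranges of x treated as pure baseline.
#' @return data.frame with `x_M` and `y_norm`.
#' @export
normalize_baselines <- function(x, raw,
                                pre_window = range(x)[1] + c(0, 0.3),
                                post_window = range(x)[2] - c(0.3, 0)) {
  pre <- x >= pre_window[1] & x <= pre_window[2]
  post <- x >= post_window[1] & x <= post_window[2]
  if (sum(pre) < 2 || sum(post) < 2)
    stop("need at least 2 points in each baseline window")
  fit_pre <- lm(raw[pre] ~ x[pre])
  fit_post <- lm(raw[post] ~ x[post])
  yp <- coef(fit_pre)[1] + coef(fit_pre)[2] * x
  yu <- coef(fit_post)[1] + coef(fit_post)[2] * x
  data.frame(x_M = x, y_norm = (raw - yu) / (yp - yu))
}
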