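# Log-linear precipitant-solubility model (Cohn-type):
#   log10 S = log10 S0 + beta * [precipitant]
# S0 is the extrapolated solubility in water, beta (negative for a
# precipitant) the resistance to the precipitant.

#' Read a solubility table from a delimited file
#'
#' Expects columns `conc_percent` (PEG % w/v) and `solubility_mg_per_ml`,
#' with an optional `sigma` column of per-point standard deviations of
#' log10 S.
#'
#' @param path CSV/TSV file.
#' @param sep field separator (default `,`).
#' @return data.frame suitable for [fit_solubility()].
#' @export
read_solubility_csv <- function(path, sep = ",") {
  d <- read.csv(path, sep = sep)
  need <- c("conc_percent", "solubility_mg_per_ml")
  if (!all(need %in% names(d)))
    stop("missing column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Fit the log-linear solubility model to a PEG sedimentation series
#'
#' Ordinary least squares of log10 S on precipitant concentration
#' (weighted when per-point sigmas are supplied). Points below the
#' detection floor are dropped with a warning rather than clamped.
#'
#' @param data data.frame with `conc_percent` and `solubility_mg_per_ml`
#'   (optionally `sigma`, sd of log10 S, enabling weighted LS).
#' @param detection_floor smallest trustworthy solubility, mg/mL.
#' @return object of class `solubility_fit`: `logS0`, `beta`, standard
#'   errors, `r_squared`, `n_points`, and the underlying `lm` fit.
#' @export
fit_solubility <- function(data, detection_floor = 0.01) {
  conc <- data$conc_percent
  S <- data$solubility_mg_per_ml
  if (any(!is.finite(conc)) || any(!is.finite(S)))
    stop("non-finite values in solubility data")
  if (any(S <= 0))
    stop("non-positive solubility values")
  low <- S < detection_floor
  if (any(low)) {
    warning(sum(low), " point(s) below detection floor ", detection_floor,
            " mg/mL dropped")
    conc <- conc[!low]; S <- S[!low]
    if (!is.null(data$sigma)) data <- data[!low, , drop = FALSE]
  }
  if (length(S) < 3)
    stop("need at least 3 points to fit")
  if (length(unique(conc)) < 2)
    stop("all precipitant concentrations identical")
  y <- log10(S)
  if (!is.null(data$sigma)) {
    w <- 1 / data$sigma^2
    fit <- lm(y ~ conc, weights = w)
  } else {
    fit <- lm(y ~ conc)
  }
  cf <- summary(fit)$coefficients
  structure(list(
    logS0 = unname(cf[1, 1]), beta = unname(cf[2, 1]),
    se_logS0 = unname(cf[1, 2]), se_beta = unname(cf[2, 2]),
    r_squared = summary(fit)$r.squared,
    n_points = length(S),
    residuals = unname(stats::residuals(fit)),
    lm = fit, log_base = 10),
    class = "solubility_fit")
}

#' @export
print.solubility_fit <- function(x, ...) {
  cat(sprintf(paste0("<solubility_fit> log10 S0 = %.4f (se %.4f) mg/mL, ",
                     "beta = %.5f (se %.5f) per %%w/v, R^2 = %.4f, n = %d\n"),
              x$logS0, x$se_logS0, x$beta, x$se_beta, x$r_squared,
              x$n_points))
  invisible(x)
}

#' Predict solubility at a precipitant concentration
#'
#' @param fit a `solubility_fit` (or any list with `logS0` and `beta`).
#' @param conc precipitant concentration(s), % w/v.
#' @return predicted solubility in mg/mL; `conc = 0` gives `10^logS0`.
#' @export
predict_solubility <- function(fit, conc) {
  10^(fit$logS0 + fit$beta * conc)
}
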