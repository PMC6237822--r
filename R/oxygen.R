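# Hill-plot analysis of oxygen equilibrium curves:
#   log10(Y/(1-Y)) = n * log10(pO2) - n * log10(P50)
# For monomeric myoglobin the Hill slope n is expected near 1; P50 is the
# partial pressure at half saturation.

#' Hill transform of an oxygen equilibrium curve
#'
#' Maps (pO2, Y) to (log10 pO2, log10(Y/(1-Y))), excluding saturations
#' outside \[y_min, y_max\] where the log ratio blows up.
#'
#' @param data data.frame with columns `pO2_mmHg` and `saturation`.
#' @param y_min,y_max retained saturation range (defaults 0.05 and 0.95).
#' @return data.frame with `log_p`, `log_ratio`; attribute `n_excluded`.
#' @export
hill_transform <- function(data, y_min = 0.05, y_max = 0.95) {
  p <- data$pO2_mmHg; Y <- data$saturation
  if (any(p <= 0)) stop("pO2 must be positive")
  keep <- Y >= y_min & Y <= y_max
  if (sum(keep) < 4)
    stop("fewer than 4 points survive the saturation filter")
  out <- data.frame(log_p = log10(p[keep]),
                    log_ratio = log10(Y[keep] / (1 - Y[keep])))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Hill-plot fit: P50 and Hill slope
#'
#' Least-squares line through the Hill plot. The slope is the Hill
#' coefficient; P50 is recovered from the x-intercept,
#' P50 = 10^(-intercept/slope). An n = 1 constrained estimate
#' (`P50_n1`, the mean of p (1-Y)/Y over retained points in log space) is
#' also reported.
#'
#' @param data data.frame with `pO2_mmHg` and `saturation`.
#' @param y_min,y_max passed to [hill_transform()].
#' @return object of class `hill_fit`: `P50` (mmHg), `n_hill`, standard
#'   errors, `P50_n1`, `points_used`.
#' @export
fit_p50 <- function(data, y_min = 0.05, y_max = 0.95) {
  h <- hill_transform(data, y_min, y_max)
  fit <- lm(log_ratio ~ log_p, data = h)
  cf <- summary(fit)$coefficients
  a <- unname(cf[1, 1]); b <- unname(cf[2, 1])
  if (b <= 0) stop("non-positive Hill slope: corrupted data")
  P50 <- 10^(-a / b)
  # se by first-order propagation of log10 P50 = -a/b
  va <- cf[1, 2]^2; vb <- cf[2, 2]^2
  cab <- stats::vcov(fit)[1, 2]
  v_log <- va / b^2 + (a^2 / b^4) * vb - 2 * (a / b^3) * cab
  se_P50 <- P50 * log(10) * sqrt(max(v_log, 0))
  structure(list(
    P50 = P50, n_hill = b,
    se_P50 = se_P50, se_n_hill = unname(cf[2, 2]),
    P50_n1 = 10^mean(h$log_p - h$log_ratio),
    points_used = nrow(h), n_excluded = attr(h, "n_excluded"),
    lm = fit),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> P50 = %.4f (se %.2g) mmHg, n = %.3f (se %.2g), %d points used (%d filtered)\n",
              x$P50, x$se_P50, x$n_hill, x$se_n_hill,
              x$points_used, x$n_excluded))
  invisible(x)
}
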