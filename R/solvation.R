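# Fluctuation-corrected ensemble average of per-conformation solvation
# free energies:
#   dG_solv = <dG_i> - kB T ln < exp[-(dG_i - <dG_i>)/kB T] >
# The exponential average is evaluated with a log-sum-exp scheme so that
# spreads much larger than kB T do not overflow. kB T is expressed as R*T
# in kcal/mol: the per-molecule vs per-mole distinction is absorbed into
# the units, since the samples themselves are molar quantities.

#' Fluctuation-corrected ensemble solvation free energy
#'
#' Returns the corrected average together with the simple mean and the
#' (always non-positive) fluctuation term separately. By Jensen's
#' inequality the corrected value never exceeds the simple mean, with
#' equality only when all samples are equal.
#'
#' @param values per-conformation solvation free energies, kcal/mol.
#' @param T_K temperature, K (default 298).
#' @return object of class `sfe_result`: `dG_solv`, `mean`,
#'   `fluctuation` (= dG_solv - mean), `n`, `T_K`.
#' @export
ensemble_sfe <- function(values, T_K = 298) {
  if (length(values) == 0) stop("empty sample set")
  if (any(!is.finite(values))) stop("non-finite solvation free energies")
  RT <- R_KCAL * T_K
  m <- mean(values)
  z <- -(values - m) / RT
  zmax <- max(z)
  # log mean exp, overflow-safe
  lme <- zmax + log(mean(exp(z - zmax)))
  fluct <- -RT * lme
  structure(list(dG_solv = m + fluct, mean = m, fluctuation = fluct,
                 n = length(values), T_K = T_K),
            class = "sfe_result")
}

#' @export
print.sfe_result <- function(x, ...) {
  cat(sprintf("<sfe_result> dG_solv = %.4f kcal/mol (mean %.4f, fluctuation %.4f), n = %d, T = %g K\n",
              x$dG_solv, x$mean, x$fluctuation, x$n, x$T_K))
  invisible(x)
}

#' Read a one-column file of per-conformation solvation free energies
#'
#' @param path text file with one numeric value per line (a header line of
#'   non-numeric text is skipped; `#` comments allowed).
#' @return numeric vector, kcal/mol.
#' @export
read_sfe_samples <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  vals <- suppressWarnings(as.numeric(lines))
  if (length(vals) && is.na(vals[1]) && !any(is.na(vals[-1])))
    vals <- vals[-1]                     # header line
  if (any(is.na(vals))) stop("non-numeric entries in SFE sample file")
  vals
}
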