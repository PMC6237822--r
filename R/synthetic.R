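# Synthetic-data generators: every generator is the exact inverse of its
# fitter at zero noise, carries its ground truth, and is bitwise
# reproducible for a fixed seed. One global seed fans out to per-modality
# child seeds through a deterministic string hash, so adding a modality
# never perturbs the outputs of another.

# deterministic 31-bit child seed from a parent seed and a label
child_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- as.double(seed %% 2147483647L)
  for (c in codes) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic PEG-solubility dataset
#'
#' S = 10^(logS0 + beta * conc + eps), eps ~ N(0, sigma) in log10 space.
#'
#' @param logS0 true intercept, log10 mg/mL.
#' @param beta true slope, per % w/v (negative for precipitants).
#' @param conc_grid precipitant concentrations, % w/v.
#' @param sigma sd of Gaussian noise on log10 S.
#' @param seed integer seed.
#' @return data.frame (`conc_percent`, `solubility_mg_per_ml`) with the
#'   truth attached as attribute `truth`.
#' @export
gen_solubility <- function(logS0, beta, conc_grid = seq(10, 40, by = 5),
                           sigma = 0.05, seed = 1) {
  stopifnot(length(conc_grid) > 0, sigma >= 0)
  eps <- with_seed(child_seed(seed, "solubility"),
                   rnorm(length(conc_grid), 0, sigma))
  out <- data.frame(conc_percent = conc_grid,
                    solubility_mg_per_ml = 10^(logS0 + beta * conc_grid + eps))
  attr(out, "truth") <- list(logS0 = logS0, beta = beta, sigma = sigma)
  out
}

#' Generate a synthetic SAXS concentration series (sample + buffer pairs)
#'
#' Profiles follow a Gaussian (Guinier-exact) form factor
#' I_abs(q) = I(0) exp(-q^2 Rg^2 / 3) with I(0) from the virial relation
#' I(0) = k M cp / (1 + 2 A2 M cp). The absolute profile is pushed back
#' through the arbitrary-scale relation (sample = f * I_abs +
#' (1 - cp v) * buffer) so the reduction pipeline sees realistic raw
#' inputs. Noise is multiplicative with fractional sd `sigma_frac`.
#'
#' @param M molecular weight, g/mol.
#' @param A2 second virial coefficient, cm^3 mol/g^2 (sign free).
#' @param Rg radius of gyration, Angstrom.
#' @param cp_list protein concentrations, g/cm^3 (each cp*v < 1).
#' @param consts a [saxs_constants()] list.
#' @param q q grid, 1/Angstrom.
#' @param buffer_level flat buffer intensity, arbitrary units.
#' @param sigma_frac fractional noise level.
#' @param seed integer seed.
#' @return list with `pairs` (list of `list(sample=, buffer=)` profiles)
#'   and `truth`.
#' @export
gen_saxs_series <- function(M = 17200, A2 = 1e-4, Rg = 15,
                            cp_list = c(5, 10, 20, 40) / 1000,
                            consts = saxs_constants(f = 2),
                            q = seq(0.01, 0.55, by = 0.002),
                            buffer_level = 0.02,
                            sigma_frac = 0.01, seed = 1) {
  stopifnot(all(cp_list * consts$v < 1), sigma_frac >= 0)
  pairs <- lapply(seq_along(cp_list), function(i) {
    cp <- cp_list[i]
    I0 <- consts$k * M * cp / (1 + 2 * A2 * M * cp)
    I_abs <- I0 * exp(-q^2 * Rg^2 / 3)
    buffer_true <- rep(buffer_level, length(q))
    sample_true <- consts$f * I_abs + (1 - cp * consts$v) * buffer_true
    sd_s <- pmax(sigma_frac * sample_true, 1e-12)
    sd_b <- pmax(sigma_frac * buffer_true, 1e-12)
    noise <- with_seed(child_seed(seed, paste0("saxs", i)),
                       rnorm(2 * length(q)))
    sample_I <- sample_true * (1 + sigma_frac * noise[seq_along(q)])
    buffer_I <- buffer_true * (1 + sigma_frac * noise[-seq_along(q)])
    list(sample = saxs_profile(q, sample_I, sd_s, cp = cp),
         buffer = saxs_profile(q, buffer_I, sd_b, cp = 0, is_buffer = TRUE))
  })
  list(pairs = pairs,
       truth = list(M = M, A2 = A2, Rg = Rg, cp = cp_list,
                    sigma_frac = sigma_frac, consts = consts))
}

#' Generate a synthetic chemical-denaturation melt
#'
#' y_obs = helical_signal(x) + N(0, sigma). Warns when the grid does not
#' span both transition midpoints.
#'
#' @param params a [three_state_params()] ground truth.
#' @param x_grid denaturant concentrations, M.
#' @param sigma sd of Gaussian noise on the normalized signal.
#' @param T_K temperature, K.
#' @param seed integer seed.
#' @return data.frame (`x_M`, `y_norm`) with attribute `truth`.
#' @export
gen_denaturation <- function(params, x_grid = seq(0, 4, length.out = 30),
                             sigma = 0.01, T_K = 298.15, seed = 1) {
  stopifnot(sigma >= 0)
  cm <- midpoints(params)
  if (min(x_grid) > min(cm) || max(x_grid) < max(cm))
    warning("x grid does not span both transition midpoints (",
            paste(round(cm, 2), collapse = ", "), " M)")
  y <- helical_signal(x_grid, params, T_K)
  eps <- with_seed(child_seed(seed, "denaturation"),
                   rnorm(length(x_grid), 0, sigma))
  out <- data.frame(x_M = x_grid, y_norm = y + eps)
  attr(out, "truth") <- list(params = params, sigma = sigma, T_K = T_K)
  out
}

#' Generate a synthetic oxygen equilibrium curve
#'
#' Y = p^n / (p^n + P50^n) + N(0, sigma), clipped to the open unit
#' interval.
#'
#' @param P50 half-saturation pressure, mmHg.
#' @param n_hill Hill coefficient (1 for a noncooperative monomer).
#' @param p_grid oxygen partial pressures, mmHg.
#' @param sigma sd of Gaussian saturation noise.
#' @param seed integer seed.
#' @return data.frame (`pO2_mmHg`, `saturation`) with attribute `truth`.
#' @export
gen_oec <- function(P50, n_hill = 1,
                    p_grid = 10^seq(log10(0.05), log10(5), length.out = 12),
                    sigma = 0.01, seed = 1) {
  stopifnot(P50 > 0, sigma >= 0)
  Y <- p_grid^n_hill / (p_grid^n_hill + P50^n_hill)
  eps <- with_seed(child_seed(seed, "oec"),
                   rnorm(length(p_grid), 0, sigma))
  Yn <- pmin(pmax(Y + eps, 1e-9), 1 - 1e-9)
  out <- data.frame(pO2_mmHg = p_grid, saturation = Yn)
  attr(out, "truth") <- list(P50 = P50, n_hill = n_hill, sigma = sigma)
  out
}

#' Generate per-conformation solvation free energy samples
#'
#' Gaussian samples around a per-taxon mean, emulating the conformational
#' spread of a molecular-dynamics ensemble.
#'
#' @param mean_sfe ensemble mean, kcal/mol.
#' @param sigma conformational spread, kcal/mol.
#' @param n number of conformations (default 5000).
#' @param seed integer seed.
#' @return numeric vector with attribute `truth`.
#' @export
gen_sfe_samples <- function(mean_sfe, sigma = 2, n = 5000, seed = 1) {
  vals <- with_seed(child_seed(seed, "sfe"), rnorm(n, mean_sfe, sigma))
  attr(vals, "truth") <- list(mean = mean_sfe, sigma = sigma, n = n)
  vals
}

#' Ground-truth parameter table for the four-taxon lineage suite
#'
#' Encodes the study conditions: precipitant tolerance (beta), net charge
#' and solvation free energy change early (terrestrial ancestor to whale
#' ancestor) and then plateau, while molecular repulsion (A2), fold
#' stability (more negative dG_fold) and the supplied mutational-energy
#' column change mainly late (whale ancestor to sperm whale). P50 values
#' are the measured ones for the four proteins. Taxa are ordered by
#' decreasing evolutionary distance from the extant tip.
#'
#' @return data.frame, one row per taxon, with every generator truth.
#' @export
lineage_truth_table <- function() {
  data.frame(
    taxon = c("aMbWp", "aMbWb'", "aMbWb", "swMb"),
    logS0 = c(2.35, 2.10, 2.05, 2.05),
    beta = c(-0.115, -0.085, -0.080, -0.080),
    dG_solv = c(-5600, -5520, -5505, -5500),
    A2 = c(0.3e-4, 0.6e-4, 0.8e-4, 1.4e-4),
    ddG_mut = c(0, -0.9, -1.3, -4.2),
    dG1_0 = c(-2.2, -2.3, -2.5, -4.6),
    dG2_0 = c(-3.8, -3.9, -3.9, -4.4),
    m1 = c(2.2, 2.2, 2.2, 2.2),
    m2 = c(1.6, 1.6, 1.6, 1.6),
    gamma = c(0.55, 0.55, 0.55, 0.55),
    P50 = c(0.42, 0.46, 0.46, 0.52),
    stringsAsFactors = FALSE)
}

#' Generate the full synthetic lineage suite
#'
#' One dataset per modality per taxon, each with known ground truth taken
#' from [lineage_truth_table()] (molecular masses and Rg scaled off the
#' reconstructed sequences). The bundle carries its truth table for
#' recovery scoring.
#'
#' @param seed integer master seed; per-taxon, per-modality child seeds
#'   are derived deterministically.
#' @param sigma_log_solubility,sigma_saxs_frac,sigma_cd,sigma_saturation,sigma_sfe
#'   noise levels per modality.
#' @param n_sfe conformations per taxon for the solvation samples.
#' @param lineage an [mb_lineage()]; built from the packaged data when
#'   omitted.
#' @return list of class `lineage_suite`: `taxa`, `truth`, `lineage`, and
#'   per-modality named lists `solubility`, `saxs`, `denaturation`, `oec`,
#'   `sfe`.
#' @export
gen_lineage_suite <- function(seed = 1,
                              sigma_log_solubility = 0.05,
                              sigma_saxs_frac = 0.01,
                              sigma_cd = 0.01,
                              sigma_saturation = 0.01,
                              sigma_sfe = 2,
                              n_sfe = 5000,
                              lineage = mb_lineage()) {
  truth <- lineage_truth_table()
  taxa <- truth$taxon
  seqs <- lineage$sequences
  if (!all(taxa %in% names(seqs)))
    stop("lineage is missing taxa: ",
         paste(setdiff(taxa, names(seqs)), collapse = ", "))
  truth$M <- vapply(taxa, function(t) molecular_mass(seqs[[t]]), 1)
  truth$Rg <- 15  # folded myoglobin-like monomer
  suite <- list(taxa = taxa, truth = truth, lineage = lineage,
                solubility = list(), saxs = list(),
                denaturation = list(), oec = list(), sfe = list())
  for (i in seq_along(taxa)) {
    t <- taxa[i]
    s_t <- child_seed(seed, t)
    suite$solubility[[t]] <- gen_solubility(
      truth$logS0[i], truth$beta[i],
      sigma = sigma_log_solubility, seed = s_t)
    suite$saxs[[t]] <- gen_saxs_series(
      M = truth$M[i], A2 = truth$A2[i], Rg = truth$Rg[i],
      sigma_frac = sigma_saxs_frac, seed = s_t)
    suite$denaturation[[t]] <- gen_denaturation(
      three_state_params(truth$dG1_0[i], truth$dG2_0[i],
                         truth$m1[i], truth$m2[i], truth$gamma[i]),
      sigma = sigma_cd, seed = s_t)
    suite$oec[[t]] <- gen_oec(truth$P50[i],
                              sigma = sigma_saturation, seed = s_t)
    suite$sfe[[t]] <- gen_sfe_samples(truth$dG_solv[i], sigma = sigma_sfe,
                                      n = n_sfe, seed = s_t)
  }
  class(suite) <- "lineage_suite"
  suite
}

#' @export
print.lineage_suite <- function(x, ...) {
  cat("<lineage_suite>", length(x$taxa), "taxa:",
      paste(x$taxa, collapse = ", "), "\n")
  cat("  modalities: solubility, saxs, denaturation, oec, sfe\n")
  invisible(x)
}
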