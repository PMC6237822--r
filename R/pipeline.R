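# End-to-end orchestration: lineage -> per-modality fits -> property
# table -> correlation. Per-stage failures are collected and reported;
# downstream consumers see NA columns, never a crash. No value is computed
# in this layer itself: every number traces to a module function.

#' Run the full analysis pipeline on a lineage suite
#'
#' Takes a data bundle shaped like [gen_lineage_suite()] output (any
#' modality may be absent for a partial run), fits every present modality
#' per taxon, assembles the taxon x property table with sequence-derived
#' columns (Mr, Z, pI, d), and computes the correlation structure.
#'
#' @param suite a `lineage_suite` (or compatible list). Modalities set to
#'   `NULL` are skipped and their columns left `NA`.
#' @param cutoff correlation threshold for property grouping.
#' @param pka_set pKa table name for the isoelectric points.
#' @param T_K temperature for denaturation fits, K.
#' @param ddG_mut optional externally supplied mutational folding energy
#'   column, one value per taxon (taken from `suite$truth$ddG_mut` when
#'   present).
#' @return object of class `pipeline_report`: `table` (a
#'   [property_table()]), `correlation`, `clusters`, `fits` (per modality,
#'   per taxon), `errors` (named list of failed stages), `parameters`.
#' @export
run_pipeline <- function(suite, cutoff = 0.9, pka_set = "emboss",
                         T_K = 298.15, ddG_mut = NULL) {
  taxa <- suite$taxa
  lineage <- suite$lineage
  if (is.null(lineage)) lineage <- mb_lineage()
  seq_props <- sequence_properties(lineage, pka_set = pka_set)
  seq_props <- seq_props[match(taxa, seq_props$taxon), , drop = FALSE]
  errors <- list()
  fits <- list()
  na_col <- function() setNames(rep(NA_real_, length(taxa)), taxa)

  col_logS0 <- na_col(); col_beta <- na_col()
  if (!is.null(suite$solubility)) {
    fits$solubility <- list()
    for (t in intersect(taxa, names(suite$solubility))) {
      f <- try(fit_solubility(suite$solubility[[t]]), silent = TRUE)
      if (inherits(f, "try-error")) {
        errors[[paste0("solubility/", t)]] <- conditionMessage(attr(f, "condition"))
      } else {
        fits$solubility[[t]] <- f
        col_logS0[t] <- f$logS0; col_beta[t] <- f$beta
      }
    }
  }

  col_A2 <- na_col()
  if (!is.null(suite$saxs)) {
    fits$saxs <- list()
    for (t in intersect(taxa, names(suite$saxs))) {
      f <- try({
        consts <- suite$saxs[[t]]$truth$consts
        if (is.null(consts)) consts <- saxs_constants()
        g <- lapply(suite$saxs[[t]]$pairs, function(pr) {
          abs_prof <- absolute_intensity(pr$sample, pr$buffer, consts)
          gu <- guinier_extrapolate(abs_prof)
          c(cp = pr$sample$cp, I0 = gu$I0)
        })
        ser <- as.data.frame(do.call(rbind, g))
        fit_virial(ser, consts)
      }, silent = TRUE)
      if (inherits(f, "try-error")) {
        errors[[paste0("saxs/", t)]] <- conditionMessage(attr(f, "condition"))
      } else {
        fits$saxs[[t]] <- f
        col_A2[t] <- f$A2
      }
    }
  }

  col_dG_fold <- na_col()
  if (!is.null(suite$denaturation)) {
    fits$denaturation <- list()
    for (t in intersect(taxa, names(suite$denaturation))) {
      f <- try(fit_three_state(suite$denaturation[[t]], T_K = T_K),
               silent = TRUE)
      if (inherits(f, "try-error")) {
        errors[[paste0("denaturation/", t)]] <- conditionMessage(attr(f, "condition"))
      } else {
        fits$denaturation[[t]] <- f
        col_dG_fold[t] <- f$dG_fold
      }
    }
  }

  col_P50 <- na_col()
  if (!is.null(suite$oec)) {
    fits$oec <- list()
    for (t in intersect(taxa, names(suite$oec))) {
      f <- try(fit_p50(suite$oec[[t]]), silent = TRUE)
      if (inherits(f, "try-error")) {
        errors[[paste0("oec/", t)]] <- conditionMessage(attr(f, "condition"))
      } else {
        fits$oec[[t]] <- f
        col_P50[t] <- f$P50
      }
    }
  }

  col_dG_solv <- na_col()
  if (!is.null(suite$sfe)) {
    fits$sfe <- list()
    for (t in intersect(taxa, names(suite$sfe))) {
      f <- try(ensemble_sfe(suite$sfe[[t]]), silent = TRUE)
      if (inherits(f, "try-error")) {
        errors[[paste0("sfe/", t)]] <- conditionMessage(attr(f, "condition"))
      } else {
        fits$sfe[[t]] <- f
        col_dG_solv[t] <- f$dG_solv
      }
    }
  }

  if (is.null(ddG_mut) && !is.null(suite$truth$ddG_mut))
    ddG_mut <- setNames(suite$truth$ddG_mut, suite$truth$taxon)[taxa]
  if (is.null(ddG_mut)) ddG_mut <- na_col()

  table <- property_table(
    taxa = taxa, d = seq_props$d,
    properties = list(
      pI = seq_props$pI, Z = seq_props$Z,
      logS0 = unname(col_logS0), beta = unname(col_beta),
      dG_solv = unname(col_dG_solv), Mr = seq_props$Mr,
      A2 = unname(col_A2), ddG_mut = unname(ddG_mut),
      dG_fold = unname(col_dG_fold), P50 = unname(col_P50)),
    units = c(pI = "pH", Z = "e", logS0 = "log10 mg/mL",
              beta = "per %w/v", dG_solv = "kcal/mol", Mr = "Da",
              A2 = "cm^3 mol/g^2", ddG_mut = "kcal/mol",
              dG_fold = "kcal/mol", P50 = "mmHg",
              d = "subst/site"))
  usable <- vapply(table[, setdiff(names(table), "taxon")],
                   function(col) sum(is.finite(col)) >= 3, TRUE)
  corr <- NULL; clusters <- NULL
  if (sum(usable) >= 2) {
    corr <- correlate(table)
    clusters <- threshold_clusters(corr, cutoff = cutoff)
  }
  structure(list(
    table = table, correlation = corr, clusters = clusters,
    fits = fits, errors = errors,
    parameters = list(cutoff = cutoff, pka_set = pka_set, T_K = T_K,
                      R_kcal = R_KCAL),
    package_version = as.character(utils::packageVersion("paleomb"))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$table)
  if (!is.null(x$clusters)) {
    cat("property groups (|r| >=", x$parameters$cutoff, "):\n")
    for (g in x$clusters) cat("  {", paste(g, collapse = ", "), "}\n")
  }
  if (length(x$errors)) {
    cat("failed stages:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n")
  }
  invisible(x)
}

#' Serialize an analysis report to JSON
#'
#' Writes the property table, correlation matrix, clusters, parameters and
#' package version. Deterministic for identical inputs.
#'
#' @param report a `pipeline_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    package_version = report$package_version,
    parameters = report$parameters,
    table = report$table,
    units = as.list(attr(report$table, "units")),
    correlation = if (!is.null(report$correlation))
      report$correlation$matrix else NULL,
    clusters = report$clusters,
    errors = report$errors)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
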