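# Taxon x property matrix and its correlation-with-distance structure.
# With four taxa, correlation coefficients are descriptive only: the
# module reports Pearson r and deliberately never attaches p-values or any
# other significance claim at n = 4.

#' Assemble a property table
#'
#' @param taxa character vector of taxon ids.
#' @param d evolutionary distances, one per taxon.
#' @param properties named list or data.frame of property columns, each of
#'   the same length as `taxa`. Missing values stay `NA`; nothing is
#'   imputed.
#' @param units optional named character vector of per-column units.
#' @return data.frame of class `property_table` with columns `taxon`, `d`,
#'   then the properties; `units` kept as an attribute.
#' @export
property_table <- function(taxa, d, properties, units = NULL) {
  stopifnot(length(taxa) == length(d))
  props <- as.data.frame(properties, stringsAsFactors = FALSE)
  if (nrow(props) != length(taxa))
    stop("property columns must have one value per taxon")
  out <- cbind(data.frame(taxon = taxa, d = d, stringsAsFactors = FALSE),
               props)
  class(out) <- c("property_table", "data.frame")
  attr(out, "units") <- units
  out
}

#' Pearson correlation of all properties with each other and with distance
#'
#' Pairwise Pearson r on complete cases, with the number of complete pairs
#' recorded. Zero-variance columns are flagged and their correlations set
#' to NA rather than propagated as NaN. No significance is reported:
#' four taxa support description, not inference.
#'
#' @param table a [property_table()].
#' @return object of class `correlation_result`: `matrix` (symmetric, unit
#'   diagonal), `n_pairs`, `zero_variance` (column names flagged),
#'   `columns`.
#' @export
correlate <- function(table) {
  cols <- setdiff(names(table), "taxon")
  X <- as.matrix(table[, cols, drop = FALSE])
  k <- ncol(X)
  r <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  n <- matrix(0L, k, k, dimnames = list(cols, cols))
  zero_var <- character(0)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- complete.cases(X[, i], X[, j])
      n[i, j] <- sum(ok)
      if (sum(ok) < 3) next
      vi <- var(X[ok, i]); vj <- var(X[ok, j])
      if (vi == 0 || vj == 0) {
        if (vi == 0) zero_var <- union(zero_var, cols[i])
        if (vj == 0) zero_var <- union(zero_var, cols[j])
        next
      }
      r[i, j] <- cor(X[ok, i], X[ok, j])
    }
  }
  diag(r) <- 1
  structure(list(matrix = r, n_pairs = n, zero_variance = zero_var,
                 columns = cols),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> Pearson r (no significance claimed at this n)\n")
  print(round(x$matrix, 3))
  if (length(x$zero_variance))
    cat("zero-variance column(s):", paste(x$zero_variance, collapse = ", "),
        "\n")
  invisible(x)
}

#' Single-linkage grouping of highly correlated properties
#'
#' Groups property columns (distance itself excluded) whose pairwise |r|
#' meets the cutoff, by single linkage: properties end up in one group if
#' they are connected through any chain of above-cutoff correlations.
#' Both strongly positive and strongly negative correlations count as one
#' structure, hence the absolute value. Output order is deterministic
#' (input column order), and singleton groups are kept.
#'
#' @param result a [correlation_result].
#' @param cutoff absolute correlation threshold, default 0.9.
#' @return list of character vectors (groups, each in column order).
#' @export
threshold_clusters <- function(result, cutoff = 0.9) {
  cols <- setdiff(result$columns, "d")
  r <- result$matrix[cols, cols, drop = FALSE]
  k <- length(cols)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j && isTRUE(abs(r[i, j]) >= cutoff)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, 1L)
  groups <- lapply(unique(roots), function(rt) cols[roots == rt])
  groups[order(vapply(groups, function(g) match(g[1], cols), 1L))]
}
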