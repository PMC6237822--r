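#!/usr/bin/env Rscript
# Fit the log-linear precipitant model to each taxon's PEG sedimentation
# series and compare against the generating truth.
#
# Expected picture: the slope beta (precipitant tolerance) rises sharply
# on the early branch (aMbWp -> aMbWb') and is flat late, while log S0
# drops early - solubility in water did not improve.

suppressPackageStartupMessages(library(paleomb))

indir <- "results/sim"
truth <- read.csv(file.path(indir, "truth.csv"))
safe <- function(t) gsub("'", "p", t)

rows <- lapply(truth$taxon, function(t) {
  d <- read_solubility_csv(file.path(indir,
                                     paste0("solubility_", safe(t), ".csv")))
  f <- fit_solubility(d)
  data.frame(taxon = t, logS0 = f$logS0, se_logS0 = f$se_logS0,
             beta = f$beta, se_beta = f$se_beta, r_squared = f$r_squared,
             n = f$n_points,
             logS0_true = truth$logS0[truth$taxon == t],
             beta_true = truth$beta[truth$taxon == t])
})
tab <- do.call(rbind, rows)
print(tab, digits = 4)
write.csv(tab, "results/fit_solubility.csv", row.names = FALSE)
cat(sprintf("beta span: %.4f (earliest) -> %.4f (extant)\n",
            tab$beta[1], tab$beta[nrow(tab)]))
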