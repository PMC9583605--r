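#!/usr/bin/env Rscript
# Degrader-field generation stage: checks the calibrated log-Gaussian Cox
# process parameters against the scenario targets (topsoil CV of 16, 161 and
# 400 %; practical semivariogram range 27 +/- 2 mm) and writes per-field
# metrics for an ensemble per scenario.

library(mcpafate)

n_fields <- 50
seed <- 1000
dir.create("results", showWarnings = FALSE)

rows <- list()
for (label in c("LOW", "HIGH", "EXTR")) {
  lg <- default_lgcp(label)
  for (k in seq_len(n_fields)) {
    f <- sample_field(lg, width = 0.3, depth = 0.3, seed = seed + k)
    m <- field_metrics(f)
    rows[[length(rows) + 1]] <- data.frame(
      scenario = label, seed = seed + k, sigma2 = lg$sigma2, beta = lg$beta,
      cv = m$cv, cr = m$cr, practical_range_mm = 1e3 * m$practical_range)
  }
  seed <- seed + n_fields
}
met <- do.call(rbind, rows)
write.csv(met, "results/field_metrics.csv", row.names = FALSE)

cat("Ensemble means over", n_fields, "fields per scenario:\n")
agg <- aggregate(cbind(cv, cr, practical_range_mm) ~ scenario, met, mean)
print(agg, digits = 4)
cat("\nTargets: CV 16 / 161 / 400 %, practical range 27 +/- 2 mm.\n")
cat("The homogeneous scenario (HOM) uses the deterministic mean profile",
    "(CV = 0 by construction) and is not sampled.\n")
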