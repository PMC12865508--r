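#!/usr/bin/env Rscript
# Step 3 -- posterior-predictive goodness of fit for the rt-SCR fit:
# total detections, detected individuals, visited traps, with Bayesian
# p-values under the Pr(T_rep >= T_obs) convention.

suppressPackageStartupMessages(library(rtscr))
seed <- as.integer(Sys.getenv("RTSCR_SEED", "1"))
fit_path <- "results/fit_rtscr/fit.rds"
if (!file.exists(fit_path)) stop("run analysis/02_fit.R first")
fit <- readRDS(fit_path)

gof <- posterior_predictive_gof(fit, n_rep = 500, seed = seed)
print(gof)
write_gof(gof, "results/gof.json", per_draw = "results/gof_replicates.csv")

grDevices::png("results/gof_histograms.png", width = 1200, height = 420)
plot(gof)
grDevices::dev.off()
message("wrote results/gof.json and results/gof_histograms.png")
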