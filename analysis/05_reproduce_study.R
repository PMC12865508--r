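#!/usr/bin/env Rscript
# Step 5 (optional, requires the deposited survey data) -- run the full
# two-stage rt-SCR workflow on a real camera-trap survey.
#
# Expects a directory (default data/study/) containing
#   deployments.csv : station, x, y, setup_date, retrieval_date
#                     (projected meters; ISO dates), one row per station
#   records.csv     : station, datetime, individual
#                     (empty individual = unidentified detection)
# for a survey whose window is given below.  The deposited jaguar survey
# (Zenodo record 10.5281/zenodo.16943255) can be reshaped into this layout;
# none of it ships with the package, so this script is not part of the test
# suite.  At the full published MCMC size (3 chains x 500,000, burn-in
# 100,000, thin 10) expect hours of runtime; the defaults below are scaled
# down (3 x 50,000) and can be raised via environment variables.

suppressPackageStartupMessages(library(rtscr))
data_dir <- Sys.getenv("RTSCR_STUDY_DIR", "data/study")
window <- as.Date(c(Sys.getenv("RTSCR_WINDOW_START", "2023-02-15"),
                    Sys.getenv("RTSCR_WINDOW_END", "2023-05-16")))
n_iter <- as.integer(Sys.getenv("RTSCR_ITER", "50000"))
n_burn <- as.integer(Sys.getenv("RTSCR_BURNIN", "10000"))
seed <- as.integer(Sys.getenv("RTSCR_SEED", "1"))

if (!file.exists(file.path(data_dir, "records.csv")))
  stop("place deployments.csv and records.csv under ", data_dir,
       " (see header comment)")

traps <- read_traps(file.path(data_dir, "deployments.csv"), window)
message("effort: ", effort(traps), " trap-days at ", n_traps(traps),
        " stations")
records <- read_record_table(file.path(data_dir, "records.csv"))
cap <- build_capture_data(records, traps, dedup_window = 30)
print(cap)

mm <- mean_max_distance(cap, traps)
message("MMDM = ", round(mm$mmdm), " m")
cl <- closure_test(cap, traps)
message(sprintf("closure test: Z = %.2f, p = %.3f", cl$statistic,
                cl$p_value))

cfg <- mcmc_config(n_chains = 3, n_iter = n_iter, n_burnin = n_burn,
                   thin = 10, seed = seed)
message("two-stage fit: provisional 15-km buffer, then 3 x sigma-hat...")
two <- fit_with_3sigma_buffer(traps, cap, provisional_buffer = 15000,
                              config = cfg)
message("final buffer: ", round(two$buffer), " m; state space ",
        round(two$fit$area_km2), " km2")
scr <- fit_scr(scr_dataset(traps, cap,
                           build_state_space(traps, two$buffer)),
               config = cfg)

s_rt <- summarize_fit(two$fit); print(s_rt)
s_s <- summarize_fit(scr)
print(compare_fits(s_s, s_rt))
gof <- posterior_predictive_gof(two$fit, n_rep = 1000, seed = seed)
print(gof)

dir.create("results/study", showWarnings = FALSE, recursive = TRUE)
write_fit(two$fit, "results/study/fit_rtscr")
write_summary(s_rt, "results/study/summary_rtscr.json")
write_gof(gof, "results/study/gof.json")
write_ac_surface(activity_center_surface(two$fit, cell_size = 1000),
                 "results/study/ac_surface.csv")
message("wrote results/study/")
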