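#!/usr/bin/env Rscript
# Step 1 -- simulate one survey from the study-emulating design.
#
# Generates a camera-trap dataset under the rt-SCR generative process on the
# 52-station / 91-day layout (3779 trap-days of effort, ~1941 km2 buffered
# state space) with a low-density jaguar population (N = 25, lambda0 = 0.047
# per day, sigma = 3050 m, identification probability theta = 0.87), and
# writes the plain-text survey files that the later steps read back.

suppressPackageStartupMessages(library(rtscr))
seed <- as.integer(Sys.getenv("RTSCR_SEED", "1"))
out_dir <- "results/simulated_survey"

des <- jaguar_design()
message("design: ", n_traps(des$traps), " stations x ",
        n_occasions(des$traps), " occasions, effort ",
        effort(des$traps), " trap-days, state space ",
        round(des$state_space$area_km2), " km2")

truth <- des$truth
truth$seed <- seed
sim <- simulate_dataset(truth, des$traps, des$state_space)
cap <- sim$dataset$captures
message("simulated ", sum(cap$y_id) + sum(cap$n_noid), " detections: ",
        sum(cap$y_id), " identified (", dim(cap$y_id)[1],
        " individuals), ", sum(cap$n_noid), " unidentified")

write_synthetic(sim, out_dir)
message("wrote traps.csv, captures.csv, truth.json under ", out_dir)
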