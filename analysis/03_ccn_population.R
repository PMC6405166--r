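#!/usr/bin/env Rscript
# Coupled canonical network (CCN): 50 feedforward subunits with the whole
# interneuron population coupled all-to-all (electrical, plus optional
# reciprocal inhibition), driven by Gaussian-jittered input times.
#
# For every grid point (sigma_inp x sum G_elec x sum G_GABA->Int) this runs
# 50 trials and tabulates the normalised spike-time-distribution statistics
# of the Int and Tgt populations, the target response rate, and the gains of
# each statistic relative to the electrically uncoupled column.

library(ffinet)
dir.create("results", showWarnings = FALSE)

sw <- sweep_ccn(sigma_grid = c(1, 3, 5, 10),
                g_elec_grid = c(0, 1, 2, 3, 4.5),
                g_gaba_int_grid = c(0, 1, 3, 5),
                n_units = 50, n_trials = 50, seed = 20260925)
sw <- add_gains(sw)
write.csv(sw, "results/ccn_population_stats.csv", row.names = FALSE)

noinh <- sw[sw$sum_g_gaba_int == 0, ]
s1 <- noinh[noinh$sigma_inp == 1, ]
cat("CCN sweep complete:", nrow(sw), "conditions x 50 trials\n")
cat(sprintf("sigma_inp = 1 ms, no reciprocal inhibition, sum G_elec 0 -> 4.5 nS:\n"))
cat(sprintf("  spike-time spread (norm SD): %.2f -> %.2f (dispersion grows)\n",
            s1$norm_sd[s1$sum_g_elec == 0], s1$norm_sd[s1$sum_g_elec == 4.5]))
cat(sprintf("  relative latency: %.1f -> %.1f ms (earlier first responses)\n",
            s1$rel_latency[s1$sum_g_elec == 0], s1$rel_latency[s1$sum_g_elec == 4.5]))
cat(sprintf("  peak density ratio: %.2f -> %.2f\n",
            s1$norm_max_density[s1$sum_g_elec == 0],
            s1$norm_max_density[s1$sum_g_elec == 4.5]))
cat("Uncoupled column gains are identically zero:",
    all(sw$gain_efficiency[sw$sum_g_elec == 0] == 0), "\n")
cat("wrote results/ccn_population_stats.csv\n")
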