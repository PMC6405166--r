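#!/usr/bin/env Rscript
# Coupled canonical circuit (CCC): two feedforward arms, one shared target.
#
# Part 1 sweeps the inter-input delay against the inhibitory strength with
# uncoupled interneurons (the baseline for everything that follows).
# Part 2 adds the electrical synapse between the interneurons (0-8 nS,
# coupling coefficients up to ~0.33): for closely timed inputs it delays
# Int_1 (extra leak) and accelerates Int_2 (spikelet), which synchronises
# the summed inhibition and lets the target integrate more.
# Part 3 adds reciprocal GABA between the interneurons (1-7 nS), which
# re-expands the integration window, most visibly for disparate timings.

library(ffinet)
dir.create("results", showWarnings = FALSE)

delta_grid <- seq(0, 20, by = 0.4)   # includes the 2 and 4.4 ms examples

base <- sweep_ccc(delta_t = delta_grid, g_elec = 0, g_gaba_int = 0,
                  g_gaba_tgt = 8)
write.csv(base, "results/ccc_baseline.csv", row.names = FALSE)

elec <- sweep_ccc(delta_t = delta_grid, g_elec = 0:8, g_gaba_int = 0,
                  g_gaba_tgt = 8)
write.csv(elec, "results/ccc_electrical.csv", row.names = FALSE)

recip <- sweep_ccc(delta_t = seq(0, 20, by = 2), g_elec = 0:5,
                   g_gaba_int = c(1, 3, 5, 7), g_gaba_tgt = 8)
write.csv(recip, "results/ccc_reciprocal.csv", row.names = FALSE)

close_in <- elec[elec$delta_t == 2, ]
cat("CCC sweeps complete:", nrow(base) + nrow(elec) + nrow(recip), "simulations\n")
cat(sprintf("Delta_t = 2 ms, G_elec 0 -> 8 nS: peak %.2f -> %.2f mV, AUC %.2f -> %.2f mV*ms, window %.2f -> %.2f ms\n",
            close_in$peak[1], close_in$peak[nrow(close_in)],
            close_in$auc[1], close_in$auc[nrow(close_in)],
            close_in$window[1], close_in$window[nrow(close_in)]))
cat(sprintf("Interneuron latencies rel. Src_1 at delta_t = 2: Int_1 %.2f -> %.2f ms (delayed), Int_2 %.2f -> %.2f ms (accelerated)\n",
            close_in$lat_int1[1], close_in$lat_int1[nrow(close_in)],
            close_in$lat_int2[1], close_in$lat_int2[nrow(close_in)]))
cat("wrote results/ccc_{baseline,electrical,reciprocal}.csv\n")
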