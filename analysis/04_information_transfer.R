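#!/usr/bin/env Rscript
# Src -> Tgt information transfer in the CCN.
#
# Treats the source population as the input channel and the target as the
# output: marginals are 0.01 ms histograms of per-unit first-spike times
# pooled over 50 units x 50 trials; the joint is the unsmoothed 2-d
# histogram of matched (Src_i, Tgt_i) pairs; silent unit-trials are imputed
# at max + 2 SD of the observed population times. Transmission efficiency is
# 100 * I(Src,Tgt) / H(Tgt).
#
# The uncoupled network relays each input spike with a fixed latency, so it
# is a perfect channel (100%). Electrical coupling disperses target spike
# times and inflates the joint entropy, degrading efficiency most for
# tightly packed inputs (small sigma_inp).

library(ffinet)
dir.create("results", showWarnings = FALSE)

sw <- sweep_ccn(sigma_grid = c(1, 3, 5, 10),
                g_elec_grid = c(0, 1, 2, 3, 4.5),
                g_gaba_int_grid = c(0, 1, 3, 5),
                n_units = 50, n_trials = 50, seed = 4)
info_cols <- c("sigma_inp", "sum_g_elec", "sum_g_gaba_int",
               "H_src", "H_tgt", "H_joint", "mi", "efficiency",
               "response_rate")
write.csv(sw[, info_cols], "results/ccn_information.csv", row.names = FALSE)

noinh <- sw[sw$sum_g_gaba_int == 0, ]
drop <- max_efficiency_drop(noinh)
cat(sprintf("Uncoupled efficiency (all sigma): %s %%\n",
            paste(round(noinh$efficiency[noinh$sum_g_elec == 0], 2), collapse = ", ")))
cat(sprintf("Largest efficiency drop without reciprocal inhibition: %.1f points at sigma_inp = %g ms, sum G_elec = %g nS\n",
            drop$drop, drop$at$sigma_inp, drop$at$sum_g_elec))

# with reciprocal inhibition the peak efficiency moves off the uncoupled column
for (g in c(1, 3, 5)) {
  sub <- sw[sw$sum_g_gaba_int == g, ]
  best <- sub[which.max(sub$mi), ]
  cat(sprintf("  sum G_GABA->Int = %g nS: max MI %.2f bits at sum G_elec = %g nS (sigma %g ms)\n",
              g, best$mi, best$sum_g_elec, best$sigma_inp))
}
cat("wrote results/ccn_information.csv\n")
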