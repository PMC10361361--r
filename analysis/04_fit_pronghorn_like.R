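#!/usr/bin/env Rscript
# Stage 4: fit the seasonal two-state HMM to the pronghorn-like study.
# Same model and sampler as stage 3; only the data differ.

suppressPackageStartupMessages(library(seasonhmm))

series <- read_daily_series("results/pronghorn_like_daily_series.csv")
post <- sample_posterior(
  series,
  config = sampler_config(n_chains = 3, n_iter = 4000, n_burn = 2000,
                          thin = 5, seed = 20260703L))

rh <- gelman_rubin_all(post)
message(sprintf("max Gelman-Rubin: %.3f (%s)", max(rh), names(which.max(rh))))

summ <- summarize_posterior(post)
utils::write.csv(summ, "results/pronghorn_like_posterior_summary.csv",
                 row.names = FALSE)
write_draws(post, "results/pronghorn_like_draws.csv")

key <- c("mu1_step", "mu2_step", "sd_step1", "sd_step2",
         "rho_turn1", "rho_turn2")
print(summ[summ$parameter %in% key, ], row.names = FALSE, digits = 3)
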