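#!/usr/bin/env Rscript
# Stage 5: post hoc seasonal summaries and figures.
#
# From the posterior draws of stages 3-4: daily transition-probability
# curves gamma_12(t), gamma_21(t), the marginal probability of being in the
# long-distance movement state on each day (Chapman-Kolmogorov propagation
# from the day-1 state distribution), and derivative-based seasonal event
# days (fall start/end, spring start/end) with 90% HPDIs.

suppressPackageStartupMessages({
  library(seasonhmm)
  library(ggplot2)
})

read_post <- function(name) {
  tab <- utils::read.csv(sprintf("results/%s_draws.csv", name),
                         check.names = FALSE)
  start_days <- as.integer(sub("^phi1_d", "",
                               grep("^phi1_d", names(tab), value = TRUE)))
  structure(list(draws = as.matrix(tab[, -1L]), chain = tab$chain,
                 basis = build_basis(make_knots(5, 1, 365)),
                 start_days = sort(start_days)),
            class = "posterior_samples")
}

for (name in c("deer_like", "pronghorn_like")) {
  post <- read_post(name)
  cv <- seasonal_curves(post)
  utils::write.csv(cv, sprintf("results/%s_seasonal_curves.csv", name),
                   row.names = FALSE)
  ev <- event_timing(post)
  utils::write.csv(ev, sprintf("results/%s_event_timing.csv", name),
                   row.names = FALSE)
  message(name, " event days (median [90% HPDI]):")
  for (i in seq_len(nrow(ev)))
    message(sprintf("  %-12s %5.1f [%d, %d]  (undefined in %.0f%% of draws)",
                    ev$event[i], ev$median[i], ev$lo[i], ev$hi[i],
                    100 * ev$frac_undefined[i]))

  long <- rbind(
    data.frame(day = cv$day, what = "P(switch SDLM -> LDM)",
               med = cv$g12_median, lo = cv$g12_lo, hi = cv$g12_hi),
    data.frame(day = cv$day, what = "P(switch LDM -> SDLM)",
               med = cv$g21_median, lo = cv$g21_lo, hi = cv$g21_hi),
    data.frame(day = cv$day, what = "marginal P(LDM)",
               med = cv$pldm_median, lo = cv$pldm_lo, hi = cv$pldm_hi))
  p <- ggplot(long, aes(day, med)) +
    geom_ribbon(aes(ymin = lo, ymax = hi), fill = "steelblue", alpha = .3) +
    geom_line(color = "steelblue") +
    geom_vline(xintercept = ev$median[!is.na(ev$median)], linetype = 2,
               linewidth = .3) +
    facet_wrap(~what, ncol = 1, scales = "free_y") +
    labs(x = "day of biological year (July 1 = 1)", y = "probability",
         title = sprintf("Seasonal movement-state dynamics (%s)", name)) +
    theme_minimal()
  ggsave(sprintf("results/%s_seasonal_curves.png", name), p,
         width = 7, height = 8, dpi = 150)
}
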