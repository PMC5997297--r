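#!/usr/bin/env Rscript
# Model chemoattractant gradient formation along the 850 um microchannel
# (D = 0.5e-4 cm2/s, constant-concentration source, concentration-proportional
# sink outflux, no-flux walls) and quantify gradient steepness stability
# between 6 and 24 h. Writes per-snapshot profiles and a stability summary.

library(fuccitrack)

dir.create("results", showWarnings = FALSE)
cfg <- diffusion_config(total_time_h = 30)
times <- c(6, 12, 18, 24, 30)
field <- solve_diffusion(cfg, snapshot_times_h = times)

profiles <- do.call(rbind, lapply(times, function(t) {
  p <- fuccitrack:::width_averaged_profile(field, t)
  data.frame(time_h = t, x_um = field$x_um, mean_concentration = p,
             relative_fluorescence = relative_fluorescence(p))
}))
write.csv(profiles, "results/gradient_profiles.csv", row.names = FALSE)

steep <- vapply(times, function(t) gradient_steepness(field, t), 0)
stab <- 100 * stability_report(field, 6, 24)
summary <- data.frame(time_h = times, steepness_per_um = steep)
write.csv(summary, "results/gradient_steepness.csv", row.names = FALSE)

message(sprintf("steepness at 6 h: %.3e per um; at 24 h: %.3e per um",
                steep[1], steep[4]))
message(sprintf("relative change 6 -> 24 h: %.4g%% (stable gradient window)",
                stab))
g <- microchip_geometry()
message(sprintf("channel volume %.1e mm3 vs reservoir %g mm3 (10^%.1f-fold)",
                g$channel_volume_mm3, g$reservoir_volume_mm3,
                g$orders_of_magnitude))
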