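#!/usr/bin/env Rscript
# Compare migration of G1- vs S/G2-classified cells from the phase-labeled
# tracks written by 03_segment_track_classify.R: per-phase instantaneous
# velocity and persistence, the per-cell G1:S/G2 ratios, and two-tailed
# Student t-tests with significance stars.

library(fuccitrack)

rows <- list()
for (nm in c("free2d", "channel")) {
  mpath <- file.path("results/pipeline", nm, "metrics.csv")
  if (!file.exists(mpath)) stop("run analysis/03_segment_track_classify.R first")
  metrics <- read.csv(mpath)
  vg1 <- metrics$mean_instantaneous_velocity[metrics$phase_segment == "G1"]
  vsg2 <- metrics$mean_instantaneous_velocity[metrics$phase_segment == "SG2"]
  cmp <- compare_groups(vg1, vsg2)
  vp <- velocity_by_phase(metrics)
  message(sprintf(
    "%s: G1 %.3f +/- %.3f um/min (n=%d) vs S/G2 %.3f +/- %.3f (n=%d): t=%.2f, p=%.3g %s; excess %.1f%%",
    nm, cmp$mean_a, cmp$sem_a, cmp$n_a, cmp$mean_b, cmp$sem_b, cmp$n_b,
    cmp$t, cmp$p, cmp$stars, vp$percent_excess_G1))
  rows[[nm]] <- data.frame(scene = nm, group = c("G1", "SG2"),
                           n = c(cmp$n_a, cmp$n_b),
                           mean_velocity = c(cmp$mean_a, cmp$mean_b),
                           sem = c(cmp$sem_a, cmp$sem_b),
                           t = cmp$t, p = cmp$p, stars = cmp$stars,
                           percent_excess_G1 = vp$percent_excess_G1)

  rpath <- file.path("results/pipeline", nm, "ratios.csv")
  if (file.exists(rpath)) {
    ratios <- read.csv(rpath)
    message(sprintf("  per-cell ratios (n=%d): median velocity %.3f, median persistence %.3f",
                    nrow(ratios), median(ratios$velocity_ratio_G1_over_SG2),
                    median(ratios$persistence_ratio_G1_over_SG2)))
  }
}
write.csv(do.call(rbind, rows), "results/group_comparisons.csv",
          row.names = FALSE)
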