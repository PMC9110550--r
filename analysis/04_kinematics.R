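#!/usr/bin/env Rscript
# Migration kinematics from the generator's three-point trajectories:
# speed (stop phases included), persistence, cell length, nuclear
# position, across a narrow-track and a wide-track condition.

suppressMessages(library(trackmech))
dir.create("results", showWarnings = FALSE)

conditions <- list(
  narrow = scene(track_width0 = 3, deformation_sign = "push",
                 wall_force_peak = 5, cell_speed = 0.5, cell_length = 30,
                 nucleus_axes = c(14, 5), seed = 2),
  wide = scene(cell_speed = 0.7, seed = 3)
)

metrics <- do.call(rbind, lapply(names(conditions), function(cond) {
  sc <- conditions[[cond]]
  g <- generate_stack(sc)
  trs <- trajectories_from_table(g$truth$trajectories, "cell_1",
                                 frame_interval = sc$frame_interval)
  m <- cell_metrics(trs$leading, trs$nucleus, trs$rear)
  m$condition <- cond
  m
}))
utils::write.csv(metrics, "results/cell_metrics.csv", row.names = FALSE)
print(metrics[, c("condition", "mean_speed_um_min", "persistence",
                  "mean_cell_length_um", "mean_nuclear_position_pct",
                  "rear_nucleus_flag")], row.names = FALSE)
cat("narrow-track cells crawl at ~0.5 um/min, wide-track at ~0.7 um/min;\n")
cat("straight generator paths give persistence 1 by construction.\n")
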