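#!/usr/bin/env Rscript
# Step 4: figures. One example cell's trajectory and angle time courses,
# cumulative-angle curves for both cohorts, and frequency box plots.
# Figures are regenerable graphics, so they go under scratch/figures/.

suppressMessages(library(flagrot))
fig_dir <- "scratch/figures"
dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)

example <- read_dlc_csv("scratch/cohort/live/cell_000.csv", fps = 200,
                        condition = "live")
res <- analyze_cell(example, run_config(), keep_series = TRUE)
ggplot2::ggsave(file.path(fig_dir, "trajectory.pdf"),
                plot_trajectory(example), width = 5, height = 5)
ggplot2::ggsave(file.path(fig_dir, "angles.pdf"),
                plot_angle_timecourse(res$series$body, res$series$flagellar,
                                      t_max = 1),
                width = 7, height = 5)

series <- list()
cond_map <- character(0)
for (cc in c("live", "demembranated")) {
  files <- list.files(file.path("scratch/cohort", cc), pattern = "\\.csv$",
                      full.names = TRUE)
  for (f in files[1:5]) {
    tr <- read_dlc_csv(f, fps = 200, condition = cc)
    id <- paste(cc, tr$cell_id, sep = "_")
    series[[id]] <- unwrap_cumulative(body_axis_angle(tr))
    cond_map[id] <- cc
  }
}
ggplot2::ggsave(file.path(fig_dir, "cumulative_angles.pdf"),
                plot_cumulative_angles(series, cond_map),
                width = 7, height = 5)

per_cell <- read.csv("results/cohort/per_cell.csv")
ggplot2::ggsave(file.path(fig_dir, "beat_box.pdf"),
                plot_freq_box(per_cell, "beat_hz"), width = 4, height = 5)
ggplot2::ggsave(file.path(fig_dir, "rotation_box.pdf"),
                plot_freq_box(per_cell, "rotfreq_hz"), width = 4, height = 5)
cat("figures written under", fig_dir, "\n")
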