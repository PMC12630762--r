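#!/usr/bin/env Rscript
# Stage 3: behavioral metrics per localized track — dive phases against the
# bathymetry (200 m at-depth rule), descent angle (KDE peak +/- trimmed sd),
# median swim speeds with the 5/10-minute phase filters, altitude above the
# seafloor — plus encounter segmentation of the detection record.

library(pamtrackr)

scene <- "results/scene"
loc <- "results/localization"
out <- "results/metrics"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bathy <- read_esri_ascii(file.path(scene, "bathymetry.asc"))
files <- list.files(loc, pattern = "^track_.*\\.csv$", full.names = TRUE)
tracks <- lapply(files, read_tracks)
names(tracks) <- sub("^track_(.*)\\.csv$", "\\1", basename(files))

met <- track_metrics(tracks, bathy, min_step_m = 20)
write.csv(met, file.path(out, "track_metrics.csv"), row.names = FALSE)

det <- read_detections(file.path(scene, "detections.csv"))
enc <- segment_encounters(det$arrival_time_s, gap_minutes = 30)
write.csv(enc, file.path(out, "encounters.csv"), row.names = FALSE)

pr <- presence_summary(det$arrival_time_s,
                       data.frame(start_s = 0, end_s = 3700), bin_s = 60)

cat("\n-- dive metrics --\n")
print(met[, c("whale_id", "descent_angle_deg", "descent_angle_sd_deg",
              "at_depth_speed_mps", "median_altitude_m")])
cat(sprintf("encounters: %d; click-positive minutes: %.1f%%\n",
            nrow(enc), 100 * pr$fraction))
cat("outputs in", out, "\n")
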