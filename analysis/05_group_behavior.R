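#!/usr/bin/env Rscript
# Stage 5: group-level behavior from the localized tracks — group size
# across arrays, per-minute pairs distances, time-free lane distances,
# closest-approach lags, single-linkage subgrouping (1000 m cutoff, 10-min
# overlap rule), and the 10 m track-density map.

library(pamtrackr)

scene <- "results/scene"
loc <- "results/localization"
out <- "results/groups"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

det <- read_detections(file.path(scene, "detections.csv"))
files <- list.files(loc, pattern = "^track_.*\\.csv$", full.names = TRUE)
tracks <- lapply(files, read_tracks)
names(tracks) <- sub("^track_(.*)\\.csv$", "\\1", basename(files))

ids_a <- unique(det$truth_whale_id[det$array_id == "A"])
ids_b <- unique(det$truth_whale_id[det$array_id == "B"])
pairings <- data.frame(train_a = names(tracks), train_b = names(tracks))
gs <- group_size(ids_a, ids_b, pairings)

pairs <- utils::combn(names(tracks), 2, simplify = FALSE)
pair_rows <- lapply(pairs, function(pp) {
  pd <- pairs_distance(tracks[[pp[1]]], tracks[[pp[2]]])
  ld <- lane_distance(tracks[[pp[1]]], tracks[[pp[2]]])
  cl <- closest_approach_lag(tracks[[pp[1]]], tracks[[pp[2]]])
  data.frame(whale_a = pp[1], whale_b = pp[2],
             median_pairs_m = median(pd$mean_distance_m),
             median_lane_m = median(ld$mean_distance_m),
             closest_lag_s = cl$lag_s,
             closest_distance_m = cl$distance_m)
})
pair_tab <- do.call(rbind, pair_rows)
write.csv(pair_tab, file.path(out, "pair_metrics.csv"), row.names = FALSE)

sub <- find_subgroups(tracks)
dens <- track_density(tracks, bin_size = 10)
write_esri_ascii(list(x = dens$x_edges[-1] - 5, y = dens$y_edges[-1] - 5,
                      depth = dens$counts, cell_size = 10),
                 file.path(out, "track_density.asc"))

summ <- data.frame(group_size = gs,
                   n_subgroups = sub$n_subgroups,
                   mean_subgroup_size = sub$mean_size,
                   modal_pairs_m = median(pair_tab$median_pairs_m),
                   modal_lane_m = median(pair_tab$median_lane_m))
write.csv(summ, file.path(out, "group_summary.csv"), row.names = FALSE)

cat("\n-- group behavior --\n")
cat("group size:", gs, " subgroups:", sub$n_subgroups,
    " mean subgroup size:", sub$mean_size, "\n")
print(pair_tab)
cat("tracks occupy", sum(dens$counts > 0), "density bins of 10 m\n")
cat("outputs in", out, "\n")
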