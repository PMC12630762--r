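# pamtrackr

Passive acoustic 3D tracking of deep-diving echolocating whales from a
pair of seafloor small-aperture hydrophone arrays — as a tested, seeded,
end-to-end R pipeline.

Deep-diving toothed whales such as goose-beaked whales (*Ziphius
cavirostris*) echolocate only during hour-long deep foraging dives, which
makes them trackable in three dimensions from fixed seafloor recorders:
each click's time-differences-of-arrival (TDOAs) across a 1 m-aperture
4-hydrophone array give a bearing, and the bearings from two arrays ~1 km
apart cross-fix the whale's position click by click. `pamtrackr`
implements that analysis chain for researchers in marine bioacoustics and
movement ecology, together with the behavioral metrics built on it and a
synthetic-scene generator so every stage can be exercised without
multi-month acoustic recordings.

## What the package computes

Given per-array click detections (simulated by the package or supplied as
CSV):

1. **TDOA measurement** — per-pair cross-correlation of 4-channel click
   windows (20 kHz highpass), with envelope-guided sub-sample peak
   interpolation; pair order (1,2),(1,3),(1,4),(2,3),(2,4),(3,4) and sign
   convention τᵢⱼ = tᵢ − tⱼ = −(pᵢ−pⱼ)·u/c.
2. **DOA inversion** — least squares on B u = −c τ for the unit bearing u.
3. **Cross-fix localization** — midpoint of the mutual perpendicular
   between the two bearing rays, with jackknife 95% confidence intervals
   (six leave-one-TDOA-pair-out re-localizations, Student-t, df = 5).
4. **Track smoothing** — constant-velocity Kalman filter (measurement
   noise from the per-point CIs, floored at 10 m) plus a centered moving
   average.
5. **Dive metrics** — encounters (30-min gap rule), dive phases (at depth
   = within 200 m of the seafloor, one-way switch), descent angle (KDE
   peak of per-segment angles ± trimmed s.d.), median swim speeds with
   5/10-minute phase filters, altitude above the seafloor.
6. **Detection probability** — Monte Carlo: 10,000 whales per iteration in
   an 8 × 8 km area on a 100 m grid, source level 221–223 dB pp,
   directivity 23–25 dB (circular-piston beam), spherical-spreading +
   absorption transmission loss (pluggable, table import supported),
   detected iff received level ≥ 112 dB pp on **both** arrays; 135
   iterations, duration weighting, max-normalization.
7. **Group behavior** — group size across arrays, per-minute pairs
   distance, time-free lane distance on 1 m arc-length resampled tracks,
   closest-approach time lags, single-linkage subgrouping (1000 m cutoff,
   10-min temporal-overlap rule), 10 m track-density maps.
8. **Receiver self-calibration** — nonlinear least squares for the phone
   positions from ship-noise TDOAs at known GPS positions.

The methods vignette (`vignettes/tracking-methods.Rmd`) documents the
models, conventions, defaults, and the design decisions taken where the
underlying methods descriptions are ambiguous.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
deployment (two tetrahedral arrays 1 km apart on a 1300 m plain, three
coordinated whales). From the repository root:

```sh
Rscript analysis/01_simulate_scene.R
Rscript analysis/02_localize_tracks.R
Rscript analysis/03_dive_metrics.R
Rscript analysis/04_detection_probability.R
Rscript analysis/05_group_behavior.R
```

Stage 1 simulates 3 whales that emit 24,421 clicks and produce 48,687
detections across the two arrays. Stage 2 re-localizes them without using
the simulation truth (beyond per-array train identities, which stand in
for the manual sorting step):

```
  w1: 8123 fixes over 3255 s, median CI95 (x) 15.2 m
  w2: 8101 fixes over 3255 s, median CI95 (x) 12.4 m
  w3: 8042 fixes over 3256 s, median CI95 (x) 14.2 m
```

Stage 3 recovers the dive behavior that was simulated (descent pitch
−68.8°, foraging 50–200 m above the seafloor):

```
  whale_id descent_angle_deg at_depth_speed_mps median_altitude_m
        w2             -69.8               1.34             125.2
        w3             -70.0               1.35             124.9
encounters: 1; click-positive minutes: 91.9%
```

Stage 4 runs the full 135-iteration detection-probability sweep (p = 1.00
between the arrays, a steep drop beyond ~900 m from the array midpoint,
and an on-axis closed-form detection radius of 3833 m at source level
222 dB). Stage 5 reports the group structure:

```
group size: 3  subgroups: 1  mean subgroup size: 3
  whale_a whale_b median_pairs_m median_lane_m closest_lag_s
        w1      w2          392.2         351.7          83.9
```

Lane distances below pairs distances are the signature of whales following
similar paths offset in time — the coordination pattern the group metrics
are designed to expose.

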