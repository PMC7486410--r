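# cahub

Analysis of population calcium-imaging rasters around network synchrony and
hub neurons: surrogate-based detection of network bursts (GDPs) in
developing hippocampal slices and of synchronous calcium events (SCEs) in
vivo, single-cell stimulation tests, locomotion- and SCE-modulation
classification, ICA-based cell assemblies, directed functional-connectivity
graphs with hub scoring, and matched-subsampling group statistics — plus
synthetic-session generators with ground truth that validate every stage
end to end.

## Who this is for

Labs doing two-photon population calcium imaging who work from binary onset
(or inferred-spike) rasters and need reproducible, testable implementations
of the now-standard raster analyses: does a cell's stimulation change the
network rhythm, is a cell recruited by locomotion or by rest-period
population events, which co-activation assemblies exist, and which cells
are functional hubs.

## The statistics at the core

Everything rests on the circular-shift surrogate: rotating each cell's
event train by an independent uniform offset preserves rates and
autostructure while destroying cross-cell timing.

* **GDP / SCE detection** — population onset sum per frame (or per 200 ms
  rest bin) thresholded at the 99th percentile of pooled surrogate sums;
  suprathreshold peaks at least 1 s apart are events.
* **Stimulation tests** — windowed inter-GDP-interval distributions compared
  across pre/stimulation/post epochs by Kolmogorov–Smirnov; burst phase
  `phi_i = (t_i - i*dt)/dt` against the control period `dt`; burst locking
  via the highest peak of the trial-aligned onset histogram against 100
  pseudo-stimulation surrogates.
* **Modulation z-PSTHs** — `Z = (PSTH - mu_B)/sigma_B` with baseline taken
  before the event; locomotion-ON needs two consecutive bins with Z > 2 (or
  a rate ratio above the per-cell shuffled 95th percentile), SCE-ON needs
  zero-lag Z > 3.
* **Assemblies** — significant pattern count from PCA eigenvalues against
  circularly shifted matrices, patterns from ICA, activity as the quadratic
  projection `R_k(t) = z(t)' P_k z(t)` with zeroed diagonal.
* **Directed connectivity** — per-pair spike-lag distributions in ±1 s;
  pairs that are sparse, zero-centered, or uniform-consistent are excluded;
  the mean-lag sign directs the edge; hubs jointly satisfy a local degree
  floor, a pooled top-5% degree criterion and a pooled 80th-percentile
  betweenness criterion.
* **Group statistics** — matched-subsampling bootstrap (per-FOV tagged-count
  matched draws, 95th-percentile rule) and exact hypergeometric-enumeration
  Fisher tests.

## Worked example

```r
library(cahub)

# a simulated slice session whose stimulated cell locks network bursts
spec <- slice_sim_spec(hub_effect = hub_locking(latency_s = 2.2,
                                                latency_sd_s = 0.3,
                                                lock_prob = 0.9),
                       seed = 1)
session <- gen_slice_session(spec)
gdps <- detect_gdps(session$raster, seed = 2)
gdps
#> <gdp_catalog> 46 GDP(s) in 900.0 s (rate 0.05111 Hz), threshold > 3

lock <- test_gdp_locking(session$raster, session$protocol, gdps, seed = 3)
lock
#> <locking_result> peak 0.3907 at 2.30 s, p = 0 (significant)
```

The catalog's rate (0.051 Hz) exceeds the spontaneous 0.02 Hz because the
locking effect inserts a burst after ~90% of the 30 stimulations; the
locking test recovers the planted 2.2 s latency within one frame (2.3 s),
and none of the 100 pseudo-stimulation surrogates reaches the observed
histogram peak (p = 0).

```r
# in vivo: SCEs during rest on the calibrated generator
ses <- gen_invivo_session(invivo_sim_spec(n_cells = 120, duration_s = 600,
                                          loco_modulated_fraction = 0,
                                          seed = 1))
detect_sces(ses$raster, ses$epochs$rest, seed = 2)
#> <sce_catalog> 36 SCE(s) in 418.2 s rest (rate 0.0861 Hz), threshold > 5
```

The detected rest-period SCE rate (0.0861 Hz) recovers the generator's
0.08 Hz within its sampling fluctuation.

## Layout

- `R/` — raster/epoch data model, simulators, slice (GDP) pipeline, in vivo
  modulation, assemblies, connectivity, group statistics
- `tests/testthat/` — unit, property and end-to-end calibration tests
- `vignettes/cahub-methods.Rmd` — the methods notes: definitions, design
  choices, generator calibration, limitations
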