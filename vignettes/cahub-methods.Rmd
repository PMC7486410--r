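---
title: "Methods: surrogate-based analysis of population calcium-imaging rasters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surrogate-based analysis of population calcium-imaging rasters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cahub)
```

## Scope and data model

`cahub` analyses *binary onset rasters*: matrices with one row per imaged
cell and one column per frame, where a 1 marks the detected onset of a
calcium event (ex vivo) or an inferred spike (in vivo). Everything upstream —
segmentation, trace extraction, spike inference — is out of scope; the
pipeline starts at the raster. Frames are indexed 0-based and all intervals
are half-open `[start, end)`, which makes epoch arithmetic composable and
avoids off-by-one errors at epoch boundaries.

The central statistical device throughout is the **circular-shift
surrogate**: each cell's event train is rotated by an independent uniform
offset. This preserves every cell's rate and autostructure exactly while
destroying cross-cell timing, and therefore provides the null model for
every synchrony-based statistic (network-burst detection, synchronous
calcium events, assembly counts, modulation thresholds). Offset 0 is
excluded whenever a train has more than one frame, so a surrogate never
coincides with the data.

## Developing-slice analysis (GDPs)

**Detection.** Network bursts (giant depolarizing potentials, GDPs) are
frames where the population onset sum exceeds the 99th percentile of the
pooled per-frame sums of 1000 circular-shift surrogates. Runs of
suprathreshold frames are merged; the burst peak is the frame of maximal sum
in the run (earliest on ties), and peaks closer than 1 s are merged keeping
the larger. Because per-frame sums are small integers in slice data, the
percentile threshold is an integer count; the suprathreshold rule is strict
(`sum > threshold`).

**Frequency effect of single-cell stimulation.** The recording is split into
pre / stimulation / post epochs. For each epoch, a windowed average
inter-GDP interval (IGI) is computed from each GDP peak over a window of
`t_s` frames (300 or 400), discarding windows that cross an epoch boundary.
The three distributions are compared pairwise by Kolmogorov–Smirnov tests at
p < 0.05; the classification is driven by the pre-vs-stimulation comparison,
with direction given by the stimulation-epoch median relative to control
(lower median IGI = increased burst frequency). A recording is excluded when
the control-IGI coefficient of variation exceeds 1, and "not assessable"
when any epoch yields fewer than two windowed values.

**Phase.** The control IGI defines the period `delta_t` of a reference
oscillator. The phase of the i-th burst, in cycles, is
`phi_i = (t_i - i * delta_t) / delta_t`. A recording is included only when
the control-condition drift stays within ±2 cycles. The measure is
translation-covariant: shifting all burst times by `k * delta_t` shifts
every phase by exactly `k`.

**Locking.** For each stimulation, a post-stimulation trial of 2.5 or 5 s is
cut out; the average histogram of all cells' onsets across trials (1-frame
bins) is normalized by the number of GDPs during the stimulation epoch, and
its highest peak is the observed statistic. Surrogate data are the
concatenated pre and post epochs (no stimulation trials); each of 100
surrogates draws one independent uniform start frame per pseudo-trial,
matching trial count and length, and the same histogram and normalizer are
applied. Two details matter for calibration and are deliberate choices:

* *Per-trial pseudo-stimulation starts.* If each surrogate instead used a
  single start with a periodic matched train, every surrogate train on the
  fixed segment would catch the same bursts at translated offsets; the
  surrogate peaks then collapse to a near-constant and the test runs far
  above its nominal level (we measured ~16% on null sessions). Independent
  per-trial starts make surrogate peaks exchangeable with the observed peak
  under the null; the measured type-I error over 200 null sessions lies
  inside the binomial 95% interval of 5%.
* *One common normalizer.* Both the observed and surrogate histograms are
  divided by the GDP count of the stimulation epoch. Normalizing surrogates
  by their own segment's count would introduce a systematic factor equal to
  the segment-length ratio.

Significance requires the observed peak in the top 5% of surrogate peaks
(empirical `p = mean(surrogate >= observed) < 0.05`); ties therefore count
against significance, which is conservative. The reported latency is the
earliest maximal bin.

## In vivo analysis

**Epochs.** Locomotion epochs are maximal runs of frames with photo-sensor
deflection; rest epochs are movement-free runs strictly longer than 200 ms.
A movement-free gap of exactly 200 ms belongs to neither set. No minimum
locomotion bout duration is imposed.

**Locomotion modulation** combines two tests per cell (OR):

1. *Onset z-PSTH.* A 10 s PSTH aligned on locomotion onsets, in bins of 5
   frames (~500 ms at 9.85 Hz, configurable), is z-scored against the
   baseline bins lying entirely before −200 ms; the cell is significant when
   at least two consecutive bins from −200 ms onward exceed Z = 2. The
   operational definition fixes the window, not the bin width. Finer bins
   look attractive but are miscalibrated: with sparse, Poisson-like onset
   counts the baseline SD of a 1-frame PSTH is a noisy underestimate and the
   two-consecutive-bin rule then flags 13–20% of rate-constant cells in null
   simulations at any realistic rate, versus ~5% at 500 ms. Even at 500 ms
   the rule needs onset counts in the tens (it is anti-conservative below
   ~30 locomotion bouts), which the validation scenarios respect.
2. *Rate ratio.* The locomotion/rest spike-count ratio is compared with the
   per-cell 95th percentile of the same ratio under 1000 circular shifts. A
   half-count (+0.5) is added to both numerator and denominator throughout —
   not only when a denominator is zero — so that real and surrogate ratios
   live on one scale and rest-silent cells remain defined.

**SCE detection.** Rest frames are binned at 200 ms (2 frames at 9.85 Hz),
epoch-wise so no bin straddles two rest intervals. The population sum per
bin is thresholded at the 99th percentile of the pooled surrogate sums from
1000 per-cell circular shifts of the binned counts (a single global
threshold). Suprathreshold peaks at least 1 s apart are SCEs. The catalog
stores both the SCE bin and the *peak frame* (frame of maximal population
count inside the bin).

**SCE modulation.** A 4 s PSTH aligned on SCE peak frames at 1-frame bins is
z-scored against the pre-event half-window (the operational definition of
the baseline — activity preceding the event — leaves its extent open; the
preceding half-window is the natural choice). A cell is SCE-ON when Z at zero lag strictly exceeds 3; zero
baseline SD flags the cell indeterminate rather than silently non-significant.
Aligning at the peak frame rather than the bin start matters at 1-frame
resolution: the co-activation may sit on either frame of the 200 ms bin.

**Assemblies.** Rest-binned counts (200 ms) are convolved with a Gaussian
kernel (SD 1 bin by default; the width is a free parameter) and z-scored per
cell. The number of significant co-activation patterns is the number of
principal-component variances above the *maximum* eigenvalue across 500
circularly shifted matrices; patterns are then extracted by independent
component analysis restricted to the significant principal subspace
(symmetric fixed-point iteration with tanh contrast; five random restarts
keep the solution with the largest log-cosh negentropy, since the iteration
has mixing local optima; deterministic under the seed), mapped back to cell
space, unit-normalized, and sign-aligned so the
largest-magnitude weight is positive. Assembly activity is the quadratic
projection `R_k(t) = z(t)' P_k z(t)` with `P_k = w_k w_k'` and zeroed
diagonal, so a single cell cannot drive its own assembly's activity, and the
activity is invariant to the sign of `w_k`. Per-cell assembly modulation
cross-correlates binned counts with each activity over ±4 s (circularly, so
circular-shift surrogates are exactly exchangeable), averages across
assemblies, and requires at least two consecutive of the five central bins
above the per-cell 95th surrogate percentile.

**Directed connectivity.** For each cell pair (A, B), the lags of B's spikes
relative to each A spike within ±1000 ms form the pair's lag distribution
(the reverse pair is its mirror). A pair is excluded when sparse (fewer than
20 samples; the normality test itself needs at least 8), when it is a
zero-delay correlation, or when it is consistent with uniform co-activation
(Kolmogorov–Smirnov against uniform on ±1000 ms, p ≥ 0.05). Zero-delay
exclusion is operationalized as |mean lag| below one frame duration, with
the D'Agostino–Pearson omnibus test distinguishing Gaussian-shaped from
merely zero-centered distributions in the recorded verdict. The design
choice to exclude *any* zero-centered distribution — not only those passing
the normality test — is deliberate: cells driven by a common source co-fire
with near-zero-mean but heavy-tailed lag distributions, which a literal
"Gaussian only" rule would retain as spurious edges. Retained pairs give one
directed edge in the direction of the mean lag. Hub cells must jointly (1)
contact at least 5% of the cells in their own field of view, (2) reach the
top 5% of the pooled across-FOV out-degree distribution, and (3) reach the
pooled 80th betweenness percentile. Percentile criteria use ≥ on empirical
quantiles: in sparse graphs the pooled betweenness distribution can be
degenerate at 0, where a strict rule would be vacuous.

**Group statistics.** The matched-subsampling bootstrap draws, in each of
1000 repetitions, as many untagged cells per field of view as there are
tagged cells (without replacement) and recomputes the statistic; the
observed tagged-cell value is significant above the surrogate 95th
percentile (upper tail by default; a two-sided 2.5/97.5 variant is
available — figure-level reports used two-sided language while the
operational definition is upper-tail). The Fisher exact test is an
exhaustive hypergeometric enumeration at fixed margins summing all tables
with probability not exceeding the observed one; this convention reproduces
the published comparisons (p = 0.0331 and p = 0.417) to printed precision.

## The synthetic generators

The generators produce sessions with known ground truth so that every stage
has a recovery and a null test.

*Slice sessions* place spontaneous GDPs as a Poisson process (0.02 Hz
default, matching the recorded median), each recruiting every cell with
probability 0.9 with 1-frame Gaussian onset jitter, over sparse background
onsets (0.015 Hz per cell). Background rate and participation are free
parameters (the recordings report neither); the defaults are chosen so that
GDPs recruit the large majority of active cells — the defining property of
these network bursts — and so that the integer surrogate threshold sits one
count above the background-only tail, keeping spurious detections to a few
frames per 15-minute session. The stimulation protocol tiles the middle
third of the session at 0.1 Hz with 5 s trials; a locking hub effect inserts
a burst after each stimulation with probability 0.9 at a latency of
2.2 ± 0.3 s (between-cell spread in the recordings was 0.9 s); a frequency
hub effect rescales the Poisson rate during the stimulation epoch.

*In vivo sessions* run at 9.85 Hz with exponential locomotion/rest
alternation (means 10 s and 30 s; rest bouts floored at 1 s), Bernoulli
background spiking at 0.05 Hz per cell (typical for inferred spikes in CA1
imaging), a locomotion rate gain of 4 for a configurable fraction of cells,
rest-only SCEs at 0.08 Hz with 1 s margins, assemblies activating jointly
within single frames (hence single 200 ms bins), and directed hub motifs
whose targets follow each source spike with probability 0.9 at a configured
lag (±40 ms jitter).

What the generators do **not** emulate: fluorescence dynamics and indicator
kinetics, imaging noise and motion artifacts, spike-inference errors,
non-stationary rates, bursting autostructure, overlapping assemblies with
graded membership, and polysynaptic lag distributions. Passing recovery
tests therefore demonstrates correctness of the statistics under their own
assumptions, not robustness to the full complexity of real recordings.

## Numerical choices and degenerate inputs

* Pooled surrogate percentiles are left-continuous (smallest value whose
  CDF reaches the target), computed exactly from integer histograms.
* Detection thresholds are strict (`>`); modulation thresholds are strict;
  the SCE-ON rule at Z exactly equal to the threshold is *not* significant.
* Zero-variance cells are dropped from assembly detection (with a message)
  and re-inserted with zero weight; zero baseline SD in a z-PSTH flags the
  cell rather than producing ±Inf.
* Empty rasters, empty rest epochs and burst-free stimulation epochs return
  empty catalogs or "not assessable" results, never errors.
* All stochastic stages take an integer `seed` and are bit-reproducible;
  surrogate draws never mutate the caller's RNG stream.

## Problem sizes used in the validation suite

The shipped tests exercise: 200 null slice sessions (80 cells, 600 s) for
the locking type-I error; 50 locking-recovery sessions at 2.2 s latency; 20
independent 100-cell rasters (10 min) for the SCE null rate; 50 sessions of
150 cells with three 20-cell assemblies (240 s, rest-dominated) for assembly
recovery; 30-minute 60-cell sessions with a planted 6-target hub (background
0.04 Hz, so that only genuinely coupled pairs reach the 20-sample floor) for
edge precision/recall and hub classification; and 500 simulated datasets of
7 fields of view for the matched-subsampling null. These sizes were chosen
as the smallest problems on which each property is sharply testable on a
single CPU.

## Known limitations

* The lag-graph pair loop is quadratic in cell count; fields of view beyond
  a few hundred cells will be slow in pure R.
* The KS uniformity test treats frame-lattice lags as continuous; at the
  sample sizes retained here the level distortion is small (measured ~3–7%
  rejection under a true lattice-uniform null), but it grows with n.
* The eigenvalue threshold for assembly counting uses the maximum over
  shuffles; with very few shuffles it is noisy, with many it is
  conservative. An analytical Marchenko–Pastur bound would be a natural
  alternative and is deliberately not the default, since the shuffle route
  is the operational definition here.
* Matched subsampling requires every FOV with tagged cells to contain at
  least as many untagged cells; designs violating this stop with an error
  naming the FOV.
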