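# Circular cross-correlation of every raster row with an indicator signal:
# out[i, o+1] = sum_t x_i[(t - o) mod T] * m[t], o = 0 .. T-1, i.e. the count
# of cell i's events falling in `m` after rotating its row by o frames.
circular_overlap_counts <- function(m01, indicator) {
  tt <- ncol(m01)
  fm <- fft(as.numeric(indicator))
  fx <- mvfft(t(m01))                      # frames x cells
  out <- Re(mvfft(Conj(fx) * fm, inverse = TRUE)) / tt
  round(t(out))
}

# Event-aligned per-cell PSTH at 1-frame bins. events0 are 0-based frames;
# only events with a complete [-pre, +post] window are used.
event_psth <- function(r, events0, pre, post) {
  tt <- n_frames(r)
  ev <- events0[events0 - pre >= 0L & events0 + post <= tt - 1L]
  nb <- pre + post + 1L
  psth <- matrix(0, n_cells(r), nb)
  for (e in ev) {
    psth <- psth + r$onsets[, (e - pre + 1L):(e + post + 1L), drop = FALSE]
  }
  list(psth = psth / max(1L, length(ev)), n_events = length(ev),
       bin_t = (seq_len(nb) - 1L - pre) / r$frame_rate_hz)
}

# Event-aligned per-cell PSTH with bins of `bw` frames tiled across the
# [-half, +half] frame window; returns bin start/end times in seconds.
event_psth_binned <- function(r, events0, half, bw) {
  tt <- n_frames(r)
  ev <- events0[events0 - half >= 0L & events0 + half <= tt - 1L]
  nbins <- (2L * half + 1L) %/% bw
  psth <- matrix(0, n_cells(r), nbins)
  grp <- rep(seq_len(nbins), each = bw)
  for (e in ev) {
    seg <- r$onsets[, (e - half + 1L):(e - half + nbins * bw), drop = FALSE]
    psth <- psth + t(rowsum(t(seg), grp))
  }
  fr <- r$frame_rate_hz
  start_f <- (seq_len(nbins) - 1L) * bw - half
  list(psth = psth / max(1L, length(ev)), n_events = length(ev),
       bin_start_t = start_f / fr, bin_end_t = (start_f + bw) / fr)
}

# TRUE where >= k consecutive TRUEs occur
has_consecutive <- function(x, k = 2L) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  any(r$values & r$lengths >= k)
}

#' Event-aligned z-scored PSTH for one cell
#'
#' Peri-event time histogram at single-frame resolution, z-scored against the
#' baseline bins: `Z = (PSTH - mu_B) / sigma_B` where `mu_B` and `sigma_B`
#' are the mean and SD of the PSTH over the baseline bins.
#'
#' @param r an [activity_raster()].
#' @param cell cell index.
#' @param events0 0-based event frames to align on.
#' @param window_s total window length in seconds (half before, half after).
#' @param baseline_end_s baseline = bins strictly before this time (seconds,
#'   relative to the event; e.g. -0.2 for activity preceding 200 ms before
#'   the event, 0 for the full pre-event half-window).
#' @return object of class `zpsth`: `bin_t`, `psth`, `mu_b`, `sd_b`, `z`,
#'   `n_events`, `defined` (FALSE when the baseline SD is zero).
#' @export
zpsth <- function(r, cell, events0, window_s, baseline_end_s = 0) {
  half <- as.integer(round(window_s / 2 * r$frame_rate_hz))
  ep <- event_psth(r, events0, half, half)
  p <- ep$psth[cell, ]
  bl <- ep$bin_t < baseline_end_s
  mu <- mean(p[bl]); s <- sd(p[bl])
  structure(list(bin_t = ep$bin_t, psth = p, mu_b = mu, sd_b = s,
                 z = if (isTRUE(s > 0)) (p - mu) / s else rep(NA_real_, length(p)),
                 n_events = ep$n_events, defined = isTRUE(s > 0)),
            class = "zpsth")
}

#' @export
print.zpsth <- function(x, ...) {
  cat(sprintf("<zpsth> %d bins, %d events, baseline %.3g +/- %.3g%s\n",
              length(x$psth), x$n_events, x$mu_b, x$sd_b,
              if (x$defined) "" else " (sigma_B = 0: Z undefined)"))
  invisible(x)
}

#' @export
plot.zpsth <- function(x, ...) {
  plot(x$bin_t, x$z, type = "s", xlab = "time from event (s)",
       ylab = "Z", ...)
  abline(h = 0, lty = 3); abline(v = 0, lty = 2)
  invisible(x)
}

#' Classify locomotion-activated cells
#'
#' Two complementary tests per cell, combined with OR. Method 1 (onset
#' z-PSTH): a 10 s PSTH aligned on locomotion onsets, in bins of
#' `psth_bin_frames` frames (~500 ms by default), is z-scored against the
#' baseline bins lying entirely before -200 ms; the cell is significant if at
#' least two consecutive bins from -200 ms onward exceed Z = 2. Method 2
#' (rate ratio): each cell's locomotion/rest spike-count ratio is compared
#' with the per-cell 95th percentile of the same ratio under circular shifts
#' of its spike train. A half-count (+0.5) is added to numerator and
#' denominator throughout so rest-silent cells remain defined.
#'
#' Sub-second PSTH bins are deliberately avoided: with sparse, Poisson-like
#' onset counts the baseline SD is a noisy underestimate and the
#' two-consecutive-bin rule then fires on a large fraction of rate-constant
#' cells (~20% at 1-frame bins in null simulations, vs ~5% at 500 ms).
#'
#' @param r an [activity_raster()].
#' @param loco,rest locomotion and rest [epoch_set()]s (e.g. from
#'   [derive_epochs()]).
#' @param n_shuffles circular shifts per cell for method 2.
#' @param window_s method-1 PSTH window (seconds).
#' @param z_thresh method-1 Z threshold.
#' @param psth_bin_frames method-1 PSTH bin width in frames.
#' @param seed optional integer seed.
#' @return object of class `loco_modulation`: logical vectors `onset_sig`,
#'   `ratio_sig`, `locomotion_on`, the z-PSTH matrix `z` (cells x bins) with
#'   `bin_t`, ratios and per-cell thresholds.
#' @export
classify_locomotion <- function(r, loco, rest, n_shuffles = 1000,
                                window_s = 10, z_thresh = 2,
                                psth_bin_frames = 5, seed = NULL) {
  stopifnot(inherits(r, "activity_raster"))
  tt <- n_frames(r); fr <- r$frame_rate_hz
  onsets0 <- loco$intervals[, 1]
  if (!length(onsets0)) stop("no locomotion onset")

  # method 1: onset-aligned z-PSTH
  half <- as.integer(round(window_s / 2 * fr))
  ep <- event_psth_binned(r, onsets0, half, as.integer(psth_bin_frames))
  bl <- ep$bin_end_t <= -0.2 + 1e-9       # baseline: entirely before -200 ms
  mu <- rowMeans(ep$psth[, bl, drop = FALSE])
  sdv <- apply(ep$psth[, bl, drop = FALSE], 1L, sd)
  z <- (ep$psth - mu) / ifelse(sdv > 0, sdv, NA_real_)
  test_cols <- !bl
  onset_sig <- apply(z[, test_cols, drop = FALSE] > z_thresh, 1L,
                     has_consecutive, k = 2L)
  onset_sig[is.na(onset_sig)] <- FALSE

  # method 2: locomotion/rest count ratio vs circular-shift null
  loco_ind <- rest_ind <- logical(tt)
  loco_ind[epoch_frames(loco) + 1L] <- TRUE
  rest_ind[epoch_frames(rest) + 1L] <- TRUE
  a_all <- circular_overlap_counts(r$onsets, loco_ind)  # cells x offsets
  b_all <- circular_overlap_counts(r$onsets, rest_ind)
  ratio_all <- (a_all + 0.5) / (b_all + 0.5)
  real_ratio <- ratio_all[, 1L]
  offs <- with_seed(seed, matrix(
    sample.int(tt - 1L, n_cells(r) * n_shuffles, replace = TRUE),
    nrow = n_cells(r)))
  thr <- vapply(seq_len(n_cells(r)), function(i) {
    quantile(ratio_all[i, offs[i, ] + 1L], 0.95, names = FALSE)
  }, numeric(1))
  ratio_sig <- real_ratio > thr

  structure(list(onset_sig = onset_sig, ratio_sig = ratio_sig,
                 locomotion_on = onset_sig | ratio_sig,
                 z = z, bin_t = ep$bin_start_t, n_onsets = ep$n_events,
                 ratio = real_ratio, ratio_threshold = thr,
                 z_thresh = z_thresh),
            class = "loco_modulation")
}

#' @export
print.loco_modulation <- function(x, ...) {
  cat(sprintf(
    "<loco_modulation> %d/%d locomotion-ON (onset: %d, ratio: %d), %d onsets\n",
    sum(x$locomotion_on), length(x$locomotion_on), sum(x$onset_sig),
    sum(x$ratio_sig), x$n_onsets))
  invisible(x)
}

#' Detect synchronous calcium events (SCEs) during rest
#'
#' Bins the rest-restricted raster in `bin_ms` windows, sums spike counts
#' across cells per bin, and thresholds at the given percentile of the pooled
#' per-bin sums from circular-shift surrogates (each cell's binned counts
#' rotated independently). Suprathreshold runs give candidate SCEs at their
#' peak bin; peaks closer than `min_sep_s` (in recording time) are merged,
#' keeping the larger.
#'
#' @param r an [activity_raster()].
#' @param rest rest [epoch_set()].
#' @param bin_ms bin width (milliseconds).
#' @param n_surrogates circular-shift surrogates for the threshold.
#' @param pctile threshold percentile (0-100) of the pooled surrogate sums.
#' @param min_sep_s minimal separation between SCE peaks in seconds.
#' @param seed optional integer seed.
#' @return object of class `sce_catalog`: `bins` (bin indices), `bin_start_frames`,
#'   `peak_frames` (frame of maximal population count inside each SCE bin,
#'   0-based), `n_coactive`, `participants`, `threshold`,
#'   `frac_suprathreshold`, `rate_hz` (per second of rest), plus binning
#'   metadata.
#' @export
detect_sces <- function(r, rest, bin_ms = 200, n_surrogates = 1000,
                        pctile = 99, min_sep_s = 1, seed = NULL) {
  stopifnot(inherits(r, "activity_raster"), inherits(rest, "epoch_set"))
  fr <- r$frame_rate_hz
  br <- bin_raster(r, bin_ms, restrict = rest)
  nb <- ncol(br$counts)
  rest_dur_s <- epoch_duration_s(rest, fr)
  empty <- function(thr = NA_real_, frac = NA_real_, sums = integer()) {
    structure(list(bins = integer(), bin_start_frames = integer(),
                   peak_frames = integer(), n_coactive = integer(),
                   participants = list(), threshold = thr,
                   frac_suprathreshold = frac, rate_hz = 0,
                   bin_sums = sums, bin_map = br$bin_map, bin_s = br$bin_s,
                   frames_per_bin = br$frames_per_bin, frame_rate_hz = fr,
                   rest_duration_s = rest_dur_s, pctile = pctile),
              class = "sce_catalog")
  }
  if (nb < 2L) return(empty())
  sums <- colSums(br$counts)
  nz <- which(br$counts > 0L, arr.ind = TRUE)
  if (!nrow(nz)) return(empty(sums = sums))
  hist <- with_seed(seed, surrogate_sum_histogram(
    nz[, 2] - 1L, nz[, 1], br$counts[nz], nrow(br$counts), nb,
    n_surrogates, sum(br$counts)))
  thr <- histogram_quantile(hist, pctile / 100)
  supra <- sums > thr
  frac <- mean(supra)
  if (!any(supra)) return(empty(thr, frac, sums))

  rl <- rle(supra)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
  runs <- cbind(starts, ends)[rl$values, , drop = FALSE]
  peaks <- apply(runs, 1L, function(ab) ab[1] + which.max(sums[ab[1]:ab[2]]) - 1L)
  # enforce minimal separation in recording time between peak bins
  min_sep_f <- min_sep_s * fr
  peak_time <- function(b) br$bin_map$start_frame[b]
  i <- 1L
  while (i < length(peaks)) {
    if (peak_time(peaks[i + 1L]) - peak_time(peaks[i]) < min_sep_f) {
      drop <- if (sums[peaks[i + 1L]] > sums[peaks[i]]) i else i + 1L
      peaks <- peaks[-drop]
    } else i <- i + 1L
  }
  participants <- lapply(peaks, function(b) which(br$counts[, b] > 0L))
  peak_frames <- vapply(peaks, function(b) {
    a <- br$bin_map$start_frame[b] + 1L
    z <- br$bin_map$end_frame[b]
    cols <- a:z
    as.integer(cols[which.max(colSums(r$onsets[, cols, drop = FALSE]))] - 1L)
  }, integer(1))
  structure(list(bins = as.integer(peaks),
                 bin_start_frames = br$bin_map$start_frame[peaks],
                 peak_frames = peak_frames,
                 n_coactive = as.integer(sums[peaks]),
                 participants = participants, threshold = thr,
                 frac_suprathreshold = frac,
                 rate_hz = length(peaks) / rest_dur_s,
                 bin_sums = sums, bin_map = br$bin_map, bin_s = br$bin_s,
                 frames_per_bin = br$frames_per_bin, frame_rate_hz = fr,
                 rest_duration_s = rest_dur_s, pctile = pctile),
            class = "sce_catalog")
}

#' @export
print.sce_catalog <- function(x, ...) {
  cat(sprintf(
    "<sce_catalog> %d SCE(s) in %.1f s rest (rate %.3g Hz), threshold > %s\n",
    length(x$bins), x$rest_duration_s, x$rate_hz, format(x$threshold)))
  invisible(x)
}

#' Classify SCE-activated cells
#'
#' Builds a 4 s PSTH aligned on SCE peak frames at 1-frame bins per cell,
#' z-scored against the pre-event half-window, and flags a cell as SCE-ON if
#' its Z at zero time lag strictly exceeds `z_thresh`. Cells with zero
#' baseline SD are flagged indeterminate (NA).
#'
#' @param r an [activity_raster()].
#' @param sces an [detect_sces()] catalog.
#' @param window_s PSTH window (seconds).
#' @param z_thresh zero-lag Z threshold (strict).
#' @return object of class `sce_modulation`: logical (with NA) vector
#'   `sce_on`, zero-lag Z values, the z matrix and bin times.
#' @export
classify_sce_on <- function(r, sces, window_s = 4, z_thresh = 3) {
  stopifnot(inherits(r, "activity_raster"), inherits(sces, "sce_catalog"))
  if (!length(sces$peak_frames)) stop("no SCE in the catalog")
  half <- as.integer(round(window_s / 2 * r$frame_rate_hz))
  ep <- event_psth(r, sces$peak_frames, half, half)
  bl <- ep$bin_t < 0
  mu <- rowMeans(ep$psth[, bl, drop = FALSE])
  sdv <- apply(ep$psth[, bl, drop = FALSE], 1L, sd)
  z <- (ep$psth - mu) / ifelse(sdv > 0, sdv, NA_real_)
  zero_col <- which(ep$bin_t == 0)
  z0 <- z[, zero_col]
  sce_on <- z0 > z_thresh            # NA propagates for sigma_B = 0
  structure(list(sce_on = sce_on, z_zero_lag = z0, z = z, bin_t = ep$bin_t,
                 n_events = ep$n_events, z_thresh = z_thresh,
                 indeterminate = !(sdv > 0)),
            class = "sce_modulation")
}

#' @export
print.sce_modulation <- function(x, ...) {
  cat(sprintf("<sce_modulation> %d/%d SCE-ON (%d indeterminate), %d SCEs\n",
              sum(x$sce_on, na.rm = TRUE), length(x$sce_on),
              sum(x$indeterminate), x$n_events))
  invisible(x)
}
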