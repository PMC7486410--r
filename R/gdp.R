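#' Detect network bursts (GDPs) from a slice raster
#'
#' Computes the per-frame population onset sum and compares it against the
#' given percentile of the pooled sum distribution obtained from circular-
#' shift surrogates (each cell's onset train rotated by an independent
#' uniform offset). Runs of frames strictly above the threshold are merged
#' into candidate bursts; the burst peak is the frame of maximal sum in the
#' run (earliest on ties) and peaks closer than `min_separation_s` are merged,
#' keeping the larger peak.
#'
#' @param r an [activity_raster()].
#' @param n_surrogates number of circular-shift surrogates.
#' @param pctile percentile (0-100) of the pooled surrogate sums used as
#'   detection threshold.
#' @param min_separation_s minimal separation between burst peaks in seconds.
#' @param seed optional integer seed for the surrogate offsets.
#' @return object of class `gdp_catalog`: list with `t_G` (0-based peak
#'   frames), `t_G_s` (seconds), `participants` (cells with onsets in each
#'   burst's suprathreshold run), `igi_frames` / `igi_s` (inter-GDP
#'   intervals), `threshold`, `frac_suprathreshold` (fraction of frames above
#'   threshold), `rate_hz`, plus the detection settings.
#' @examples
#' m <- matrix(0L, 20, 100); m[, 51] <- 1L
#' detect_gdps(activity_raster(m, 10), n_surrogates = 100, seed = 1)
#' @export
detect_gdps <- function(r, n_surrogates = 1000, pctile = 99,
                        min_separation_s = 1, seed = NULL) {
  stopifnot(inherits(r, "activity_raster"))
  tt <- n_frames(r); nc <- n_cells(r); fr <- r$frame_rate_hz
  empty <- function(thr = NA_real_, frac = NA_real_) {
    structure(list(t_G = integer(), t_G_s = numeric(),
                   participants = list(), igi_frames = integer(),
                   igi_s = numeric(), threshold = thr,
                   frac_suprathreshold = frac, rate_hz = 0,
                   frame_rate_hz = fr, n_frames = tt, pctile = pctile,
                   n_surrogates = n_surrogates),
              class = "gdp_catalog")
  }
  if (tt < 2L || sum(r$onsets) == 0L) return(empty())

  s_real <- colSums(r$onsets)
  idx <- which(r$onsets == 1L, arr.ind = TRUE)
  pos0 <- idx[, 2] - 1L
  cell_of <- idx[, 1]
  hist <- with_seed(seed, surrogate_sum_histogram(
    pos0, cell_of, rep(1L, length(pos0)), nc, tt, n_surrogates, nc))
  thr <- histogram_quantile(hist, pctile / 100)
  supra <- s_real > thr
  frac <- mean(supra)
  if (!any(supra)) return(empty(thr, frac))

  rl <- rle(supra)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
  runs <- cbind(starts, ends)[rl$values, , drop = FALSE]
  peaks <- apply(runs, 1L, function(ab) {
    a <- ab[1]; b <- ab[2]
    a + which.max(s_real[a:b]) - 1L
  })
  # merge peaks closer than min_separation (keep the higher sum; earlier wins
  # ties), merging run extents for participation
  min_sep <- max(1L, as.integer(round(min_separation_s * fr)))
  ord <- order(peaks)
  peaks <- peaks[ord]; runs <- runs[ord, , drop = FALSE]
  i <- 1L
  while (i < length(peaks)) {
    if (peaks[i + 1L] - peaks[i] < min_sep) {
      keep <- if (s_real[peaks[i + 1L]] > s_real[peaks[i]]) i + 1L else i
      runs[keep, ] <- c(min(runs[i:(i + 1L), 1L]), max(runs[i:(i + 1L), 2L]))
      peaks <- peaks[-(i + (keep == i))]
      runs <- runs[-(i + (keep == i)), , drop = FALSE]
    } else i <- i + 1L
  }
  participants <- lapply(seq_along(peaks), function(k) {
    cols <- runs[k, 1L]:runs[k, 2L]
    which(rowSums(r$onsets[, cols, drop = FALSE]) > 0L)
  })
  t_G <- as.integer(peaks - 1L)   # 0-based
  structure(list(t_G = t_G, t_G_s = t_G / fr, participants = participants,
                 igi_frames = diff(t_G), igi_s = diff(t_G) / fr,
                 threshold = thr, frac_suprathreshold = frac,
                 rate_hz = length(t_G) / (tt / fr), frame_rate_hz = fr,
                 n_frames = tt, pctile = pctile,
                 n_surrogates = n_surrogates),
            class = "gdp_catalog")
}

#' @export
print.gdp_catalog <- function(x, ...) {
  cat(sprintf(
    "<gdp_catalog> %d GDP(s) in %.1f s (rate %.4g Hz), threshold > %s\n",
    length(x$t_G), x$n_frames / x$frame_rate_hz, x$rate_hz,
    format(x$threshold)))
  invisible(x)
}

#' @export
summary.gdp_catalog <- function(object, ...) {
  igi <- object$igi_s
  cat(sprintf("GDPs: %d; rate: %.4g Hz\n", length(object$t_G), object$rate_hz))
  if (length(igi)) {
    cat(sprintf("IGI (s): median %.1f, IQR %.1f-%.1f, CV %.2f\n",
                median(igi), quantile(igi, 0.25), quantile(igi, 0.75),
                sd(igi) / mean(igi)))
  }
  cat(sprintf("participation: median %.0f cells\n",
              if (length(object$participants))
                median(lengths(object$participants)) else 0))
  invisible(object)
}
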