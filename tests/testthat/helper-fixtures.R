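# Small deterministic fixtures shared across test files.

# raster with given onset coordinates (1-based cell, 1-based frame)
make_raster <- function(n_cells, n_frames, coords = NULL, frame_rate_hz = 10) {
  m <- matrix(0L, n_cells, n_frames)
  if (!is.null(coords)) m[coords] <- 1L
  activity_raster(m, frame_rate_hz)
}

# independent Bernoulli raster at a per-frame probability
poisson_raster <- function(n_cells, n_frames, p, frame_rate_hz = 10,
                           seed = 1) {
  set.seed(seed)
  activity_raster(matrix(rbinom(n_cells * n_frames, 1L, p), n_cells),
                  frame_rate_hz)
}

# minimal gdp_catalog from peak times in seconds
make_catalog <- function(t_s, frame_rate_hz = 10, n_frames = NULL) {
  t_G <- as.integer(round(t_s * frame_rate_hz))
  structure(list(t_G = t_G, t_G_s = t_G / frame_rate_hz,
                 participants = vector("list", length(t_G)),
                 igi_frames = diff(t_G), igi_s = diff(t_G) / frame_rate_hz,
                 threshold = 0, frac_suprathreshold = NA_real_,
                 rate_hz = NA_real_, frame_rate_hz = frame_rate_hz,
                 n_frames = n_frames %||% (max(t_G) + 100L),
                 pctile = 99, n_surrogates = 0),
            class = "gdp_catalog")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal sce_catalog with given peak frames (0-based)
detect_sces_stub <- function(peak_frames, frame_rate_hz, n_frames) {
  structure(list(bins = seq_along(peak_frames),
                 bin_start_frames = as.integer(peak_frames),
                 peak_frames = as.integer(peak_frames),
                 n_coactive = rep(NA_integer_, length(peak_frames)),
                 participants = vector("list", length(peak_frames)),
                 threshold = NA_real_, frac_suprathreshold = NA_real_,
                 rate_hz = NA_real_, bin_sums = integer(),
                 bin_map = NULL, bin_s = 0.2, frames_per_bin = 2L,
                 frame_rate_hz = frame_rate_hz,
                 rest_duration_s = NA_real_, pctile = 99),
            class = "sce_catalog")
}
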