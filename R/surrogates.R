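#' Circular-shift surrogate of a raster or count matrix
#'
#' Rotates each row (cell) by an independent uniform offset, preserving every
#' cell's event count and autostructure while destroying cross-cell timing.
#' When the matrix has more than one column, offset 0 is excluded so that the
#' surrogate always differs from the data.
#'
#' @param x an [activity_raster()], or a numeric/integer matrix with one row
#'   per cell.
#' @param shifts optional integer vector of per-row offsets (recycled);
#'   overrides random draws.
#' @param seed optional integer seed for reproducible offsets.
#' @return same type as `x`, with an integer attribute `"shifts"`.
#' @examples
#' m <- matrix(1:12, 3)
#' s <- circular_shift(m, shifts = c(1, 2, 3))
#' rowSums(s) == rowSums(m)
#' @export
circular_shift <- function(x, shifts = NULL, seed = NULL) {
  is_raster <- inherits(x, "activity_raster")
  m <- if (is_raster) x$onsets else x
  if (!is.matrix(m)) stop("`x` must be a matrix or activity_raster")
  tt <- ncol(m)
  if (tt < 2L) stop("need at least 2 time points")
  nr <- nrow(m)
  if (is.null(shifts)) {
    shifts <- with_seed(seed, sample.int(tt - 1L, nr, replace = TRUE))
  } else {
    shifts <- rep_len(as.integer(shifts) %% tt, nr)
  }
  out <- m
  base <- seq_len(tt)
  for (i in seq_len(nr)) {
    s <- shifts[i]
    if (s != 0L) out[i, ] <- m[i, ((base - 1L - s) %% tt) + 1L]
  }
  res <- if (is_raster) {
    activity_raster(out, x$frame_rate_hz, cell_ids = x$cell_ids, tag = x$tag)
  } else out
  attr(res, "shifts") <- as.integer(shifts)
  res
}

# Rotate one sparse row given 0-based event positions; returns 0-based
# positions after a rotation by `s` frames to the right.
rotate_positions <- function(pos0, s, tt) (pos0 + s) %% tt

# Pooled distribution of per-frame (or per-bin) population sums over
# circular-shift surrogates, returned as a tabulated histogram over the sum
# values 0..max_sum. Works on 0-based event positions with weights.
surrogate_sum_histogram <- function(pos0, cell_of, weights, n_rows, tt,
                                    n_surrogates, max_sum) {
  hist <- numeric(max_sum + 1L)
  for (b in seq_len(n_surrogates)) {
    off <- sample.int(tt - 1L, n_rows, replace = TRUE)
    if (length(pos0)) {
      np <- (pos0 + off[cell_of]) %% tt
      sums <- rowsum(weights, np)
      s_tab <- tabulate(as.integer(sums) + 1L, nbins = max_sum + 1L)
      s_tab[1L] <- s_tab[1L] + (tt - nrow(sums))
    } else {
      s_tab <- c(tt, numeric(max_sum))
    }
    hist <- hist + s_tab
  }
  hist
}

# Left-continuous empirical quantile (smallest value v with CDF(v) >= p) from
# a histogram over integer values 0..length(hist)-1.
histogram_quantile <- function(hist, p) {
  cdf <- cumsum(hist) / sum(hist)
  which(cdf >= p)[1L] - 1L
}
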