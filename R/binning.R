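#' Bin a raster into fixed-width count windows
#'
#' Counts onsets in non-overlapping windows of `bin_ms`. Binning is
#' epoch-wise: when `restrict` is given, each epoch interval is tiled from its
#' start so that no bin straddles two epochs; trailing partial bins are
#' dropped. Per-cell counts are conserved over the binned range.
#'
#' @param r an [activity_raster()].
#' @param bin_ms bin width in milliseconds; at least one frame period.
#' @param restrict optional [epoch_set()] restricting the binning.
#' @return object of class `binned_raster`: list with `counts`
#'   (cells x bins integer matrix), `bin_map` (data.frame with 0-based
#'   `start_frame`, `end_frame` per bin), `frames_per_bin`, `bin_s`,
#'   `frame_rate_hz`.
#' @examples
#' r <- activity_raster(matrix(1L, 2, 10), 10)
#' bin_raster(r, 200)   # 5 bins of 2 frames
#' @export
bin_raster <- function(r, bin_ms, restrict = NULL) {
  stopifnot(inherits(r, "activity_raster"))
  frame_ms <- 1000 / r$frame_rate_hz
  if (bin_ms < frame_ms - 1e-9) {
    stop("`bin_ms` is smaller than one frame period")
  }
  fpb <- max(1L, as.integer(round(bin_ms / frame_ms)))
  iv <- if (is.null(restrict)) {
    matrix(c(0L, n_frames(r)), ncol = 2)
  } else {
    stopifnot(inherits(restrict, "epoch_set"))
    restrict$intervals
  }
  counts_l <- list(); map_l <- list()
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1]; e <- iv[i, 2]
    nb <- (e - s) %/% fpb
    if (nb == 0L) next
    cols <- (s + 1L):(s + nb * fpb)           # 1-based matrix columns
    grp <- rep(seq_len(nb), each = fpb)
    counts_l[[length(counts_l) + 1L]] <-
      t(rowsum(t(r$onsets[, cols, drop = FALSE]), grp, reorder = TRUE))
    map_l[[length(map_l) + 1L]] <- data.frame(
      start_frame = s + (seq_len(nb) - 1L) * fpb,
      end_frame = s + seq_len(nb) * fpb,
      epoch = i)
  }
  if (!length(counts_l)) {
    counts <- matrix(integer(), nrow = n_cells(r))
    bin_map <- data.frame(start_frame = integer(), end_frame = integer(),
                          epoch = integer())
  } else {
    counts <- do.call(cbind, counts_l)
    bin_map <- do.call(rbind, map_l)
    rownames(bin_map) <- NULL
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- NULL
  structure(list(counts = counts, bin_map = bin_map, frames_per_bin = fpb,
                 bin_s = fpb / r$frame_rate_hz,
                 frame_rate_hz = r$frame_rate_hz),
            class = "binned_raster")
}

#' @export
print.binned_raster <- function(x, ...) {
  cat(sprintf("<binned_raster> %d cells x %d bins (%d frames/bin, %.3g s)\n",
              nrow(x$counts), ncol(x$counts), x$frames_per_bin, x$bin_s))
  invisible(x)
}
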