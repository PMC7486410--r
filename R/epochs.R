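#' Construct an epoch set
#'
#' A labelled list of half-open frame intervals `[start, end)` in 0-based
#' frame coordinates. Intervals must be sorted, pairwise disjoint and lie
#' within `[0, n_frames)`.
#'
#' @param label epoch label, typically `"locomotion"` or `"rest"`.
#' @param intervals two-column matrix (or 2-vector) of 0-based half-open
#'   frame intervals; may have zero rows.
#' @param n_frames total number of frames in the recording.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(label, intervals, n_frames) {
  if (is.null(intervals) || length(intervals) == 0L) {
    intervals <- matrix(integer(), ncol = 2)
  }
  intervals <- matrix(as.integer(intervals), ncol = 2)
  colnames(intervals) <- c("start", "end")
  if (nrow(intervals)) {
    if (any(intervals[, 1] >= intervals[, 2])) stop("empty or reversed interval")
    if (any(intervals[, 1] < 0L) || any(intervals[, 2] > n_frames)) {
      stop("interval outside [0, n_frames)")
    }
    o <- order(intervals[, 1])
    intervals <- intervals[o, , drop = FALSE]
    if (nrow(intervals) > 1L &&
        any(intervals[-1, 1] < intervals[-nrow(intervals), 2])) {
      stop("overlapping intervals")
    }
  }
  structure(list(label = label, intervals = intervals,
                 n_frames = as.integer(n_frames)),
            class = "epoch_set")
}

# 0-based frame indices covered by the epoch set
epoch_frames <- function(e) {
  iv <- e$intervals
  if (!nrow(iv)) return(integer())
  unlist(lapply(seq_len(nrow(iv)),
                function(i) seq.int(iv[i, 1], iv[i, 2] - 1L)))
}

epoch_duration_s <- function(e, frame_rate_hz) {
  sum(e$intervals[, 2] - e$intervals[, 1]) / frame_rate_hz
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> '%s': %d interval(s), %d of %d frames\n",
              x$label, nrow(x$intervals),
              sum(x$intervals[, 2] - x$intervals[, 1]), x$n_frames))
  invisible(x)
}

#' Derive locomotion and rest epochs from a treadmill movement signal
#'
#' Locomotion epochs are maximal runs of frames with photo-sensor deflection
#' (any non-zero signal). Rest epochs are maximal movement-free runs strictly
#' longer than `min_rest_ms`; shorter movement-free gaps belong to neither
#' epoch set.
#'
#' @param movement per-frame movement signal: logical, or numeric where any
#'   non-zero deflection counts as movement.
#' @param frame_rate_hz frames per second.
#' @param min_rest_ms minimal duration (exclusive) for a movement-free run to
#'   count as rest, in milliseconds.
#' @return list with `epoch_set` elements `locomotion` and `rest`.
#' @examples
#' mv <- rep(c(0, 1, 0), c(30, 20, 50))
#' derive_epochs(mv, frame_rate_hz = 10)
#' @export
derive_epochs <- function(movement, frame_rate_hz, min_rest_ms = 200) {
  if (is.numeric(movement)) movement <- movement != 0
  if (!is.logical(movement)) stop("`movement` must be logical or numeric")
  if (anyNA(movement)) stop("`movement` contains NA")
  nf <- length(movement)
  if (nf == 0L) stop("empty movement signal")
  r <- rle(movement)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based starts
  loco <- cbind(starts, ends)[r$values, , drop = FALSE]
  still <- cbind(starts, ends)[!r$values, , drop = FALSE]
  # strict: a gap of exactly min_rest_ms is not rest
  keep <- (still[, 2] - still[, 1]) / frame_rate_hz * 1000 > min_rest_ms
  list(locomotion = epoch_set("locomotion", loco, nf),
       rest = epoch_set("rest", still[keep, , drop = FALSE], nf))
}

#' Write / read epoch sets as delimited text
#'
#' Columns `label,start_frame,end_frame` with half-open 0-based intervals.
#'
#' @param epochs a single `epoch_set` or a list of them.
#' @param path CSV file path.
#' @param n_frames recording length, needed when reading.
#' @export
write_epochs <- function(epochs, path) {
  if (inherits(epochs, "epoch_set")) epochs <- list(epochs)
  rows <- do.call(rbind, lapply(epochs, function(e) {
    if (!nrow(e$intervals)) return(NULL)
    data.frame(label = e$label, start_frame = e$intervals[, 1],
               end_frame = e$intervals[, 2])
  }))
  if (is.null(rows)) {
    rows <- data.frame(label = character(), start_frame = integer(),
                       end_frame = integer())
  }
  write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path, n_frames) {
  d <- read.table(path, sep = ",", header = TRUE)
  lapply(split(d, d$label), function(g) {
    epoch_set(g$label[1], cbind(g$start_frame, g$end_frame), n_frames)
  })
}
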