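#' Construct an activity raster
#'
#' The universal input of the pipeline: a binary onset/spike matrix with one
#' row per cell and one column per imaging frame, plus the acquisition frame
#' rate. Entries mark the frames at which a calcium-event onset (or inferred
#' spike) was detected for each cell.
#'
#' @param onsets binary matrix (cells x frames); logical or 0/1 numeric.
#' @param frame_rate_hz acquisition rate in frames per second (> 0).
#' @param cell_ids optional character vector of cell labels (defaults to
#'   `cell_1 ... cell_n`).
#' @param tag optional per-cell annotation (e.g. `"ebGABA"` vs `"ctrl"`);
#'   recycled if length 1.
#' @return an object of class `activity_raster`: a list with elements
#'   `onsets` (integer matrix), `frame_rate_hz`, `cell_ids`, `tag`.
#' @examples
#' r <- activity_raster(matrix(rbinom(50, 1, 0.1), 5), frame_rate_hz = 10)
#' r
#' @export
activity_raster <- function(onsets, frame_rate_hz, cell_ids = NULL, tag = NULL) {
  if (is.logical(onsets)) storage.mode(onsets) <- "integer"
  onsets <- as.matrix(onsets)
  if (!all(onsets %in% c(0L, 1L))) {
    stop("`onsets` must be binary (0/1)")
  }
  storage.mode(onsets) <- "integer"
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    stop("`frame_rate_hz` must be a single positive number")
  }
  n <- nrow(onsets)
  cell_ids <- cell_ids %||% paste0("cell_", seq_len(n))
  if (length(cell_ids) != n) stop("`cell_ids` must have one entry per cell")
  tag <- tag %||% rep(NA_character_, n)
  if (length(tag) == 1L) tag <- rep(tag, n)
  if (length(tag) != n) stop("`tag` must have one entry per cell")
  dimnames(onsets) <- NULL
  structure(
    list(onsets = onsets, frame_rate_hz = frame_rate_hz,
         cell_ids = as.character(cell_ids), tag = as.character(tag)),
    class = "activity_raster"
  )
}

n_cells <- function(r) nrow(r$onsets)
n_frames <- function(r) ncol(r$onsets)
raster_duration_s <- function(r) n_frames(r) / r$frame_rate_hz

#' @export
print.activity_raster <- function(x, ...) {
  cat(sprintf(
    "<activity_raster> %d cells x %d frames @ %.3g Hz (%.1f s), %d onsets\n",
    n_cells(x), n_frames(x), x$frame_rate_hz, raster_duration_s(x),
    sum(x$onsets)))
  tg <- x$tag[!is.na(x$tag)]
  if (length(tg)) {
    tb <- table(tg)
    cat("  tags:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / read a raster as delimited text with a JSON sidecar
#'
#' The matrix is stored as tab-separated 0/1 values (rows = cells, columns =
#' frames); `<path>.json` holds `frame_rate_hz`, `cell_ids` and `tag`.
#'
#' @param r an [activity_raster()].
#' @param path file path for the matrix; the sidecar is `<path>.json`.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns an
#'   `activity_raster`.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "activity_raster"))
  write.table(r$onsets, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  meta <- list(frame_rate_hz = r$frame_rate_hz, cell_ids = r$cell_ids,
               tag = r$tag)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tag <- meta$tag
  if (!is.null(tag)) tag[tag == "NA"] <- NA_character_
  activity_raster(m, meta$frame_rate_hz, cell_ids = meta$cell_ids, tag = tag)
}

#' Plot an activity raster
#'
#' Onsets as a dot raster over time with the population onset count below.
#'
#' @param x an [activity_raster()].
#' @param ... ignored.
#' @export
plot.activity_raster <- function(x, ...) {
  t_s <- (seq_len(n_frames(x)) - 1) / x$frame_rate_hz
  op <- par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(par(op))
  idx <- which(x$onsets == 1L, arr.ind = TRUE)
  plot(t_s[idx[, 2]], idx[, 1], pch = ".", cex = 2,
       xlab = "", ylab = "cell", xlim = range(t_s))
  plot(t_s, colSums(x$onsets), type = "h", xlab = "time (s)",
       ylab = "co-active cells")
  invisible(x)
}
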