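# Gaussian smoothing of each row with edge renormalization (kernel truncated
# at 3 SD; weights re-scaled near the edges so a constant row stays constant).
smooth_rows_gaussian <- function(m, sd_bins) {
  if (sd_bins <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sd_bins)))
  k <- dnorm(seq(-half, half), sd = sd_bins)
  k <- k / sum(k)
  nb <- ncol(m)
  pad <- function(x) c(rep(0, half), x, rep(0, half))
  w <- convolve(pad(rep(1, nb)), k, type = "filter")   # in-range weight mass
  t(apply(m, 1L, function(x) convolve(pad(x), k, type = "filter") / w))
}

# Symmetric fixed-point ICA (tanh contrast) on whitened data y (comps x obs).
# Returns the orthogonal unmixing matrix W (rows = components). The
# fixed-point iteration has mixing local optima, so several random restarts
# are run and the solution maximizing the log-cosh negentropy objective is
# kept. Deterministic given the caller's RNG state.
fastica_symmetric <- function(y, max_iter = 500, tol = 1e-9, n_restarts = 5) {
  m <- nrow(y); nb <- ncol(y)
  if (m == 1L) return(matrix(1, 1, 1))
  orthonormalize <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), m) %*%
      t(e$vectors) %*% w
  }
  e_logcosh_gauss <- 0.3745672976                  # E[log cosh Z], Z ~ N(0,1)
  best_w <- NULL; best_j <- -Inf
  for (r in seq_len(n_restarts)) {
    w <- orthonormalize(matrix(rnorm(m * m), m))
    for (it in seq_len(max_iter)) {
      wy <- w %*% y
      g <- tanh(wy)
      w_new <- g %*% t(y) / nb - diag(rowMeans(1 - g^2), m) %*% w
      w_new <- orthonormalize(w_new)
      delta <- max(abs(abs(rowSums(w_new * w)) - 1))
      w <- w_new
      if (delta < tol) break
    }
    j <- sum((rowMeans(log(cosh(w %*% y))) - e_logcosh_gauss)^2)
    if (j > best_j) { best_j <- j; best_w <- w }
  }
  best_w
}

#' Detect cell assemblies from rest-period co-activation
#'
#' Rest-restricted spike counts in `bin_ms` windows are Gaussian-smoothed and
#' z-scored per cell. The number of significant co-activation patterns is the
#' number of principal-component variances exceeding the maximum eigenvalue
#' observed across circularly shifted versions of the matrix; the patterns
#' themselves are then extracted with independent component analysis on the
#' data projected onto the significant principal subspace. Pattern weight
#' vectors have unit norm and are sign-aligned so that the largest-magnitude
#' weight is positive. Zero-variance cells are dropped (with a message) and
#' carry zero weight in the returned patterns.
#'
#' @param r an [activity_raster()].
#' @param rest rest [epoch_set()].
#' @param bin_ms count bin width (milliseconds).
#' @param kernel_sd_bins SD of the Gaussian smoothing kernel, in bins.
#' @param n_shuffles circular-shift matrices for the eigenvalue threshold.
#' @param seed optional integer seed (shuffles and ICA initialization).
#' @return object of class `assembly_set`: `n_significant`, `patterns`
#'   (cells x patterns, unit columns), `activities` (patterns x bins, the
#'   quadratic projections), `eigenvalues`, `eigen_threshold`, `zcounts`
#'   (the preprocessed matrix), `counts` (raw binned counts), `bin_map`,
#'   `bin_s`, `dropped_cells`, `underdetermined`.
#' @export
detect_assemblies <- function(r, rest, bin_ms = 200, kernel_sd_bins = 1,
                              n_shuffles = 500, seed = NULL) {
  stopifnot(inherits(r, "activity_raster"))
  if (n_cells(r) < 2L) stop("need at least 2 cells")
  br <- bin_raster(r, bin_ms, restrict = rest)
  nb <- ncol(br$counts)
  underdetermined <- nb < n_cells(r)
  if (underdetermined) {
    warning("fewer rest bins than cells: pattern count is under-determined")
  }
  sm <- smooth_rows_gaussian(br$counts, kernel_sd_bins)
  sdv <- apply(sm, 1L, sd)
  dropped <- which(!(sdv > 0))
  if (length(dropped)) {
    message(length(dropped), " zero-variance cell(s) dropped from assembly detection")
  }
  keep <- which(sdv > 0)
  z <- (sm[keep, , drop = FALSE] - rowMeans(sm[keep, , drop = FALSE])) /
    sdv[keep]
  nk <- length(keep)

  ev <- eigen(tcrossprod(z) / nb, symmetric = TRUE)
  res <- with_seed(seed, {
    lam_max <- vapply(seq_len(n_shuffles), function(s) {
      zs <- circular_shift(z)
      max(eigen(tcrossprod(zs) / nb, symmetric = TRUE,
                only.values = TRUE)$values)
    }, numeric(1))
    thr <- max(lam_max)
    n_sig <- sum(ev$values > thr)
    n_sig <- min(n_sig, nk, nb)
    patterns <- matrix(numeric(), n_cells(r), 0)
    activities <- matrix(numeric(), 0, nb)
    if (n_sig > 0L) {
      v <- ev$vectors[, seq_len(n_sig), drop = FALSE]
      lam <- ev$values[seq_len(n_sig)]
      y <- diag(1 / sqrt(lam), n_sig) %*% t(v) %*% z      # whitened projections
      w <- fastica_symmetric(y)
      pk <- v %*% diag(sqrt(lam), n_sig) %*% t(w)         # loadings, kept cells
      pk <- sweep(pk, 2L, sqrt(colSums(pk^2)), "/")
      flip <- apply(pk, 2L, function(col) sign(col[which.max(abs(col))]))
      pk <- sweep(pk, 2L, flip, "*")
      patterns <- matrix(0, n_cells(r), n_sig)
      patterns[keep, ] <- pk
      activities <- quadratic_projection(patterns[keep, , drop = FALSE], z)
    }
    list(thr = thr, n_sig = n_sig, patterns = patterns,
         activities = activities)
  })
  zfull <- matrix(0, n_cells(r), nb)
  zfull[keep, ] <- z
  structure(list(n_significant = res$n_sig, patterns = res$patterns,
                 activities = res$activities, eigenvalues = ev$values,
                 eigen_threshold = res$thr, zcounts = zfull,
                 counts = br$counts, bin_map = br$bin_map, bin_s = br$bin_s,
                 frame_rate_hz = r$frame_rate_hz, kept_cells = keep,
                 dropped_cells = dropped, underdetermined = underdetermined,
                 n_shuffles = n_shuffles),
            class = "assembly_set")
}

# R_k(t) = z(t)' P_k z(t) with P_k = w_k w_k' and zeroed diagonal
quadratic_projection <- function(patterns, z) {
  a <- t(patterns) %*% z            # w_k . z(t)
  d <- t(patterns^2) %*% z^2        # diagonal part
  a^2 - d
}

#' Assembly activity time series
#'
#' Projects each time bin of the z-scored count matrix onto an assembly
#' pattern through the pattern's outer-product projection matrix with zeroed
#' diagonal: `R_k(t) = z(t)' P_k z(t)`, `P_k = w_k w_k' - diag(w_k^2)`.
#' Removing the diagonal ensures a single cell cannot drive its own
#' assembly's activity.
#'
#' @param aset an [detect_assemblies()] result.
#' @param zcounts optional preprocessed matrix (cells x bins) from the same
#'   preprocessing as detection; defaults to the matrix stored in `aset`.
#' @return matrix (patterns x bins) of activities.
#' @export
compute_assembly_activity <- function(aset, zcounts = NULL) {
  stopifnot(inherits(aset, "assembly_set"))
  z <- zcounts %||% aset$zcounts
  if (nrow(z) != nrow(aset$patterns)) {
    stop("dimension mismatch between patterns and zcounts")
  }
  if (aset$n_significant == 0L) return(matrix(numeric(), 0, ncol(z)))
  quadratic_projection(aset$patterns, z)
}

#' @export
print.assembly_set <- function(x, ...) {
  cat(sprintf(
    "<assembly_set> %d significant pattern(s) over %d cells x %d bins (eigen threshold %.3g)\n",
    x$n_significant, nrow(x$zcounts), ncol(x$zcounts), x$eigen_threshold))
  invisible(x)
}

#' @export
summary.assembly_set <- function(object, ...) {
  print(object)
  if (object$n_significant > 0L) {
    for (k in seq_len(object$n_significant)) {
      top <- order(abs(object$patterns[, k]), decreasing = TRUE)[1:5]
      cat(sprintf("  pattern %d top cells: %s\n", k,
                  paste(top, collapse = ", ")))
    }
  }
  invisible(object)
}

#' Test per-cell modulation by assembly activity
#'
#' Cross-correlates each cell's binned spike counts with every assembly
#' activity over a +/- `window_s`/2 window (circularly, so circular-shift
#' surrogates are exactly exchangeable) and averages the correlograms across
#' assemblies. The per-cell threshold is the 95th percentile of the pooled
#' surrogate correlogram values obtained by circularly shifting the cell's
#' count vector. A cell is significantly modulated if at least two
#' consecutive of the five bins around zero lag exceed its threshold.
#'
#' @param r an [activity_raster()] (used only if `aset` lacks counts).
#' @param aset an [detect_assemblies()] result with `n_significant >= 1`.
#' @param window_s full correlogram window in seconds.
#' @param n_shuffles circular shifts per cell for the threshold.
#' @param seed optional integer seed.
#' @return object of class `assembly_modulation`: `mean_ccg` (cells x lags),
#'   `lags_s`, per-cell `threshold`, logical `significant` (NA when not
#'   assessable).
#' @export
test_assembly_modulation <- function(r, aset, window_s = 8,
                                     n_shuffles = 100, seed = NULL) {
  stopifnot(inherits(aset, "assembly_set"))
  counts <- aset$counts
  nc <- nrow(counts); nb <- ncol(counts)
  if (aset$n_significant == 0L) {
    return(structure(list(mean_ccg = NULL, lags_s = NULL,
                          threshold = rep(NA_real_, nc),
                          significant = rep(NA, nc)),
                     class = "assembly_modulation"))
  }
  nlag <- as.integer(round(window_s / 2 / aset$bin_s))
  act <- aset$activities
  # circular cross-correlation cell x all lags via FFT:
  # full[i, l+1] = mean_t counts[i, t] * act_k[(t + l) mod nb], avg over k
  fx <- mvfft(t(counts))
  fa <- mvfft(t(act))
  full <- matrix(0, nc, nb)
  for (k in seq_len(nrow(act))) {
    full <- full + t(Re(mvfft(Conj(fx) * fa[, k], inverse = TRUE))) / nb
  }
  full <- full / nrow(act) / nb       # mean over assemblies, mean over t
  lag_cols <- function(shift0) ((c(-(nlag:1), 0:nlag) + shift0) %% nb) + 1L
  mean_ccg <- full[, lag_cols(0L), drop = FALSE]
  offs <- with_seed(seed, matrix(
    sample.int(nb - 1L, nc * n_shuffles, replace = TRUE), nrow = nc))
  threshold <- vapply(seq_len(nc), function(i) {
    surr <- full[i, as.vector(vapply(offs[i, ], lag_cols,
                                     integer(2L * nlag + 1L)))]
    quantile(surr, 0.95, names = FALSE)
  }, numeric(1))
  central <- nlag + 1L + (-2L:2L)
  significant <- vapply(seq_len(nc), function(i) {
    has_consecutive(mean_ccg[i, central] > threshold[i], 2L)
  }, logical(1))
  structure(list(mean_ccg = mean_ccg,
                 lags_s = (-nlag:nlag) * aset$bin_s,
                 threshold = threshold, significant = significant),
            class = "assembly_modulation")
}

#' @export
print.assembly_modulation <- function(x, ...) {
  if (is.null(x$mean_ccg)) {
    cat("<assembly_modulation> not assessable (no significant assembly)\n")
  } else {
    cat(sprintf("<assembly_modulation> %d/%d cells assembly-modulated\n",
                sum(x$significant, na.rm = TRUE), length(x$significant)))
  }
  invisible(x)
}
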