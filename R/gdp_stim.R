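#' Test the effect of single-cell stimulation on GDP frequency
#'
#' For each protocol epoch (pre / stimulation / post), computes the windowed
#' average inter-GDP interval: starting from each GDP peak in the epoch, the
#' mean of the successive intervals between GDP peaks within a window of
#' `t_s_frames` frames, discarding windows that overlap an epoch boundary.
#' The three distributions are compared pairwise with Kolmogorov-Smirnov
#' tests. A slice is included only if the coefficient of variation of the
#' control (pre-epoch) inter-GDP interval does not exceed `cv_max`.
#'
#' @param cat a [detect_gdps()] catalog.
#' @param proto a [stimulation_protocol()].
#' @param t_s_frames window length in frames (300 or 400 in the recordings
#'   emulated).
#' @param alpha significance level for the KS tests.
#' @param cv_max maximal control-IGI coefficient of variation for inclusion.
#' @return object of class `gdp_frequency_test`: windowed IGI distributions
#'   per epoch, pairwise KS p-values, `classification` (`"increase"`,
#'   `"decrease"`, `"none"`, `"not assessable"` or `"excluded"`), `included`,
#'   and the control-IGI CV. "increase" means increased GDP frequency, i.e.
#'   stimulation-epoch median IGI below the control median.
#' @export
test_frequency_effect <- function(cat, proto, t_s_frames = 300,
                                  alpha = 0.05, cv_max = 1) {
  stopifnot(inherits(cat, "gdp_catalog"),
            inherits(proto, "stimulation_protocol"))
  fr <- cat$frame_rate_hz
  eps <- proto$epochs
  windowed <- lapply(eps, function(iv) {
    tg <- cat$t_G[cat$t_G >= iv[1] & cat$t_G < iv[2]]
    vals <- numeric()
    for (t0 in tg) {
      if (t0 + t_s_frames > iv[2]) next      # window overlaps epoch boundary
      win <- tg[tg >= t0 & tg <= t0 + t_s_frames]
      if (length(win) >= 2L) vals <- c(vals, mean(diff(win)) / fr)
    }
    vals
  })
  pre_tg <- cat$t_G[cat$t_G >= eps$pre[1] & cat$t_G < eps$pre[2]]
  cv_control <- if (length(pre_tg) >= 3L) {
    igi <- diff(pre_tg)
    sd(igi) / mean(igi)
  } else NA_real_

  res <- list(windowed = windowed, cv_control = cv_control,
              t_s_frames = t_s_frames, alpha = alpha,
              ks_p = c(pre_stim = NA_real_, stim_post = NA_real_,
                       pre_post = NA_real_))
  if (!is.na(cv_control) && cv_control > cv_max) {
    res$included <- FALSE
    res$classification <- "excluded"
    class(res) <- "gdp_frequency_test"
    return(res)
  }
  res$included <- TRUE
  if (any(lengths(windowed) < 2L)) {
    res$classification <- "not assessable"
    class(res) <- "gdp_frequency_test"
    return(res)
  }
  ksp <- function(a, b) suppressWarnings(ks.test(a, b)$p.value)
  res$ks_p <- c(pre_stim = ksp(windowed$pre, windowed$stim),
                stim_post = ksp(windowed$stim, windowed$post),
                pre_post = ksp(windowed$pre, windowed$post))
  res$classification <- if (res$ks_p[["pre_stim"]] < alpha) {
    if (median(windowed$stim) < median(windowed$pre)) "increase" else "decrease"
  } else "none"
  class(res) <- "gdp_frequency_test"
  res
}

#' @export
print.gdp_frequency_test <- function(x, ...) {
  cat(sprintf("<gdp_frequency_test> classification: %s (included: %s)\n",
              x$classification, x$included))
  if (!all(is.na(x$ks_p))) {
    cat(sprintf("  KS p: pre-stim %.3g, stim-post %.3g, pre-post %.3g\n",
                x$ks_p[1], x$ks_p[2], x$ks_p[3]))
  }
  invisible(x)
}

#' GDP phase series relative to the control rhythm
#'
#' Treats the control inter-GDP interval as the period of a harmonic
#' oscillator: the expected occurrence of the i-th GDP is `i * delta_t`, and
#' the phase of GDP i (in cycles) is `(t_i - i * delta_t) / delta_t`. A
#' recording is included only if the control-condition drift stays within
#' `max_drift_cycles` cycles.
#'
#' @param times a `gdp_catalog` or a numeric vector of GDP peak times in
#'   seconds.
#' @param delta_t_s reference period: the mean control inter-GDP interval in
#'   seconds (> 0).
#' @param control_idx indices of the GDPs belonging to the control condition
#'   (used for the drift-based inclusion flag); defaults to all.
#' @param max_drift_cycles inclusion bound on |phase| during control.
#' @return object of class `phase_series`: `phi` (cycles, one per GDP),
#'   `expected_s`, `delta_t_s`, `included`.
#' @examples
#' compute_phase_series(c(50, 100, 160), delta_t_s = 50)$phi
#' @export
compute_phase_series <- function(times, delta_t_s, control_idx = NULL,
                                 max_drift_cycles = 2) {
  if (inherits(times, "gdp_catalog")) times <- times$t_G_s
  if (!is.numeric(delta_t_s) || length(delta_t_s) != 1L ||
      !is.finite(delta_t_s) || delta_t_s <= 0) {
    stop("`delta_t_s` must be a single positive number")
  }
  i <- seq_along(times)
  expected <- i * delta_t_s
  phi <- (times - expected) / delta_t_s
  control_idx <- control_idx %||% i
  included <- !length(control_idx) ||
    max(abs(phi[control_idx])) <= max_drift_cycles
  structure(list(phi = phi, expected_s = expected, times_s = times,
                 delta_t_s = delta_t_s, included = included,
                 max_drift_cycles = max_drift_cycles),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf(
    "<phase_series> %d GDP(s), period %.3g s, drift range [%.2f, %.2f] cycles, included: %s\n",
    length(x$phi), x$delta_t_s,
    if (length(x$phi)) min(x$phi) else NA, if (length(x$phi)) max(x$phi) else NA,
    x$included))
  invisible(x)
}

#' Surrogate test for stimulation-locked GDP onsets
#'
#' Builds the average histogram (1-frame bins) of all cells' onsets across
#' the post-stimulation trials, normalized by the number of GDPs during the
#' stimulation epoch, and stores its highest peak. Surrogate data are the
#' concatenated control (pre) and post epochs — stimulation trials removed —
#' in which pseudo-stimulation trains with matched trial count, spacing and
#' length start at `n_surrogates` random frames; surrogate histograms use the
#' same normalizer so peak heights are directly comparable. Locking is
#' significant if the observed peak falls within the top 5% of surrogate
#' peaks.
#'
#' @param r an [activity_raster()].
#' @param proto a [stimulation_protocol()].
#' @param cat a [detect_gdps()] catalog (for the normalization counts).
#' @param n_surrogates number of pseudo-stimulation start frames.
#' @param trial_len_s trial length in seconds (2.5 or 5); defaults to the
#'   protocol's trial length.
#' @param seed optional integer seed.
#' @return object of class `locking_result`: `observed` peak height,
#'   `surrogate_peaks`, empirical `p` (fraction of surrogate peaks >=
#'   observed), `significant`, `latency_s` of the earliest maximal bin, and
#'   the trial histogram. If no GDP occurs during the stimulation epoch the
#'   result is flagged `assessable = FALSE`.
#' @export
test_gdp_locking <- function(r, proto, cat, n_surrogates = 100,
                             trial_len_s = NULL, seed = NULL) {
  stopifnot(inherits(r, "activity_raster"),
            inherits(proto, "stimulation_protocol"),
            inherits(cat, "gdp_catalog"))
  fr <- r$frame_rate_hz
  trial_len_s <- trial_len_s %||% (proto$trial_len_frames / fr)
  L <- as.integer(round(trial_len_s * fr))
  stim <- proto$stim_frames
  stim <- stim[stim + L <= n_frames(r)]
  if (!length(stim)) stop("no stimulation with a complete trial")

  se <- proto$epochs$stim
  n_gdp_stim <- sum(cat$t_G >= se[1] & cat$t_G < se[2])
  not_assessable <- structure(
    list(observed = NA_real_, surrogate_peaks = numeric(), p = NA_real_,
         significant = NA, latency_s = NA_real_, histogram = NULL,
         trial_len_s = trial_len_s, assessable = FALSE),
    class = "locking_result")
  if (n_gdp_stim == 0L) return(not_assessable)

  pop <- colSums(r$onsets)   # population onset count per frame
  trial_hist <- function(starts0, popv, n_gdp) {
    # mean across trials of the population onset count at each trial frame
    h <- numeric(L)
    for (s in starts0) h <- h + popv[(s + 1L):(s + L)]
    h / length(starts0) / n_gdp
  }
  h <- trial_hist(stim, pop, n_gdp_stim)
  observed <- max(h)
  latency_s <- (which.max(h) - 1L) / fr

  # surrogate segment: concatenated pre + post epochs
  seg0 <- c(seq.int(proto$epochs$pre[1], proto$epochs$pre[2] - 1L),
            seq.int(proto$epochs$post[1], proto$epochs$post[2] - 1L))
  pop_seg <- pop[seg0 + 1L]
  max_start <- length(pop_seg) - L
  if (max_start < 0L) return(not_assessable)
  # each surrogate uses arbitrary pseudo-stimulation frames: one independent
  # uniform start per trial, so surrogate peaks are exchangeable with the
  # observed peak under the null
  peaks <- with_seed(seed, vapply(seq_len(n_surrogates), function(b) {
    starts0 <- sample.int(max_start + 1L, length(stim), replace = TRUE) - 1L
    max(trial_hist(starts0, pop_seg, n_gdp_stim))
  }, numeric(1)))
  p <- mean(peaks >= observed)
  structure(list(observed = observed, surrogate_peaks = peaks, p = p,
                 significant = p < 0.05, latency_s = latency_s,
                 histogram = h, trial_len_s = trial_len_s,
                 assessable = TRUE),
            class = "locking_result")
}

#' @export
print.locking_result <- function(x, ...) {
  if (!x$assessable) {
    cat("<locking_result> not assessable (no GDP during stimulation)\n")
  } else {
    cat(sprintf(
      "<locking_result> peak %.4g at %.2f s, p = %.3g (%ssignificant)\n",
      x$observed, x$latency_s, x$p, if (isTRUE(x$significant)) "" else "not "))
  }
  invisible(x)
}
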