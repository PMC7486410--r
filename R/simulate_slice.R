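#' Hub-effect specifications for slice simulations
#'
#' `hub_none()` simulates a cell whose stimulation has no effect.
#' `hub_locking()` inserts an extra network burst after each stimulation with
#' probability `lock_prob`, at a latency drawn from
#' `Normal(latency_s, latency_sd_s)` — emulating a cell that locks burst
#' onset times. `hub_frequency()` multiplies the spontaneous burst rate during
#' the stimulation epoch — emulating a cell that changes burst frequency
#' (multiplier > 1 increases frequency, < 1 decreases it).
#'
#' @param latency_s mean stimulation-to-burst latency in seconds.
#' @param latency_sd_s latency jitter SD in seconds.
#' @param lock_prob probability that a stimulation triggers a burst.
#' @param multiplier rate multiplier applied during the stimulation epoch.
#' @return a list describing the effect, class `hub_effect`.
#' @export
hub_none <- function() structure(list(type = "none"), class = "hub_effect")

#' @rdname hub_none
#' @export
hub_locking <- function(latency_s = 2.2, latency_sd_s = 0.3, lock_prob = 0.9) {
  stopifnot(latency_s > 0, latency_sd_s >= 0,
            lock_prob >= 0, lock_prob <= 1)
  structure(list(type = "locking", latency_s = latency_s,
                 latency_sd_s = latency_sd_s, lock_prob = lock_prob),
            class = "hub_effect")
}

#' @rdname hub_none
#' @export
hub_frequency <- function(multiplier) {
  stopifnot(multiplier >= 0)
  structure(list(type = "frequency", multiplier = multiplier),
            class = "hub_effect")
}

#' Specification of a simulated developing-slice session
#'
#' Defaults emulate the recorded slice sessions: spontaneous network bursts
#' (GDPs) as a Poisson process at ~0.02 Hz recruiting most of the active
#' cells with small onset jitter, sparse asynchronous background onsets, and
#' a three-epoch single-cell stimulation protocol (pre / stimulation / post).
#'
#' @param n_cells number of imaged cells.
#' @param duration_s recording duration in seconds.
#' @param frame_rate_hz imaging rate (slice movies ran at roughly 7-12 Hz).
#' @param gdp_rate_hz spontaneous GDP rate (events/s).
#' @param gdp_participation probability that a cell joins a given GDP, in
#'   (0, 1].
#' @param gdp_jitter_frames SD of per-cell onset jitter around the GDP peak,
#'   in frames.
#' @param baseline_event_rate_hz per-cell asynchronous onset rate.
#' @param hub_effect a [hub_none()], [hub_locking()] or [hub_frequency()]
#'   specification of the stimulated cell's effect.
#' @param stim_rate_hz stimulation rate within the stimulation epoch (the
#'   protocol used 0.1, 0.2 or 0.4 Hz).
#' @param trial_len_s post-stimulation trial length in seconds (2.5 or 5).
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   session.
#' @return a validated list of class `slice_sim_spec`.
#' @export
slice_sim_spec <- function(n_cells = 100, duration_s = 900,
                           frame_rate_hz = 10, gdp_rate_hz = 0.02,
                           gdp_participation = 0.9, gdp_jitter_frames = 1,
                           baseline_event_rate_hz = 0.015,
                           hub_effect = hub_none(), stim_rate_hz = 0.1,
                           trial_len_s = 5, seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), duration_s = duration_s,
               frame_rate_hz = frame_rate_hz, gdp_rate_hz = gdp_rate_hz,
               gdp_participation = gdp_participation,
               gdp_jitter_frames = gdp_jitter_frames,
               baseline_event_rate_hz = baseline_event_rate_hz,
               hub_effect = hub_effect, stim_rate_hz = stim_rate_hz,
               trial_len_s = trial_len_s, seed = as.integer(seed))
  if (spec$n_cells < 1L) stop("invalid spec: need at least one cell")
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("invalid spec: non-positive duration")
  }
  if (!is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    stop("invalid spec: non-positive frame rate")
  }
  if (gdp_rate_hz < 0 || baseline_event_rate_hz < 0 || stim_rate_hz < 0) {
    stop("invalid spec: negative rate")
  }
  if (gdp_participation <= 0 || gdp_participation > 1) {
    stop("invalid spec: participation must be in (0, 1]")
  }
  if (duration_s * frame_rate_hz < 1) stop("invalid spec: less than one frame")
  if (!inherits(hub_effect, "hub_effect")) stop("invalid hub_effect")
  class(spec) <- "slice_sim_spec"
  spec
}

#' Construct a single-cell stimulation protocol
#'
#' @param stim_frames ordered 0-based frame indices of the stimulations.
#' @param trial_len_frames frames per post-stimulation trial.
#' @param epochs named list of half-open 0-based frame intervals `pre`,
#'   `stim`, `post` (each a length-2 vector).
#' @param stim_rate_hz nominal stimulation rate.
#' @param n_frames recording length (for validation).
#' @return list of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(stim_frames, trial_len_frames, epochs,
                                 stim_rate_hz = NA_real_, n_frames = NULL) {
  stim_frames <- sort(as.integer(stim_frames))
  stopifnot(all(c("pre", "stim", "post") %in% names(epochs)))
  se <- epochs$stim
  if (length(stim_frames) &&
      (any(stim_frames < se[1]) || any(stim_frames >= se[2]))) {
    stop("stimulation frames outside the stimulation epoch")
  }
  if (!is.null(n_frames) && length(stim_frames) &&
      max(stim_frames) + trial_len_frames > n_frames) {
    stop("trials extend past the end of the recording")
  }
  structure(list(stim_frames = stim_frames,
                 trial_len_frames = as.integer(trial_len_frames),
                 epochs = epochs, stim_rate_hz = stim_rate_hz),
            class = "stimulation_protocol")
}

#' Generate a simulated developing-slice session
#'
#' Spontaneous GDP peak times are drawn as a Poisson process; each GDP
#' recruits every cell independently with the participation probability, with
#' Gaussian onset jitter. Background onsets are homogeneous Poisson per cell,
#' thinned to one onset per frame (the raster is binary). The stimulation
#' protocol splits the recording into equal pre / stimulation / post epochs;
#' a `hub_locking` effect inserts stimulation-locked GDPs, a `hub_frequency`
#' effect rescales the GDP rate during the stimulation epoch.
#'
#' @param spec a [slice_sim_spec()].
#' @return list of class `slice_session` with elements `raster`
#'   ([activity_raster()]), `protocol` ([stimulation_protocol()]) and
#'   `ground_truth` (true GDP frames, inserted-vs-spontaneous split, effect).
#' @examples
#' s <- gen_slice_session(slice_sim_spec(n_cells = 20, duration_s = 300,
#'                                       seed = 7))
#' length(s$ground_truth$gdp_frames)
#' @export
gen_slice_session <- function(spec) {
  stopifnot(inherits(spec, "slice_sim_spec"))
  with_seed(spec$seed, {
    fr <- spec$frame_rate_hz
    tt <- as.integer(round(spec$duration_s * fr))
    third <- tt %/% 3L
    epochs <- list(pre = c(0L, third), stim = c(third, 2L * third),
                   post = c(2L * third, tt))

    # stimulation train inside the stim epoch, trials fully inside recording
    period <- max(1L, as.integer(round(fr / spec$stim_rate_hz)))
    trial_len <- as.integer(round(spec$trial_len_s * fr))
    stim <- seq.int(epochs$stim[1], epochs$stim[2] - 1L, by = period)
    stim <- stim[stim + trial_len <= tt]

    # spontaneous GDP times (Poisson), epoch-wise rate for frequency effects
    rate_mult <- c(1, 1, 1)
    if (spec$hub_effect$type == "frequency") {
      rate_mult[2] <- spec$hub_effect$multiplier
    }
    spont <- integer()
    bounds <- rbind(epochs$pre, epochs$stim, epochs$post)
    for (k in 1:3) {
      dur_k <- (bounds[k, 2] - bounds[k, 1]) / fr
      n_k <- rpois(1L, spec$gdp_rate_hz * rate_mult[k] * dur_k)
      if (n_k > 0L) {
        spont <- c(spont, bounds[k, 1] +
                     as.integer(floor(runif(n_k) * (bounds[k, 2] - bounds[k, 1]))))
      }
    }
    inserted <- integer()
    if (spec$hub_effect$type == "locking" && length(stim)) {
      hit <- runif(length(stim)) < spec$hub_effect$lock_prob
      lat <- rnorm(sum(hit), spec$hub_effect$latency_s,
                   spec$hub_effect$latency_sd_s)
      inserted <- stim[hit] + as.integer(round(lat * fr))
      inserted <- inserted[inserted >= 0L & inserted < tt]
    }
    gdp <- sort(unique(c(spont, inserted)))

    onsets <- matrix(0L, spec$n_cells, tt)
    for (g in gdp) {
      part <- which(runif(spec$n_cells) < spec$gdp_participation)
      if (!length(part)) next
      f <- g + as.integer(round(rnorm(length(part), 0, spec$gdp_jitter_frames)))
      ok <- f >= 0L & f < tt
      onsets[cbind(part[ok], f[ok] + 1L)] <- 1L
    }
    n_bg <- rpois(spec$n_cells, spec$baseline_event_rate_hz * tt / fr)
    for (i in which(n_bg > 0L)) {
      onsets[i, sample.int(tt, min(n_bg[i], tt))] <- 1L
    }

    raster <- activity_raster(onsets, fr)
    proto <- stimulation_protocol(stim, trial_len, epochs,
                                  spec$stim_rate_hz, n_frames = tt)
    gt <- list(gdp_frames = gdp, spontaneous_frames = sort(spont),
               inserted_frames = sort(inserted),
               effect = spec$hub_effect$type,
               effect_params = unclass(spec$hub_effect))
    structure(list(raster = raster, protocol = proto, ground_truth = gt),
              class = "slice_session")
  })
}
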