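#' Specification of a simulated head-fixed in vivo session
#'
#' Defaults emulate adult CA1 two-photon sessions: acquisition at 9.85 Hz,
#' 77-236 cells per field of view, self-paced alternation between locomotion
#' and rest, synchronous calcium events (SCEs) during rest at ~0.08 Hz,
#' recurring co-activation assemblies confined to single 200 ms windows, and
#' directed-lag "hub" cells whose spikes are followed by target spikes at a
#' fixed lag.
#'
#' @param n_cells number of cells.
#' @param duration_s session duration in seconds.
#' @param frame_rate_hz imaging rate (9.85 Hz in the recordings emulated).
#' @param locomotion_bout_s,rest_bout_s mean durations of the exponential
#'   locomotion/rest alternation.
#' @param loco_modulated_fraction fraction of cells whose rate is scaled
#'   during locomotion.
#' @param loco_rate_gain rate multiplier for locomotion-modulated cells
#'   during locomotion frames.
#' @param sce_rate_hz SCE rate during rest (events/s of rest time).
#' @param sce_participation probability that a cell joins a given SCE.
#' @param assemblies list of assemblies, each
#'   `list(members =, rate_hz =, member_prob =)`: member cell indices,
#'   activation rate during rest, and per-member activation probability.
#' @param hub_spec list of planted directed motifs, each
#'   `list(source =, targets =, lag_ms =, prob =, jitter_ms =)`: after every
#'   source spike each target fires with probability `prob` at
#'   `lag_ms + Normal(0, jitter_ms)`. Lags must lie within +/-1000 ms.
#' @param baseline_rate_hz per-cell background rate.
#' @param seed integer seed; same spec + seed gives a bit-identical session.
#' @return a validated list of class `invivo_sim_spec`.
#' @export
invivo_sim_spec <- function(n_cells = 150, duration_s = 600,
                            frame_rate_hz = 9.85, locomotion_bout_s = 10,
                            rest_bout_s = 30, loco_modulated_fraction = 0.3,
                            loco_rate_gain = 4, sce_rate_hz = 0.08,
                            sce_participation = 0.3, assemblies = list(),
                            hub_spec = list(), baseline_rate_hz = 0.05,
                            seed = 1L) {
  spec <- list(n_cells = as.integer(n_cells), duration_s = duration_s,
               frame_rate_hz = frame_rate_hz,
               locomotion_bout_s = locomotion_bout_s,
               rest_bout_s = rest_bout_s,
               loco_modulated_fraction = loco_modulated_fraction,
               loco_rate_gain = loco_rate_gain, sce_rate_hz = sce_rate_hz,
               sce_participation = sce_participation,
               assemblies = assemblies, hub_spec = hub_spec,
               baseline_rate_hz = baseline_rate_hz, seed = as.integer(seed))
  if (spec$n_cells < 1L) stop("invalid spec: need at least one cell")
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("invalid spec: non-positive duration")
  }
  if (!is.finite(frame_rate_hz) || frame_rate_hz <= 0) {
    stop("invalid spec: non-positive frame rate")
  }
  if (duration_s * frame_rate_hz < 1) stop("invalid spec: less than one frame")
  if (any(c(sce_rate_hz, baseline_rate_hz, loco_rate_gain) < 0)) {
    stop("invalid spec: negative rate")
  }
  if (loco_modulated_fraction < 0 || loco_modulated_fraction > 1) {
    stop("invalid spec: loco_modulated_fraction outside [0, 1]")
  }
  if (sce_participation < 0 || sce_participation > 1) {
    stop("invalid spec: sce_participation outside [0, 1]")
  }
  for (a in assemblies) {
    if (!all(a$members >= 1L & a$members <= n_cells)) {
      stop("invalid spec: assembly members outside the cell index range")
    }
    if (a$rate_hz < 0 || a$member_prob < 0 || a$member_prob > 1) {
      stop("invalid spec: bad assembly rate or probability")
    }
  }
  for (h in hub_spec) {
    if (!(h$source >= 1L && h$source <= n_cells) ||
        !all(h$targets >= 1L & h$targets <= n_cells)) {
      stop("invalid spec: hub cells outside the cell index range")
    }
    if (abs(h$lag_ms) > 1000) stop("invalid spec: hub lag outside +/-1000 ms")
    if (h$prob < 0 || h$prob > 1) stop("invalid spec: bad transmission prob")
  }
  class(spec) <- "invivo_sim_spec"
  spec
}

#' Generate a simulated in vivo session
#'
#' Locomotion and rest bouts alternate with exponential durations (rest bouts
#' are floored at 1 s, locomotion bouts at 0.3 s). Background spiking is
#' Bernoulli per frame at the baseline rate, scaled by `loco_rate_gain`
#' during locomotion for the modulated cells. SCEs occur only during rest,
#' at least 1 s away from rest-epoch boundaries and from each other; each SCE
#' places participant spikes in a single frame. Assembly activations place
#' joint member spikes in one frame (hence inside a single 200 ms analysis
#' bin). Hub motifs append target spikes after source spikes at the given lag
#' and transmission probability.
#'
#' @param spec an [invivo_sim_spec()].
#' @return list of class `invivo_session` with `raster`, `movement`
#'   (per-frame logical), `epochs` (list `locomotion`, `rest`) and
#'   `ground_truth` (modulated cells, SCE frames, assembly memberships and
#'   activation frames, planted directed edges).
#' @export
gen_invivo_session <- function(spec) {
  stopifnot(inherits(spec, "invivo_sim_spec"))
  with_seed(spec$seed, {
    fr <- spec$frame_rate_hz
    tt <- as.integer(round(spec$duration_s * fr))

    # exponential locomotion/rest alternation, starting at rest
    movement <- logical(tt)
    pos <- 0L; state_loco <- FALSE
    while (pos < tt) {
      dur_s <- if (state_loco) {
        max(0.3, rexp(1L, 1 / spec$locomotion_bout_s))
      } else {
        max(1.0, rexp(1L, 1 / spec$rest_bout_s))
      }
      len <- max(1L, as.integer(round(dur_s * fr)))
      end <- min(tt, pos + len)
      movement[(pos + 1L):end] <- state_loco
      pos <- end; state_loco <- !state_loco
    }
    ep <- derive_epochs(movement, fr)
    loco_frames0 <- epoch_frames(ep$locomotion)
    rest_iv <- ep$rest$intervals

    # background Bernoulli spiking with locomotion gain for modulated cells
    n_mod <- as.integer(round(spec$loco_modulated_fraction * spec$n_cells))
    mod_cells <- if (n_mod > 0L) sort(sample.int(spec$n_cells, n_mod)) else integer()
    p_base <- min(1, spec$baseline_rate_hz / fr)
    p_loco <- min(1, p_base * spec$loco_rate_gain)
    onsets <- matrix(rbinom(spec$n_cells * tt, 1L, p_base),
                     spec$n_cells, tt)
    if (length(mod_cells) && length(loco_frames0) && p_loco > p_base) {
      cols <- loco_frames0 + 1L
      onsets[mod_cells, cols] <-
        rbinom(length(mod_cells) * length(cols), 1L, p_loco)
    }

    # SCE frames: rest only, >= 1 s from rest-epoch edges, >= 1 s apart
    margin <- as.integer(ceiling(fr))
    eligible <- integer()
    for (i in seq_len(nrow(rest_iv))) {
      a <- rest_iv[i, 1] + margin; b <- rest_iv[i, 2] - 1L - margin
      if (b >= a) eligible <- c(eligible, seq.int(a, b))
    }
    rest_dur_s <- epoch_duration_s(ep$rest, fr)
    n_sce <- rpois(1L, spec$sce_rate_hz * rest_dur_s)
    sce_frames <- integer()
    if (n_sce > 0L && length(eligible)) {
      cand <- sort(sample(eligible, min(n_sce, length(eligible))))
      for (f in cand) {
        if (!length(sce_frames) || f - tail(sce_frames, 1L) >= margin) {
          sce_frames <- c(sce_frames, f)
        }
      }
      for (f in sce_frames) {
        part <- which(runif(spec$n_cells) < spec$sce_participation)
        onsets[part, f + 1L] <- 1L
      }
    }

    # assembly activations: all members in one frame of a rest epoch
    assembly_gt <- list()
    for (k in seq_along(spec$assemblies)) {
      a <- spec$assemblies[[k]]
      n_act <- rpois(1L, a$rate_hz * rest_dur_s)
      act <- if (n_act > 0L && length(eligible)) {
        sort(sample(eligible, min(n_act, length(eligible))))
      } else integer()
      for (f in act) {
        hit <- a$members[runif(length(a$members)) < a$member_prob]
        onsets[hit, f + 1L] <- 1L
      }
      assembly_gt[[k]] <- list(members = as.integer(a$members),
                               activation_frames = act)
    }

    # directed-lag hub motifs
    edges <- list()
    for (h in spec$hub_spec) {
      jit <- h$jitter_ms %||% 40
      src_frames <- which(onsets[h$source, ] == 1L) - 1L
      for (tg in h$targets) {
        if (length(src_frames)) {
          hit <- src_frames[runif(length(src_frames)) < h$prob]
          lag_f <- as.integer(round((h$lag_ms + rnorm(length(hit), 0, jit)) /
                                      1000 * fr))
          f <- hit + lag_f
          f <- f[f >= 0L & f < tt]
          onsets[tg, f + 1L] <- 1L
        }
        edges[[length(edges) + 1L]] <- data.frame(
          source = h$source, target = tg, lag_ms = h$lag_ms)
      }
    }
    edges <- if (length(edges)) do.call(rbind, edges) else
      data.frame(source = integer(), target = integer(), lag_ms = numeric())

    raster <- activity_raster(onsets, fr)
    gt <- list(loco_modulated_cells = mod_cells, sce_frames = sce_frames,
               assemblies = assembly_gt, edges = edges,
               hub_sources = vapply(spec$hub_spec, function(h)
                 as.integer(h$source), integer(1)))
    structure(list(raster = raster, movement = movement, epochs = ep,
                   ground_truth = gt),
              class = "invivo_session")
  })
}

#' Write a simulated session to plain-text files
#'
#' Writes `raster.tsv` (+ `raster.tsv.json` sidecar), `epochs.csv` (in vivo)
#' or `protocol.json` (slice), and `ground_truth.json` into `dir`.
#'
#' @param session a `slice_session` or `invivo_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(session$raster, file.path(dir, "raster.tsv"))
  if (inherits(session, "invivo_session")) {
    write_epochs(session$epochs, file.path(dir, "epochs.csv"))
  } else {
    jsonlite::write_json(unclass(session$protocol),
                         file.path(dir, "protocol.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(session$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
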