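# The sequential map-and-ablate loop: record electrograms, reconstruct the
# rotor, build its trajectory density map, ablate the density peak, repeat
# (up to three lesions), carrying the electrical state over continuously.

#' Default rotor-tracking persistence threshold for a catheter
#'
#' 8 mm for the 3 mm grid, 17 mm for the 6 mm grid, 20 mm for the basket.
#'
#' @param electrodes an \code{ElectrodeSet}.
#' @return threshold in mm.
#' @export
tracking_threshold <- function(electrodes) {
  top <- electrodes$topology
  if (top$kind == "BASKET") return(20)
  if (top$spacing <= 4.5) 8 else 17
}

#' Reconstruct rotor tracks from electrograms
#'
#' The catheter-side pipeline: sinusoidal recomposition, analytic-signal
#' phase, nearest-neighbor mapping onto the mesh (13 mm cutoff),
#' phase-singularity detection on frames downsampled to
#' \code{frame_rate_hz}, and greedy persistence tracking.
#'
#' @param egms an \code{EGMSet}.
#' @param mesh an \code{rb_mesh}.
#' @param cutoff nearest-neighbor mapping cutoff, mm.
#' @param frame_rate_hz singularity-detection frame rate.
#' @param threshold tracking threshold, mm (default from the catheter type).
#' @param gap_frames allowed unobserved frames inside a track.
#' @return list of \code{RotorTrack}s.
#' @export
reconstruct_tracks <- function(egms, mesh, cutoff = 13, frame_rate_hz = 100,
                               threshold = NULL, gap_frames = 1) {
  if (is.null(threshold)) threshold <- tracking_threshold(egms$electrodes)
  pt <- egm_phase(egms)
  mapped <- map_phase_to_mesh(pt, egms$electrodes, mesh, cutoff = cutoff)
  keep <- frame_indices(mapped$time, frame_rate_hz)
  ps <- detect_ps_frames(mapped$phase[, keep, drop = FALSE],
                         mapped$time[keep], mesh)
  track_ps(ps, threshold = threshold, gap_frames = gap_frames,
           times = mapped$time[keep])
}

#' Ground-truth rotor tracks from the transmembrane voltages
#'
#' Analytic-signal phase per node, singularity detection at
#' \code{frame_rate_hz}, persistence tracking with an 8 mm threshold.
#'
#' @param result a \code{SimulationResult}.
#' @param frame_rate_hz detection frame rate.
#' @param threshold tracking threshold, mm.
#' @param gap_frames allowed unobserved frames inside a track.
#' @return list of \code{RotorTrack}s.
#' @export
ground_truth_tracks <- function(result, frame_rate_hz = 100, threshold = 8,
                                gap_frames = 1) {
  pt <- ground_truth_phase(result)
  ph <- t(pt$phase)
  ph[!t(pt$valid)] <- NA_real_
  keep <- frame_indices(result$time, frame_rate_hz)
  ps <- detect_ps_frames(ph[, keep, drop = FALSE], result$time[keep],
                         result$mesh)
  track_ps(ps, threshold = threshold, gap_frames = gap_frames,
           times = result$time[keep])
}

frame_indices <- function(time, rate_hz) {
  dt <- time[2] - time[1]
  every <- max(1L, round(1000 / rate_hz / dt))
  seq(1L, length(time), by = every)
}

# TRUE when the recorded window shows reentry encircling the lesion: the
# ground-truth phase winds by ~2*pi around a node ring just outside the
# lesion rim in most late-window frames.
anchored_around <- function(result, center, radius, window_frac = 0.5) {
  mesh <- result$mesh
  center <- as.numeric(center)
  if (length(center) == 2) center <- c(center, 0)
  h <- mesh_edge_length(mesh)
  d <- sqrt(colSums((t(mesh$nodes) - center)^2))
  ring <- which(d > radius + 0.5 * h & d <= radius + 2.5 * h)
  if (length(ring) < 6) return(FALSE)
  # order ring nodes by angle in the best-fit plane around the center
  rel <- sweep(mesh$nodes[ring, , drop = FALSE], 2, center)
  sv <- svd(rel)
  ang <- atan2(rel %*% sv$v[, 2], rel %*% sv$v[, 1])
  ring <- ring[order(ang)]
  pt <- ground_truth_phase(result)
  ph <- t(pt$phase)
  ok <- t(pt$valid)
  n_t <- ncol(ph)
  frames <- seq(max(1, ceiling(n_t * (1 - window_frac))), n_t, by = 10)
  wind <- vapply(frames, function(f) {
    p <- ph[ring, f]
    if (any(!ok[ring, f])) return(NA_real_)
    sum(wrap_phase(diff(c(p, p[1]))))
  }, 0)
  wind <- wind[!is.na(wind)]
  if (!length(wind)) return(FALSE)
  mean(abs(wind) > pi) > 0.5
}

#' Run the sequential map-and-ablate protocol
#'
#' Repeats up to \code{max_ablations} times: (a) continue the simulation for
#' \code{record_ms}, recording electrograms with the given catheter; (b)
#' reconstruct rotor tracks from the electrograms; (c) build the trajectory
#' density map of the longest-lived track; (d) apply a circular lesion at
#' the density peak. The loop stops early when no target is found or when
#' activity terminates (no activation anywhere for \code{silence_ms}).
#' A final observation window classifies the outcome.
#'
#' @param mesh an \code{rb_mesh} carrying the reentrant substrate.
#' @param model the cell model of the running simulation.
#' @param state per-node state exhibiting sustained activity (e.g.
#'   \code{$state} of \code{\link{run_reentry_fixture}}'s result).
#' @param t0 simulation clock at protocol start, ms.
#' @param catheter a placed \code{ElectrodeSet}.
#' @param max_ablations lesion budget (default 3).
#' @param lesion_radius mm (default 7).
#' @param record_ms recording window per iteration (default 2000); the last
#'   window, recorded after the final lesion, doubles as the observation
#'   window for the outcome classification.
#' @param silence_ms no-activation span that defines termination.
#' @param frame_rate_hz,threshold passed to the reconstruction.
#' @param check_precondition require a sustained ground-truth rotor (a track
#'   living >= 50 percent of the first window) before ablating.
#' @return a \code{ProtocolReport}: list with \code{iterations},
#'   \code{status} ("TERMINATED", "SUSTAINED" or "NO_TARGET"),
#'   \code{anchored}, \code{final_mesh}, \code{final_state}, \code{config}.
#' @export
run_protocol <- function(mesh, model, state, t0, catheter,
                         max_ablations = 3, lesion_radius = 7,
                         record_ms = 2000,
                         silence_ms = 500, frame_rate_hz = 100,
                         threshold = NULL, check_precondition = TRUE) {
  stopifnot(max_ablations >= 0, lesion_radius > 0)
  iterations <- list()
  status <- NA_character_
  anchored <- FALSE
  t_clock <- t0
  empty_prot <- stimulus_protocol(list())
  n_done <- 0L
  last_lesion <- NULL
  repeat {
    run <- run_monodomain(mesh, model, empty_prot, duration_ms = record_ms,
                          init_state = state, t0 = t_clock)
    state <- run$state
    t_clock <- run$t_end
    if (check_precondition && n_done == 0L) {
      gt0 <- ground_truth_tracks(run, frame_rate_hz = frame_rate_hz)
      life <- if (length(gt0)) max(vapply(gt0, function(t) t$lifespan, 0)) else 0
      if (life < 0.5 * record_ms)
        stop("protocol error: no sustained activity in the first window")
    }
    if (is_terminated(run, silence_ms)) { status <- "TERMINATED"; break }
    gt <- ground_truth_tracks(run, frame_rate_hz = frame_rate_hz)
    if (n_done >= max_ablations) {
      status <- "SUSTAINED"
      if (!is.null(last_lesion))
        anchored <- anchored_around(run, last_lesion$center, last_lesion$radius)
      break
    }
    egms <- record_egms(run, catheter)
    tracks <- reconstruct_tracks(egms, mesh, frame_rate_hz = frame_rate_hz,
                                 threshold = threshold)
    if (!length(tracks)) { status <- "NO_TARGET"; break }
    target <- select_target(tracks)
    est_map <- density_map(target, mesh, window_ms = record_ms)
    gt_map <- if (length(gt))
      density_map(select_target(gt), mesh, window_ms = record_ms) else NULL
    err <- if (!is.null(gt_map)) peak_error(est_map, gt_map) else NA_real_
    mesh <- apply_circular_lesion(mesh, est_map$peak_position, lesion_radius)
    last_lesion <- list(center = est_map$peak_position, radius = lesion_radius)
    n_done <- n_done + 1L
    iterations[[n_done]] <- list(
      record_window = c(run$time[1], run$t_end),
      n_tracks = length(tracks),
      target_lifespan_ms = target$lifespan,
      density_peak = est_map$peak_position,
      gt_peak = if (!is.null(gt_map)) gt_map$peak_position else NULL,
      peak_error_mm = err,
      lesion = last_lesion)
  }
  structure(list(iterations = iterations, status = status,
                 anchored = anchored, final_mesh = mesh,
                 final_state = state, t_end = t_clock,
                 config = list(max_ablations = max_ablations,
                               lesion_radius = lesion_radius,
                               record_ms = record_ms,
                               silence_ms = silence_ms)),
            class = "rb_report")
}

# No node activates during the trailing silence_ms of the window.
is_terminated <- function(run, silence_ms = 500) {
  t_end <- run$time[length(run$time)]
  cnt <- count_activations(run, window = c(t_end - silence_ms, t_end))
  sum(cnt) == 0
}

#' @export
print.rb_report <- function(x, ...) {
  cat("<rb_report> ", length(x$iterations), " ablation(s), status ",
      x$status, if (x$anchored) " (anchored reentry)", "\n", sep = "")
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf("  #%d lesion at (%s) r=%g mm, peak error %.2f mm\n", i,
                paste(signif(it$lesion$center, 4), collapse = ", "),
                it$lesion$radius, it$peak_error_mm))
  }
  invisible(x)
}

#' Lesion-size sweep
#'
#' One single-ablation protocol run per radius, from identical initial
#' conditions, classifying the post-ablation behavior as ANCHORED (reentry
#' encircles the lesion), UNANCHORED (activity persists elsewhere) or
#' TERMINATED.
#'
#' @inheritParams run_protocol
#' @param radii lesion radii to test, mm.
#' @return data.frame with radius, status, anchored, class, peak_error_mm.
#' @export
lesion_size_sweep <- function(mesh, model, state, t0, catheter, radii,
                              record_ms = 2000, ...) {
  stopifnot(all(radii > 0))
  rows <- lapply(radii, function(r) {
    rep <- run_protocol(mesh, model, state, t0, catheter,
                        max_ablations = 1, lesion_radius = r,
                        record_ms = record_ms, ...)
    cls <- if (rep$status == "TERMINATED") "TERMINATED"
           else if (rep$anchored) "ANCHORED" else "UNANCHORED"
    err <- if (length(rep$iterations)) rep$iterations[[1]]$peak_error_mm else NA_real_
    data.frame(radius = r, status = rep$status, anchored = rep$anchored,
               class = cls, peak_error_mm = err)
  })
  do.call(rbind, rows)
}
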