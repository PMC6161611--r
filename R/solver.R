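# Monodomain solver on triangulated surfaces.
#
# Space: P1 finite elements with mass lumping; the anisotropic conductivity
# tensor per element is sigma_t*I + (sigma_l - sigma_t) f f', with f the
# fiber direction projected into the element plane. No-flux boundaries are
# the natural FEM boundary condition (sheet edges and hole rims).
# Time: operator splitting per step -- reaction first (Rush-Larsen for the
# gating states, forward Euler for the rest), then explicit diffusion.

# Conductivity (mS/m) to diffusivity (mm^2/ms): the lumped inverse of the
# surface-to-volume ratio times membrane capacitance. The default is chosen
# so the remodeled substrate (8.9 mS/m longitudinal) conducts at ~0.4 m/s
# along fibers with the default cell model.
DEFAULT_DIFFUSIVITY_SCALE <- 0.02

#' Assemble the anisotropic surface diffusion operator
#'
#' Builds the P1 stiffness matrix weighted by the per-element anisotropic
#' conductivity tensor and the lumped mass vector, and returns the explicit
#' diffusion operator \code{M^-1 (-K)} scaled to mm^2/ms.
#'
#' @param mesh an \code{rb_mesh}.
#' @param diffusivity_scale conversion from mS/m to mm^2/ms.
#' @return list with sparse \code{op} (n x n), stiffness \code{K} (in raw
#'   conductivity units, used for current sources) and lumped areas
#'   \code{mass} (mm^2 per node).
#' @export
assemble_diffusion <- function(mesh, diffusivity_scale = DEFAULT_DIFFUSIVITY_SCALE) {
  el <- mesh$elements
  p <- mesh$nodes
  m <- nrow(el)
  p1 <- p[el[, 1], , drop = FALSE]
  p2 <- p[el[, 2], , drop = FALSE]
  p3 <- p[el[, 3], , drop = FALSE]
  u <- p2 - p1
  w <- p3 - p1
  # local orthonormal frame per element
  e1 <- u / sqrt(rowSums(u^2))
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  two_area <- sqrt(rowSums(nrm^2))
  if (any(two_area <= 0)) stop("degenerate element in mesh")
  nrm <- nrm / two_area
  e2 <- cbind(nrm[, 2] * e1[, 3] - nrm[, 3] * e1[, 2],
              nrm[, 3] * e1[, 1] - nrm[, 1] * e1[, 3],
              nrm[, 1] * e1[, 2] - nrm[, 2] * e1[, 1])
  # 2D vertex coordinates
  x2 <- rowSums(u * e1); y2 <- rowSums(u * e2)   # vertex 2 (y2 == 0)
  x3 <- rowSums(w * e1); y3 <- rowSums(w * e2)   # vertex 3
  area <- two_area / 2
  # P1 basis gradients in the local frame: grad_i = rot90(opposite edge)/2A
  gx <- cbind(y2 - y3, y3, -y2) / two_area
  gy <- cbind(x3 - x2, -x3, x2) / two_area
  # fiber projected into the plane
  f1 <- rowSums(mesh$fiber * e1)
  f2 <- rowSums(mesh$fiber * e2)
  fn <- sqrt(f1^2 + f2^2)
  degen <- fn < 1e-8
  f1[degen] <- 1; f2[degen] <- 0; fn[degen] <- 1
  f1 <- f1 / fn; f2 <- f2 / fn
  dl <- mesh$sigma_l
  dt_ <- mesh$sigma_t
  # tensor D = dt I + (dl - dt) f f'
  dxx <- dt_ + (dl - dt_) * f1 * f1
  dxy <- (dl - dt_) * f1 * f2
  dyy <- dt_ + (dl - dt_) * f2 * f2
  # K_e[a,b] = A * grad_a' D grad_b
  ii <- jj <- vv <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    val <- area * (gx[, a] * (dxx * gx[, b] + dxy * gy[, b]) +
                   gy[, a] * (dxy * gx[, b] + dyy * gy[, b]))
    ii[[k]] <- el[, a]; jj[[k]] <- el[, b]; vv[[k]] <- val
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(nrow(p), nrow(p)))
  mass <- as.numeric(Matrix::sparseMatrix(i = as.vector(el),
                                          j = rep(1L, 3 * m),
                                          x = rep(area / 3, 3),
                                          dims = c(nrow(p), 1L)))
  mass_safe <- ifelse(mass > 0, mass, 1)
  op <- Matrix::Diagonal(x = -diffusivity_scale / mass_safe) %*% K
  list(op = methods::as(op, "CsparseMatrix"), K = K, mass = mass)
}

#' Stimulus protocol constructors
#'
#' A stimulus protocol is a list of stimuli, each a disc (center + radius in
#' mm) or an explicit node set, with onset and duration in ms and an
#' amplitude in cell-model units (added to dv/dt). A missing amplitude is
#' resolved at run time to the model default (2x diastolic threshold).
#'
#' @param stimuli list of stimuli from \code{stim_disc}/\code{stim_nodes}.
#' @return a \code{StimulusProtocol} list.
#' @export
stimulus_protocol <- function(stimuli = list()) {
  for (s in stimuli) {
    if (!is.null(s$duration) && s$duration <= 0) stop("stimulus duration must be > 0")
    if (!is.null(s$radius) && s$radius <= 0) stop("stimulus disc radius must be > 0")
  }
  structure(list(stimuli = stimuli), class = "rb_protocol")
}

#' @rdname stimulus_protocol
#' @param center,radius stimulation disc in mm.
#' @param onset,duration ms.
#' @param amplitude model units (NULL = 2x diastolic threshold).
#' @export
stim_disc <- function(center, radius, onset, duration = NULL, amplitude = NULL) {
  if (radius <= 0) stop("stimulus disc radius must be > 0")
  center <- as.numeric(center)
  if (length(center) == 2) center <- c(center, 0)
  list(kind = "disc", center = center, radius = radius, onset = onset,
       duration = duration, amplitude = amplitude)
}

#' @rdname stimulus_protocol
#' @param nodes integer vector of mesh node indices.
#' @export
stim_nodes <- function(nodes, onset, duration = NULL, amplitude = NULL) {
  list(kind = "nodes", nodes = as.integer(nodes), onset = onset,
       duration = duration, amplitude = amplitude)
}

#' Sinus-rhythm pacing protocol
#'
#' Two disc stimuli: one at the Bachmann-bundle insertion site and one at
#' the fossa ovalis, the second delayed by a physiological inter-site delay
#' (default 26 ms). A negative delay makes the fossa site fire first.
#'
#' @param bb_site,fo_site lists with \code{center} (mm) and \code{radius} (mm).
#' @param delay fossa onset minus Bachmann onset, ms.
#' @param onset onset of the Bachmann stimulus, ms.
#' @param duration,amplitude stimulus shape (NULL = model defaults).
#' @return a \code{StimulusProtocol}.
#' @export
sinus_protocol <- function(bb_site, fo_site, delay = 26, onset = 0,
                           duration = NULL, amplitude = NULL) {
  stimulus_protocol(list(
    stim_disc(bb_site$center, bb_site$radius, onset, duration, amplitude),
    stim_disc(fo_site$center, fo_site$radius, onset + delay, duration, amplitude)
  ))
}

resolve_stimuli <- function(protocol, mesh, model) {
  lapply(protocol$stimuli, function(s) {
    nodes <- if (s$kind == "disc") {
      d2 <- colSums((t(mesh$nodes) - s$center)^2)
      which(d2 <= s$radius^2)
    } else s$nodes
    if (!length(nodes)) warning("stimulus covers no mesh node")
    list(nodes = nodes, onset = s$onset,
         duration = if (is.null(s$duration)) model$stim_duration_ms else s$duration,
         amplitude = if (is.null(s$amplitude)) model$stim_amplitude else s$amplitude)
  })
}

#' Run a monodomain simulation
#'
#' Explicit operator-split monodomain integration on a triangulated surface
#' (reaction then diffusion per step). Deterministic: identical inputs give
#' bit-identical outputs.
#'
#' @param mesh an \code{rb_mesh} with conductivities set.
#' @param model a cell model (see \code{\link{mitchell_schaeffer_model}}).
#' @param protocol a \code{StimulusProtocol}; onsets are relative to the
#'   same clock as \code{t0}.
#' @param duration_ms simulated duration in ms.
#' @param dt_ms reaction-diffusion step (default: model recommendation).
#' @param output_rate_hz voltage output sampling rate (default 1 kHz).
#' @param init_state per-node state list (e.g. a previous run's
#'   \code{$state}) or NULL for the model rest state everywhere; a
#'   single-cell steady state is broadcast to all nodes.
#' @param t0 simulation clock at the first step (ms).
#' @param diffusion optional precomputed \code{\link{assemble_diffusion}}.
#' @param record if FALSE, only the final state is kept.
#' @return a \code{SimulationResult}: list with \code{time} (ms), \code{vm}
#'   (nodes x samples, mV), \code{state}, \code{mesh}, \code{dt_ms},
#'   \code{model_name}, \code{t_end}.
#' @export
run_monodomain <- function(mesh, model, protocol, duration_ms,
                           dt_ms = NULL, output_rate_hz = 1000,
                           init_state = NULL, t0 = 0,
                           diffusion = NULL, record = TRUE) {
  if (is.null(dt_ms)) dt_ms <- model$recommended_dt_ms
  if (dt_ms > model$recommended_dt_ms + 1e-12)
    stop("dt exceeds the model's recommended reaction step")
  n <- nrow(mesh$nodes)
  if (is.null(diffusion)) diffusion <- assemble_diffusion(mesh)
  op <- diffusion$op
  state <- if (is.null(init_state)) model$rest_state() else init_state
  state <- lapply(state, function(x) if (length(x) == 1) rep(x, n) else x)
  stopifnot(all(lengths(state) == n))
  stims <- resolve_stimuli(protocol, mesh, model)
  n_steps <- round(duration_ms / dt_ms)
  out_every <- max(1L, round(1000 / output_rate_hz / dt_ms))
  out_idx <- seq(0L, n_steps, by = out_every)
  vm <- if (record) matrix(NA_real_, n, length(out_idx)) else NULL
  if (record) vm[, 1] <- vm_to_mv(model, state$v)
  oi <- 1L
  zero_stim <- numeric(n)
  for (s in seq_len(n_steps)) {
    t <- t0 + (s - 1) * dt_ms
    i_stim <- zero_stim
    for (st in stims) {
      if (t >= st$onset && t < st$onset + st$duration)
        i_stim[st$nodes] <- i_stim[st$nodes] + st$amplitude
    }
    state <- model$step(state, dt_ms, i_stim)
    state$v <- state$v + dt_ms * as.numeric(op %*% state$v)
    if (s %% 200L == 0L || s == n_steps) {
      if (anyNA(state$v) || any(!is.finite(state$v))) {
        bad <- which(!is.finite(state$v))[1]
        stop("numerical instability at step ", s, " (t=", t + dt_ms,
             " ms), node ", bad)
      }
    }
    if (record && oi < length(out_idx) && s == out_idx[oi + 1L]) {
      oi <- oi + 1L
      vm[, oi] <- vm_to_mv(model, state$v)
    }
  }
  structure(list(
    time = t0 + out_idx * dt_ms,
    vm = vm,
    state = state,
    mesh = mesh,
    dt_ms = dt_ms,
    output_rate_hz = 1000 / (out_every * dt_ms),
    model_name = model$name,
    t_end = t0 + n_steps * dt_ms
  ), class = "rb_simulation")
}

#' @export
print.rb_simulation <- function(x, ...) {
  cat("<rb_simulation> ", nrow(x$mesh$nodes), " nodes, t = [",
      signif(x$time[1], 6), ", ", signif(x$t_end, 6), "] ms, dt = ",
      x$dt_ms, " ms\n", sep = "")
  invisible(x)
}

#' Count activations per node
#'
#' Upward crossings of the mid-repolarization level with a refractory
#' blanking, on the recorded voltage traces.
#'
#' @param result a simulation result (or any nodes-x-time mV matrix via
#'   \code{vm}/\code{time}).
#' @param vm,time optional explicit matrix and time grid.
#' @param threshold_mv crossing level; default midway between global min/max.
#' @param blank_ms refractory blanking between counted activations.
#' @param window optional c(t_from, t_to) restriction in ms.
#' @return integer vector of activation counts per node.
#' @export
count_activations <- function(result = NULL, vm = NULL, time = NULL,
                              threshold_mv = NULL, blank_ms = 40,
                              window = NULL) {
  if (is.null(vm)) { vm <- result$vm; time <- result$time }
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    vm <- vm[, keep, drop = FALSE]
    time <- time[keep]
  }
  if (ncol(vm) < 2) return(integer(nrow(vm)))
  if (is.null(threshold_mv)) threshold_mv <- (max(vm) + min(vm)) / 2
  dt <- time[2] - time[1]
  blank <- max(1L, round(blank_ms / dt))
  above <- vm > threshold_mv
  up <- above[, -1, drop = FALSE] & !above[, -ncol(above), drop = FALSE]
  counts <- integer(nrow(vm))
  for (i in seq_len(nrow(vm))) {
    w <- which(up[i, ])
    if (!length(w)) next
    last <- w[1]; cnt <- 1L
    for (x in w[-1]) if (x - last >= blank) { cnt <- cnt + 1L; last <- x }
    counts[i] <- cnt
  }
  counts
}

#' Induce reentry with an S1-S2 protocol
#'
#' Runs the S1 protocol, then scans the onset of a premature disc stimulus
#' (S2) over a time range, coarse-to-fine, and returns the earliest onset
#' whose continuation shows reentry: at least 3 activations (the S2 response
#' plus two full reactivations) at the S2 site within the probe window.
#' Candidates are screened with a short probe first (activity must outlive
#' the time a non-reentrant wave needs to clear the tissue) before the full
#' reactivation criterion is evaluated.
#'
#' @param mesh,model as \code{\link{run_monodomain}}.
#' @param s1_protocol the S1 \code{StimulusProtocol}.
#' @param s2_center,s2_radius premature-stimulus disc (radius default 5 mm).
#' @param s2_scan numeric c(from, to) onset range in ms.
#' @param coarse_ms,fine_ms scan resolutions.
#' @param probe_ms continuation length used to judge reentry.
#' @param quick_ms screening probe length; activity at its end is a
#'   necessary condition for reentry.
#' @param s2_duration,s2_amplitude premature-pulse shape; the default is a
#'   5 ms pulse at twice the default (already 2x-threshold) amplitude,
#'   strong enough to capture partially recovered tissue.
#' @param post_ms extra simulated time appended after a successful probe
#'   (the returned result covers s1 + probe + post).
#' @param dt_ms,diffusion passed through to the solver.
#' @return list with \code{result} (full \code{SimulationResult}),
#'   \code{s2_time} (chosen onset, NA if none), \code{reentry} (flag).
#' @export
induce_reentry <- function(mesh, model, s1_protocol, s2_center, s2_radius = 5,
                           s2_scan, coarse_ms = 10, fine_ms = 5,
                           probe_ms = 600, quick_ms = 350,
                           s2_duration = 5, s2_amplitude = NULL,
                           post_ms = 0, dt_ms = NULL, diffusion = NULL) {
  if (s2_radius <= 0) stop("s2_radius must be > 0")
  if (length(s2_scan) != 2 || s2_scan[2] < s2_scan[1])
    stop("empty S2 scan range")
  if (is.null(diffusion)) diffusion <- assemble_diffusion(mesh)
  if (is.null(s2_amplitude)) s2_amplitude <- 2 * model$stim_amplitude
  s2_center <- as.numeric(s2_center)
  if (length(s2_center) == 2) s2_center <- c(s2_center, 0)
  # base run: S1 only, up to the start of the scan window
  base <- run_monodomain(mesh, model, s1_protocol, duration_ms = s2_scan[1],
                         dt_ms = dt_ms, init_state = NULL,
                         diffusion = diffusion, record = FALSE)
  site_nodes <- which(colSums((t(mesh$nodes) - s2_center)^2) <= s2_radius^2)
  rest_mv <- vm_to_mv(model, model$rest_state()$v)
  active_mv <- rest_mv + 0.5 * model$v_amp_mv
  try_s2 <- function(t2, run_ms) {
    prot <- stimulus_protocol(c(s1_protocol$stimuli,
                                list(stim_disc(s2_center, s2_radius, t2,
                                               duration = s2_duration,
                                               amplitude = s2_amplitude))))
    run_monodomain(mesh, model, prot,
                   duration_ms = t2 - s2_scan[1] + run_ms,
                   dt_ms = dt_ms, init_state = base$state,
                   t0 = s2_scan[1], diffusion = diffusion, record = TRUE)
  }
  quick_ok <- function(run) any(run$vm[, ncol(run$vm)] > active_mv)
  full_ok <- function(run, t2) {
    cnt <- count_activations(run, window = c(t2, run$t_end))
    length(site_nodes) > 0 && stats::median(cnt[site_nodes]) >= 3 &&
      any(run$vm[, ncol(run$vm)] > active_mv)   # reentry must persist
  }
  test <- function(t2, extend_ms = 0) {
    q <- try_s2(t2, quick_ms)
    if (!quick_ok(q)) return(list(ok = FALSE, run = NULL))
    run <- try_s2(t2, probe_ms + extend_ms)
    list(ok = full_ok(run, t2), run = run)
  }
  candidates <- seq(s2_scan[1], s2_scan[2], by = coarse_ms)
  hit <- NA_real_
  for (t2 in candidates) {
    if (test(t2)$ok) { hit <- t2; break }
  }
  if (!is.na(hit) && fine_ms < coarse_ms && hit > candidates[1]) {
    for (t2 in seq(max(s2_scan[1], hit - coarse_ms + fine_ms), hit - fine_ms,
                   by = fine_ms)) {
      if (test(t2)$ok) { hit <- t2; break }
    }
  }
  if (is.na(hit))
    return(list(result = NULL, s2_time = NA_real_, reentry = FALSE))
  final <- try_s2(hit, probe_ms + post_ms)
  list(result = final, s2_time = hit, reentry = full_ok(final, hit))
}
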