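# Cell-model interface and the default phenomenological membrane model.
#
# A cell model is a plain list with fields:
#   name           identifier string
#   state_names    character vector; first state is always "v" (normalized)
#   rest_state()   named list of numeric scalars (the resting fixed point)
#   rates(state)   named list of time derivatives (1/ms), unstimulated
#   step(state, dt_ms, i_stim)  one reaction step, vectorized over nodes:
#                  gating states advance by their exact exponential
#                  (Rush-Larsen) update, the remaining states by forward
#                  Euler; i_stim adds to dv/dt in model units (1/ms)
#   recommended_dt_ms  largest stable reaction step
#   v_rest_mv, v_amp_mv  affine map from normalized v to millivolts
#   stim_amplitude  default stimulus amplitude (2x diastolic threshold)
#   stim_duration_ms  default stimulus duration

#' Two-variable phenomenological atrial cell model
#'
#' A Mitchell-Schaeffer-class excitable membrane with one voltage and one
#' recovery gate. The gate relaxes exponentially toward 1 (recovery, time
#' constant \code{tau_open}) below \code{v_gate} and toward 0 (inactivation,
#' \code{tau_close}) above it, so its update is closed-form (the Rush-Larsen
#' scheme); the voltage integrates by forward Euler. Default parameters give
#' an action-potential duration of roughly 130 ms and, on the remodeled
#' fixture sheet, a longitudinal conduction velocity in the 0.3-0.6 m/s
#' band -- a short-wavelength, AF-remodeled substrate.
#'
#' @param tau_in,tau_out,tau_open,tau_close,v_gate model time constants (ms)
#'   and gate threshold (normalized voltage).
#' @param v_rest_mv,v_amp_mv affine map from the normalized voltage to mV.
#' @param recommended_dt_ms largest reaction time step (ms).
#' @return a cell-model list (see package vignette).
#' @export
mitchell_schaeffer_model <- function(tau_in = 0.3, tau_out = 6,
                                     tau_open = 120, tau_close = 80,
                                     v_gate = 0.13,
                                     v_rest_mv = -85, v_amp_mv = 110,
                                     recommended_dt_ms = 0.1) {
  model <- list(
    name = "mitchell_schaeffer",
    state_names = c("v", "h"),
    pars = list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                tau_close = tau_close, v_gate = v_gate),
    v_rest_mv = v_rest_mv,
    v_amp_mv = v_amp_mv,
    recommended_dt_ms = recommended_dt_ms,
    stim_duration_ms = 2
  )
  model$rest_state <- function() list(v = 0, h = 1)
  model$rates <- function(state) {
    v <- state$v; h <- state$h
    open <- v < v_gate
    list(v = h * v * v * (1 - v) / tau_in - v / tau_out,
         h = ifelse(open, (1 - h) / tau_open, -h / tau_close))
  }
  model$step <- function(state, dt_ms, i_stim = 0) {
    v <- state$v; h <- state$h
    dv <- h * v * v * (1 - v) / tau_in - v / tau_out + i_stim
    closed <- v >= v_gate
    # Rush-Larsen: exact exponential relaxation of the gate
    e_open <- exp(-dt_ms / tau_open)
    e_close <- exp(-dt_ms / tau_close)
    h_new <- 1 + (h - 1) * e_open
    if (any(closed)) h_new[closed] <- (h * e_close)[closed]
    list(v = v + dt_ms * dv, h = h_new)
  }
  model$stim_amplitude <- 2 * diastolic_threshold(model)
  model
}

# mV <-> normalized voltage
vm_to_mv <- function(model, v) model$v_rest_mv + model$v_amp_mv * v

# Integrate a single cell (all states scalar) with a stimulus train.
# stim_onsets in ms; returns voltage trace in mV at dt resolution.
single_cell_run <- function(model, duration_ms, dt_ms = model$recommended_dt_ms,
                            stim_onsets = numeric(0),
                            stim_amplitude = model$stim_amplitude,
                            stim_duration = model$stim_duration_ms,
                            init_state = NULL) {
  n_steps <- round(duration_ms / dt_ms)
  state <- if (is.null(init_state)) model$rest_state() else init_state
  vm <- numeric(n_steps + 1)
  vm[1] <- vm_to_mv(model, state$v)
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt_ms
    i_stim <- if (length(stim_onsets) &&
                  any(t >= stim_onsets & t < stim_onsets + stim_duration))
      stim_amplitude else 0
    state <- model$step(state, dt_ms, i_stim)
    vm[s + 1] <- vm_to_mv(model, state$v)
  }
  list(time = seq(0, by = dt_ms, length.out = n_steps + 1), vm = vm,
       state = state)
}

# Smallest stimulus amplitude (2 ms pulse) that elicits an action potential
# from rest, found by bisection.
diastolic_threshold <- function(model, duration_ms = NULL, tol = 0.005) {
  if (is.null(duration_ms)) duration_ms <- model$stim_duration_ms
  fires <- function(amp) {
    r <- single_cell_run(model, 60, stim_onsets = 0, stim_amplitude = amp,
                         stim_duration = duration_ms)
    max(r$vm) > vm_to_mv(model, 0.7)
  }
  lo <- 0; hi <- 0.5
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 100) stop("protocol error: no action potential elicited at any amplitude")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

# APD90 of the last action potential in a single-cell mV trace.
apd90 <- function(time, vm) {
  rest <- min(vm)
  peak <- max(vm)
  if (peak - rest < 1) return(NA_real_)
  thr <- rest + 0.1 * (peak - rest)
  above <- vm > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  up <- which(runs$values)
  if (!length(up)) return(NA_real_)
  # last complete action potential
  k <- up[length(up)]
  if (ends[k] >= length(vm)) {
    up <- up[-length(up)]
    if (!length(up)) return(NA_real_)
    k <- up[length(up)]
  }
  time[ends[k]] - time[starts[k]]
}

#' Pace a single cell to steady state
#'
#' Paces one cell at a fixed basic cycle length until APD90 changes by less
#' than 1 ms between consecutive beats (or \code{max_beats} is reached) and
#' returns the limiting state, the standard initialization used before
#' tissue-level runs.
#'
#' @param model a cell model.
#' @param bcl basic cycle length in ms (default 800).
#' @param max_beats maximum number of pacing beats; 0 returns the rest state.
#' @param apd_tol convergence tolerance on APD90 (ms).
#' @return list with \code{state}, \code{beats}, \code{apd90},
#'   \code{converged}.
#' @export
init_steady_state <- function(model, bcl = 800, max_beats = 20, apd_tol = 1) {
  stopifnot(bcl > 0)
  state <- model$rest_state()
  if (max_beats == 0)
    return(list(state = state, beats = 0L, apd90 = NA_real_, converged = FALSE))
  prev_apd <- NA_real_
  apd <- NA_real_
  for (b in seq_len(max_beats)) {
    r <- single_cell_run(model, bcl, stim_onsets = 1, init_state = state)
    state <- r$state
    apd <- apd90(r$time, r$vm)
    if (is.na(apd))
      stop("protocol error: no action potential elicited (stimulus below threshold)")
    if (!is.na(prev_apd) && abs(apd - prev_apd) < apd_tol)
      return(list(state = state, beats = b, apd90 = apd, converged = TRUE))
    prev_apd <- apd
  }
  list(state = state, beats = max_beats, apd90 = apd, converged = FALSE)
}
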