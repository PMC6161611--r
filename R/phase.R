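# Signal-to-phase conversion: analytic-signal (Hilbert) phase for clean
# transmembrane traces, and sinusoidal recomposition for unipolar
# electrograms, whose sharp deflections make the raw Hilbert phase
# unusable for singularity analysis.

# Analytic signal by the frequency-domain construction: zero the negative
# frequencies, double the positive ones. x may be a vector or a
# samples-x-channels matrix; the mean is removed per channel first.
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  x <- sweep(x, 2, colMeans(x))
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

#' Analytic-signal phase of a trace
#'
#' Phase and amplitude of \code{x + j H\{x\}} with the channel mean removed
#' before the transform. The first and last 5 percent of the samples are
#' flagged invalid (transform edge effects), as are constant channels.
#'
#' @param trace numeric vector or samples-x-channels matrix.
#' @param time ms grid (uniform).
#' @param edge_frac fraction of samples invalidated at each end.
#' @return a \code{PhaseTrace}: list with \code{time}, \code{phase}
#'   (samples x channels, wrapped), \code{amplitude}, \code{valid}
#'   (samples x channels logical).
#' @export
hilbert_phase <- function(trace, time, edge_frac = 0.05) {
  trace <- as.matrix(trace)
  stopifnot(nrow(trace) == length(time))
  z <- analytic_signal(trace)
  phase <- atan2(Im(z), Re(z))
  amplitude <- Mod(z)
  valid <- matrix(TRUE, nrow(trace), ncol(trace))
  n_edge <- ceiling(edge_frac * nrow(trace))
  if (n_edge > 0) {
    valid[seq_len(n_edge), ] <- FALSE
    valid[nrow(trace) - seq_len(n_edge) + 1L, ] <- FALSE
  }
  flat <- apply(trace, 2, function(col) max(col) - min(col) < 1e-12)
  valid[, flat] <- FALSE
  structure(list(time = time, phase = phase, amplitude = amplitude,
                 valid = valid), class = "rb_phase")
}

#' Ground-truth phase from a simulation
#'
#' Applies the analytic-signal phase per node to the recorded transmembrane
#' voltages; resting (constant) nodes come back invalid.
#'
#' @param result a \code{SimulationResult}.
#' @return a \code{PhaseTrace} with one channel per mesh node.
#' @export
ground_truth_phase <- function(result) {
  hilbert_phase(t(result$vm), result$time)
}

#' Sinusoidal recomposition of an electrogram
#'
#' Replaces each detected activation (steep negative deflection) with one
#' cosine period at the local cycle length and sums the wavelets, yielding
#' a smooth oscillation whose analytic phase tracks local activation. An
#' activation at t_k with local cycle length T_k contributes
#' \code{|dV/dt|(t_k) * cos(2*pi*(t - t_k)/T_k - pi)} on
#' \code{[t_k - T_k/2, t_k + T_k/2]}.
#'
#' @param trace numeric vector (one electrogram).
#' @param time ms grid (uniform).
#' @param slope_frac activation threshold as a fraction of the most negative
#'   dV/dt (default 0.2).
#' @param blank_ms refractory blanking between detected activations.
#' @param cl_clamp_ms admissible local cycle-length range.
#' @return list with \code{recomposed} (numeric vector), \code{activations}
#'   (times, ms), \code{warning_flag} (TRUE when no activation was found).
#' @export
sinusoidal_recomposition <- function(trace, time, slope_frac = 0.2,
                                     blank_ms = 50,
                                     cl_clamp_ms = c(100, 400)) {
  n <- length(trace)
  stopifnot(length(time) == n, n >= 3)
  dt <- time[2] - time[1]
  dv <- c(0, diff(trace)) / dt
  thr <- slope_frac * min(dv)
  if (thr >= 0 || min(dv) >= -1e-12)
    return(list(recomposed = numeric(n), activations = numeric(0),
                warning_flag = TRUE))
  # local minima of dV/dt below threshold, with refractory blanking
  cand <- which(dv < thr)
  is_min <- cand[dv[cand] <= c(Inf, dv)[cand] & dv[cand] <= c(dv, Inf)[cand + 1L]]
  is_min <- is_min[order(time[is_min])]
  act <- integer(0)
  blank <- blank_ms / dt
  for (i in is_min) {
    if (!length(act) || i - act[length(act)] >= blank) {
      act <- c(act, i)
    } else if (dv[i] < dv[act[length(act)]]) {
      act[length(act)] <- i  # keep the steeper of two close deflections
    }
  }
  if (!length(act))
    return(list(recomposed = numeric(n), activations = numeric(0),
                warning_flag = TRUE))
  t_act <- time[act]
  out <- numeric(n)
  for (k in seq_along(act)) {
    gaps <- c(if (k > 1) t_act[k] - t_act[k - 1],
              if (k < length(act)) t_act[k + 1] - t_act[k])
    T_k <- if (length(gaps)) min(gaps) else mean(cl_clamp_ms)
    T_k <- min(max(T_k, cl_clamp_ms[1]), cl_clamp_ms[2])
    amp <- abs(dv[act[k]])
    sel <- time >= t_act[k] - T_k / 2 & time <= t_act[k] + T_k / 2
    out[sel] <- out[sel] + amp * cos(2 * pi * (time[sel] - t_act[k]) / T_k - pi)
  }
  list(recomposed = out, activations = t_act, warning_flag = FALSE)
}

#' Phase of an electrogram set
#'
#' Runs sinusoidal recomposition then analytic-signal phase on every
#' electrode channel; channels with no detected activations are invalid.
#'
#' @param egms an \code{EGMSet} from \code{\link{compute_egms}}.
#' @param ... passed to \code{\link{sinusoidal_recomposition}}.
#' @return a \code{PhaseTrace} (channels = electrodes).
#' @export
egm_phase <- function(egms, ...) {
  rec <- apply(egms$phi, 2, function(ch)
    sinusoidal_recomposition(ch, egms$time, ...)$recomposed)
  pt <- hilbert_phase(rec, egms$time)
  dead <- apply(rec, 2, function(col) max(abs(col)) < 1e-12)
  pt$valid[, dead] <- FALSE
  pt
}
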