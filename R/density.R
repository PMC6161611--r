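# Trajectory density maps: time-integrated, Gaussian-smoothed occupancy of
# the rotor tip over the mesh, peak-normalized; the peak is the ablation
# target and the peak-to-peak distance is the localization error.

#' Trajectory density map of a rotor track
#'
#' For every mesh node x_i sums f(||y(t_j) - x_i||) over the tip positions
#' y(t_j) falling in the integration window, with the Gaussian kernel
#' f(z) = exp(-z^2 / (2 sigma^2)), then rescales so the maximum is 1.
#' The window is anchored to the last \code{window_ms} of the track.
#'
#' @param track a \code{RotorTrack}.
#' @param mesh an \code{rb_mesh}.
#' @param sigma kernel width, mm (default 3).
#' @param window_ms integration interval length, ms (default 2000).
#' @return a \code{DensityMap}: list with \code{values} (per node, in
#'   [0, 1]), \code{peak_node}, \code{peak_position}, \code{normalization},
#'   \code{window}, \code{sigma}.
#' @export
density_map <- function(track, mesh, sigma = 3, window_ms = 2000) {
  stopifnot(sigma > 0)
  obs <- track$obs
  t_end <- max(obs$time_ms)
  window <- c(t_end - window_ms, t_end)
  obs <- obs[obs$time_ms >= window[1] & obs$time_ms <= window[2], , drop = FALSE]
  if (!nrow(obs)) stop("empty density map: no track observations in window")
  d <- cross_dist(mesh$nodes, cbind(obs$x, obs$y, obs$z))
  raw <- rowSums(exp(-d^2 / (2 * sigma^2)))
  A <- 1 / max(raw)
  values <- raw * A
  peak_node <- which.max(values)   # which.max: lowest index on ties
  structure(list(values = values, peak_node = peak_node,
                 peak_position = mesh$nodes[peak_node, ],
                 normalization = A, window = window, sigma = sigma),
            class = "rb_density")
}

#' @export
print.rb_density <- function(x, ...) {
  cat("<rb_density> peak at node ", x$peak_node, " (",
      paste(signif(x$peak_position, 4), collapse = ", "), ") mm; sigma ",
      x$sigma, " mm, window [", x$window[1], ", ", x$window[2], "] ms\n",
      sep = "")
  invisible(x)
}

#' Peak-to-peak localization error
#'
#' Euclidean distance in mm between the density peaks of an estimated and a
#' ground-truth map.
#'
#' @param estimated,ground_truth \code{DensityMap}s.
#' @return distance in mm.
#' @export
peak_error <- function(estimated, ground_truth) {
  if (is.null(estimated$peak_position) || is.null(ground_truth$peak_position))
    stop("empty density map")
  sqrt(sum((estimated$peak_position - ground_truth$peak_position)^2))
}
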