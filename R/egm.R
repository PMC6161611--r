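# Unipolar electrogram forward model: monopole superposition of the
# element-integrated transmembrane current sources in an unbounded volume
# conductor. Only relative amplitudes matter downstream (the pipeline uses
# phase), so the source scale is the raw conductivity-weighted diffusion
# operator.

#' Element-integrated transmembrane current sources
#'
#' Applies the discrete anisotropic diffusion operator (the FEM stiffness
#' matrix in raw conductivity units) to the recorded voltages, converts the
#' nodal integrated currents to densities via the lumped areas, and
#' distributes them to elements by area-weighted averaging of the three
#' vertex densities. On a closed lesion-free surface the element sources
#' sum to zero at every instant (discrete divergence theorem); elements
#' with zero conductivity are set to exactly zero.
#'
#' @param result a \code{SimulationResult} with recorded \code{vm}.
#' @param diffusion optional precomputed \code{\link{assemble_diffusion}}.
#' @return elements x samples matrix of source strengths (relative units).
#' @export
current_sources <- function(result, diffusion = NULL) {
  if (is.null(result$vm)) stop("simulation result has no recorded voltages")
  mesh <- result$mesh
  if (is.null(diffusion)) diffusion <- assemble_diffusion(mesh)
  nodal <- as.matrix(-diffusion$K %*% result$vm)     # integrated current per node
  dens <- nodal / ifelse(diffusion$mass > 0, diffusion$mass, 1)
  area <- mesh_areas(mesh)
  el <- mesh$elements
  src <- (dens[el[, 1], , drop = FALSE] + dens[el[, 2], , drop = FALSE] +
          dens[el[, 3], , drop = FALSE]) * (area / 3)
  src[mesh$sigma_l == 0 & mesh$sigma_t == 0, ] <- 0
  src
}

#' Forward-compute unipolar electrograms
#'
#' phi(x, t) = 1/(4 pi sigma) * sum_i I(x_i, t) / ||x_i - x|| over all wall
#' elements (x_i the element centroids), the unbounded-volume-conductor
#' monopole superposition; linear in the sources. Denominators below
#' \code{min_dist} mm are clamped (contact electrodes can coincide with
#' centroids). Output is decimated to \code{fs_hz}.
#'
#' @param sources elements x samples matrix from \code{\link{current_sources}}.
#' @param electrodes an \code{ElectrodeSet}.
#' @param mesh the \code{rb_mesh} the sources live on.
#' @param time ms grid of the source samples.
#' @param sigma_blood volume-conductor conductivity, S/m (default 0.7).
#' @param fs_hz output sampling rate (default 1000).
#' @param min_dist denominator clamp, mm.
#' @return an \code{EGMSet}: list with \code{time}, \code{phi}
#'   (samples x electrodes), \code{electrodes}, \code{sigma_blood}.
#' @export
compute_egms <- function(sources, electrodes, mesh, time,
                         sigma_blood = 0.7, fs_hz = 1000, min_dist = 0.5) {
  if (sigma_blood <= 0) stop("sigma_blood must be > 0")
  stopifnot(ncol(sources) == length(time))
  d <- cross_dist(electrodes$positions, mesh_centroids(mesh))
  d[d < min_dist] <- min_dist
  transfer <- (1 / (4 * pi * sigma_blood)) / d      # electrodes x elements
  # decimate (sample picking) to fs_hz
  if (length(time) > 1) {
    dt <- time[2] - time[1]
    every <- max(1L, round(1000 / fs_hz / dt))
    keep <- seq(1L, length(time), by = every)
  } else keep <- 1L
  phi <- t(transfer %*% sources[, keep, drop = FALSE])  # samples x electrodes
  structure(list(time = time[keep], phi = phi, electrodes = electrodes,
                 sigma_blood = sigma_blood), class = "rb_egms")
}

#' @export
print.rb_egms <- function(x, ...) {
  cat("<rb_egms> ", ncol(x$phi), " electrodes, ", nrow(x$phi),
      " samples @ ", round(1000 / diff(x$time[1:2])), " Hz\n", sep = "")
  invisible(x)
}

#' Record electrograms from a simulation
#'
#' Convenience chain: current sources -> monopole superposition at the
#' electrode positions -> 1 kHz decimation.
#'
#' @param result a \code{SimulationResult}.
#' @param electrodes an \code{ElectrodeSet}.
#' @param ... passed to \code{\link{compute_egms}}.
#' @export
record_egms <- function(result, electrodes, ...) {
  src <- current_sources(result)
  compute_egms(src, electrodes, result$mesh, result$time, ...)
}
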