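# Virtual radiofrequency lesions: elements inside the lesion footprint get
# zero conductivity (longitudinal and transverse) and the LESION label, which
# makes them transmural conduction blocks on the surface model.

#' Apply a circular ablation lesion
#'
#' Zeroes the conductivities of every element whose centroid lies within
#' \code{radius} mm (closed ball, 3D Euclidean) of \code{center} and labels
#' it LESION. Idempotent; warns when no element is affected.
#'
#' @param mesh an \code{rb_mesh}.
#' @param center numeric length-3 position in mm.
#' @param radius lesion radius in mm (default 7).
#' @return the modified mesh.
#' @export
apply_circular_lesion <- function(mesh, center, radius = 7) {
  stopifnot(radius > 0)
  center <- as.numeric(center)
  if (length(center) == 2) center <- c(center, 0)
  cc <- mesh_centroids(mesh)
  d <- sqrt(colSums((t(cc) - center)^2))
  hit <- d <= radius
  if (!any(hit)) {
    warning("circular lesion at (", paste(signif(center, 4), collapse = ", "),
            ") touches no element centroid")
    return(mesh)
  }
  zero_elements(mesh, hit)
}

#' Apply a linear ablation lesion
#'
#' Zeroes every element whose centroid lies within \code{half_width} mm of
#' the polyline (minimum point-to-segment distance over all segments). If
#' the resulting lesion is not edge-connected, the minimal half-width that
#' would make it contiguous is reported in a warning.
#'
#' @param mesh an \code{rb_mesh}.
#' @param polyline numeric matrix (>= 2 rows) of ordered mm positions.
#' @param half_width lesion half-width in mm.
#' @return the modified mesh.
#' @export
apply_linear_lesion <- function(mesh, polyline, half_width) {
  polyline <- as.matrix(polyline)
  if (ncol(polyline) == 2) polyline <- cbind(polyline, 0)
  if (nrow(polyline) < 2) stop("linear lesion requires a polyline with >= 2 points")
  stopifnot(half_width > 0)
  cc <- mesh_centroids(mesh)
  d <- dist_to_polyline(cc, polyline)
  hit <- d <= half_width
  if (!any(hit)) {
    warning("linear lesion touches no element centroid")
    return(mesh)
  }
  comp <- element_components(mesh, hit)
  if (max(comp) > 1L) {
    # minimal contiguity width: smallest w such that {d <= w} is connected
    cand <- sort(unique(d[d > half_width & d <= half_width + 5 * mesh_edge_length(mesh)]))
    w_ok <- NA_real_
    for (w in cand) {
      if (max(element_components(mesh, d <= w)) == 1L) { w_ok <- w; break }
    }
    warning("linear lesion is not contiguous at half_width = ", half_width,
            if (!is.na(w_ok)) paste0("; minimal contiguous half_width ~ ",
                                     signif(w_ok, 4)) else "")
  }
  zero_elements(mesh, hit)
}

zero_elements <- function(mesh, hit) {
  mesh$sigma_l[hit] <- 0
  mesh$sigma_t[hit] <- 0
  mesh$label[hit] <- "LESION"
  mesh
}

# Minimum distance from each point (rows of p) to a polyline (rows of poly).
dist_to_polyline <- function(p, poly) {
  best <- rep(Inf, nrow(p))
  for (s in seq_len(nrow(poly) - 1)) {
    a <- poly[s, ]; b <- poly[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    pa <- sweep(p, 2, a)
    tpar <- if (len2 == 0) rep(0, nrow(p)) else
      pmin(1, pmax(0, as.numeric(pa %*% ab) / len2))
    proj <- outer(tpar, ab)
    best <- pmin(best, sqrt(rowSums((pa - proj)^2)))
  }
  best
}
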