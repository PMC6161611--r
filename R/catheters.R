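# Virtual multi-electrode catheters: planar grid catheters placed against
# the wall at a controlled distance, and a spherical basket surrogate whose
# splines contract radially where the cavity is narrower than the basket.

#' Construct a planar grid catheter (local frame)
#'
#' n x n electrodes on a square lattice in the z = 0 plane, centered at the
#' origin; side length (n - 1) * spacing. The clinical setups are 9 x 9 at
#' 3 mm and 5 x 5 at 6 mm, both spanning a 24 x 24 mm patch.
#'
#' @param n electrodes per side (>= 2).
#' @param spacing inter-electrode distance, mm.
#' @return an \code{ElectrodeSet}: list with \code{positions} (mm),
#'   \code{labels}, \code{topology}, \code{wall_distance}.
#' @export
build_grid <- function(n, spacing) {
  if (n < 2) stop("grid needs at least 2 electrodes per side")
  stopifnot(spacing > 0)
  s <- (seq_len(n) - (n + 1) / 2) * spacing
  pos <- cbind(rep(s, times = n), rep(s, each = n), 0)
  labels <- paste0("R", rep(seq_len(n), each = n), "C", rep(seq_len(n), times = n))
  structure(list(positions = pos, labels = labels,
                 topology = list(kind = "GRID", n_rows = n, n_cols = n,
                                 spacing = spacing),
                 wall_distance = rep(NA_real_, n * n)),
            class = "rb_electrodes")
}

#' @export
print.rb_electrodes <- function(x, ...) {
  cat("<rb_electrodes> ", nrow(x$positions), " electrodes (",
      x$topology$kind, ")\n", sep = "")
  invisible(x)
}

#' Place a grid catheter on the wall
#'
#' Implements the plane-fit placement: (1) a least-squares plane through the
#' mesh nodes within \code{fit_radius} mm of \code{roi_center} defines a
#' local frame (two tangents, one normal oriented "inwards"); (2) the grid
#' is rigidly moved into that frame; (3) each electrode snaps to its closest
#' point on the triangulated surface; (4) all electrodes translate rigidly
#' by \code{wall_distance} along the inward normal.
#'
#' @param mesh an \code{rb_mesh}.
#' @param grid an \code{ElectrodeSet} from \code{\link{build_grid}}.
#' @param roi_center endocardial position, mm (within ~1 mm of a node).
#' @param wall_distance mm (clinical values 0/5/10/15).
#' @param fit_radius plane-fit neighborhood radius, mm.
#' @param inward optional length-3 vector fixing the inward normal sign
#'   (for open sheets, where "toward the cavity" is undefined); by default
#'   the normal points from the surface toward the cavity centroid.
#' @return the placed \code{ElectrodeSet} with recomputed wall distances.
#' @export
place_grid <- function(mesh, grid, roi_center, wall_distance = 0,
                       fit_radius = 5, inward = NULL) {
  stopifnot(wall_distance >= 0)
  roi_center <- as.numeric(roi_center)
  if (length(roi_center) == 2) roi_center <- c(roi_center, 0)
  d <- sqrt(colSums((t(mesh$nodes) - roi_center)^2))
  nb <- which(round(d, 6) <= fit_radius)   # tolerant: stable under rigid motion
  if (length(nb) < 3)
    stop("geometry error: fewer than 3 mesh nodes within ", fit_radius,
         " mm of roi_center")
  pts <- mesh$nodes[nb, , drop = FALSE]
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  nrm <- sv$v[, 3]
  if (is.null(inward)) {
    cavity <- colMeans(mesh$nodes)
    s <- sum(nrm * (cavity - ctr))
    if (abs(s) > 1e-9) nrm <- nrm * sign(s)
  } else {
    nrm <- nrm * sign(sum(nrm * inward))
  }
  # in-plane axes anchored to the neighborhood geometry (covariant under
  # rigid transforms even when the fit is rotationally degenerate): t1
  # points toward the farthest neighborhood node, projected into the plane
  dnb <- sqrt(colSums((t(mesh$nodes[nb, , drop = FALSE]) - ctr)^2))
  far <- nb[order(-round(dnb, 6), nb)]   # tolerant tie-break: stable under
                                         # rigid transforms of the mesh
  t1 <- NULL
  for (cand in far) {
    v <- mesh$nodes[cand, ] - ctr
    v <- v - nrm * sum(v * nrm)
    if (sqrt(sum(v^2)) > 1e-6) { t1 <- v / sqrt(sum(v^2)); break }
  }
  if (is.null(t1)) stop("geometry error: degenerate plane-fit neighborhood")
  t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
          nrm[3] * t1[1] - nrm[1] * t1[3],
          nrm[1] * t1[2] - nrm[2] * t1[1])
  # rigid move into the local frame
  pos <- grid$positions %*% rbind(t1, t2, nrm)
  pos <- sweep(pos, 2, roi_center, `+`)
  # snap to the surface, then offset along the inward normal
  pos <- t(apply(pos, 1, function(p) closest_point_on_surface(mesh, p)$point))
  pos <- sweep(pos, 2, wall_distance * nrm, `+`)
  grid$positions <- pos
  grid$frame <- list(t1 = t1, t2 = t2, normal = nrm, origin = roi_center)
  grid$wall_distance <- electrode_wall_distance(mesh, pos)
  grid
}

# Distance from each point to the nearest mesh node.
electrode_wall_distance <- function(mesh, positions) {
  d <- cross_dist(positions, mesh$nodes)
  apply(d, 1, min)
}

# Closest point on the triangulated surface to p (exact point-triangle
# projection over candidate triangles preselected by centroid distance).
closest_point_on_surface <- function(mesh, p, n_candidates = 40) {
  cc <- mesh_centroids(mesh)
  d2 <- colSums((t(cc) - p)^2)
  cand <- order(d2)[seq_len(min(n_candidates, nrow(cc)))]
  best <- NULL; bestd <- Inf
  for (e in cand) {
    el <- mesh$elements[e, ]
    q <- point_triangle_closest(p, mesh$nodes[el[1], ], mesh$nodes[el[2], ],
                                mesh$nodes[el[3], ])
    dd <- sum((q - p)^2)
    if (dd < bestd) { bestd <- dd; best <- q }
  }
  list(point = best, dist = sqrt(bestd))
}

# Ericson's closest-point-on-triangle.
point_triangle_closest <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * (d1 / (d1 - d3)))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * (d2 / (d2 - d6)))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c - b) * ((d4 - d3) / ((d4 - d3) + (d5 - d6))))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Place a basket catheter
#'
#' A simplified Constellation-style basket: splines are meridian arcs of a
#' sphere of the given diameter between the distal and proximal poles,
#' equally spaced in azimuth, with electrodes equally spaced in arc length
#' along each spline. Where the nominal sphere would exit the cavity, an
#' electrode is contracted radially (toward the basket center) to sit
#' \code{clearance} mm inside the wall; spline ordering is preserved.
#'
#' @param mesh a closed (cavity) \code{rb_mesh}.
#' @param diameter basket diameter, mm (default 48).
#' @param n_splines number of splines (default 8).
#' @param electrodes_per_spline electrodes per spline (default 8).
#' @param pole_axis distal-proximal axis direction.
#' @param center basket center, mm; must lie inside the cavity.
#' @param clearance minimal distance kept to the wall after contraction, mm.
#' @return an \code{ElectrodeSet} with spline labels A1..H8.
#' @export
place_basket <- function(mesh, diameter = 48, n_splines = 8,
                         electrodes_per_spline = 8,
                         pole_axis = c(0, 0, 1), center = c(0, 0, 0),
                         clearance = 1) {
  stopifnot(diameter > 0, n_splines >= 1, electrodes_per_spline >= 1)
  center <- as.numeric(center)
  r <- diameter / 2
  axis <- pole_axis / sqrt(sum(pole_axis^2))
  if (!point_inside_surface(mesh, center))
    stop("geometry error: basket center outside the cavity")
  # orthonormal frame around the pole axis
  seed_vec <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed_vec - axis * sum(seed_vec * axis)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  # electrodes equally spaced in polar angle (arc length) along meridians,
  # interior to the poles
  theta <- pi * (seq_len(electrodes_per_spline) - 0.5) / electrodes_per_spline
  phi <- 2 * pi * (seq_len(n_splines) - 1) / n_splines
  pos <- matrix(0, n_splines * electrodes_per_spline, 3)
  labels <- character(nrow(pos))
  k <- 0
  for (s in seq_len(n_splines)) {
    dir_t <- cos(phi[s]) * e1 + sin(phi[s]) * e2
    for (ei in seq_len(electrodes_per_spline)) {
      k <- k + 1
      u <- cos(theta[ei]) * axis + sin(theta[ei]) * dir_t
      p <- center + r * u
      # radial contraction where the sphere exits the cavity
      if (!point_inside_surface(mesh, p)) {
        lo <- 0; hi <- r
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          q <- center + mid * u
          if (point_inside_surface(mesh, q) &&
              closest_point_on_surface(mesh, q)$dist >= clearance) lo <- mid
          else hi <- mid
        }
        p <- center + lo * u
      }
      pos[k, ] <- p
      labels[k] <- paste0(LETTERS[s], ei)
    }
  }
  structure(list(positions = pos, labels = labels,
                 topology = list(kind = "BASKET", n_splines = n_splines,
                                 electrodes_per_spline = electrodes_per_spline,
                                 diameter = diameter),
                 wall_distance = electrode_wall_distance(mesh, pos)),
            class = "rb_electrodes")
}

# Inside test for a closed surface: sign of (p - q) . n at the closest
# surface point q, with n the outward element normal (meshes here are
# oriented outward).
point_inside_surface <- function(mesh, p) {
  cc <- mesh_centroids(mesh)
  e <- which.min(colSums((t(cc) - p)^2))
  el <- mesh$elements[e, ]
  u <- mesh$nodes[el[2], ] - mesh$nodes[el[1], ]
  w <- mesh$nodes[el[3], ] - mesh$nodes[el[1], ]
  nrm <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
  sum((p - cc[e, ]) * nrm) < 0
}
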