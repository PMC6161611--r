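# Seeded synthetic fixtures: sheets, cables, spheres, an ellipsoidal
# atrial surrogate with ostial holes, analytic vortex phase fields, and a
# reproducible spiral-wave (rotor) scenario. Everything is a pure function
# of its arguments and seed, so the whole pipeline is testable offline.

#' Flat triangulated sheet
#'
#' Regular nx x ny node lattice in the z = 0 plane, two triangles per cell,
#' consistent counter-clockwise orientation (normal +z), fibers along +x,
#' BULK labels, remodeled bulk conductivities.
#'
#' @param nx,ny node counts per side (>= 2).
#' @param spacing lattice spacing in mm.
#' @param sigma_l longitudinal conductivity, mS/m.
#' @param anisotropy conductivity ratio sigma_l / sigma_t.
#' @return an \code{rb_mesh}.
#' @export
make_sheet <- function(nx, ny, spacing = 1, sigma_l = DEFAULT_SIGMA_L,
                       anisotropy = DEFAULT_ANISOTROPY) {
  stopifnot(nx >= 2, ny >= 2, spacing > 0)
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx), 0)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  elements <- rbind(cbind(a, b, c), cbind(a, c, d))
  m <- nrow(elements)
  rb_mesh(nodes, elements,
          fiber = matrix(rep(c(1, 0, 0), each = m), m, 3),
          sigma_l = rep(sigma_l, m), sigma_t = rep(sigma_l / anisotropy, m))
}

#' Thin cable strip (1D conduction fixture)
#'
#' An n x 2 node strip of width one spacing, used for conduction-velocity
#' measurements and convergence checks.
#'
#' @inheritParams make_sheet
#' @param n nodes along the cable.
#' @export
make_cable <- function(n, spacing = 1, sigma_l = DEFAULT_SIGMA_L,
                       anisotropy = DEFAULT_ANISOTROPY) {
  make_sheet(n, 2, spacing, sigma_l, anisotropy)
}

# Icosphere of given radius, subdivided until the median edge is <=
# resolution. Returns nodes/elements with outward CCW orientation.
icosphere <- function(radius = 1, resolution = 0.3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  repeat {
    edge <- sqrt(sum((v[f[1, 1], ] - v[f[1, 2], ])^2)) * radius
    if (edge <= resolution || nrow(v) > 50000) break
    # subdivide: each triangle into four
    nv <- nrow(v)
    ekey <- new.env()
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- ekey[[k]]
      if (is.null(id)) {
        p <- (v[a, ] + v[b, ]) / 2
        p <- p / sqrt(sum(p^2))
        v <<- rbind(v, p)
        id <- nrow(v)
        ekey[[k]] <- id
      }
      id
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  list(nodes = v * radius, elements = f)
}

#' Closed sphere mesh
#'
#' @param radius mm.
#' @param resolution target median edge length, mm.
#' @inheritParams make_sheet
#' @export
make_sphere <- function(radius, resolution = radius / 8,
                        sigma_l = DEFAULT_SIGMA_L,
                        anisotropy = DEFAULT_ANISOTROPY) {
  ic <- icosphere(radius, resolution)
  m <- nrow(ic$elements)
  mesh <- rb_mesh(ic$nodes, ic$elements,
                  sigma_l = rep(sigma_l, m), sigma_t = rep(sigma_l / anisotropy, m))
  mesh
}

#' Ellipsoidal atrial surrogate
#'
#' A closed triangulated ellipsoid (default semi-axes 45 x 30 x 27.5 mm,
#' adult left-atrium scale) with optional circular holes standing in for
#' pulmonary-vein ostia and the mitral ring (open, no-flux boundaries).
#' Fibers run circumferentially around the long (x) axis.
#'
#' @param semi_axes numeric length-3, mm.
#' @param resolution target median edge length, mm.
#' @param holes list of lists with \code{center} (mm, on/near the surface),
#'   \code{radius} (mm) and optional \code{label} ("PV" or "MVR").
#' @inheritParams make_sheet
#' @export
make_ellipsoid_atrium <- function(semi_axes = c(45, 30, 27.5), resolution = 3,
                                  holes = list(),
                                  sigma_l = DEFAULT_SIGMA_L,
                                  anisotropy = DEFAULT_ANISOTROPY) {
  stopifnot(all(semi_axes > 0))
  ic <- icosphere(1, resolution / max(semi_axes))
  nodes <- sweep(ic$nodes, 2, semi_axes, `*`)
  elements <- ic$elements
  # circumferential fibers around the long axis (+x): at centroid (x,y,z),
  # direction ~ (0, -z, y) projected into the element plane
  cc <- (nodes[elements[, 1], ] + nodes[elements[, 2], ] + nodes[elements[, 3], ]) / 3
  fib <- cbind(0, -cc[, 3], cc[, 2])
  fn <- sqrt(rowSums(fib^2))
  degen <- fn < 1e-6
  fib[degen, ] <- matrix(rep(c(0, 1, 0), sum(degen)), ncol = 3, byrow = TRUE)
  fn[degen] <- 1
  fib <- fib / sqrt(rowSums(fib^2))
  # project into element planes and renormalize
  u <- nodes[elements[, 2], ] - nodes[elements[, 1], ]
  w <- nodes[elements[, 3], ] - nodes[elements[, 1], ]
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  fib <- fib - nrm * rowSums(fib * nrm)
  bad <- sqrt(rowSums(fib^2)) < 1e-6
  fib[bad, ] <- u[bad, , drop = FALSE]
  fib <- fib / sqrt(rowSums(fib^2))
  label <- rep("BULK", nrow(elements))
  keep <- rep(TRUE, nrow(elements))
  if (length(holes)) {
    ctrs <- do.call(rbind, lapply(holes, function(h) as.numeric(h$center)))
    for (hi in seq_along(holes)) {
      h <- holes[[hi]]
      d <- sqrt(colSums((t(cc) - as.numeric(h$center))^2))
      keep[d <= h$radius] <- FALSE
      rim <- d > h$radius & d <= h$radius + 2 * resolution
      label[rim] <- if (is.null(h$label)) "PV" else h$label
    }
  }
  elements <- elements[keep, , drop = FALSE]
  fib <- fib[keep, , drop = FALSE]
  label <- label[keep]
  # drop orphan nodes
  used <- sort(unique(as.vector(elements)))
  remap <- integer(nrow(nodes)); remap[used] <- seq_along(used)
  elements <- matrix(remap[elements], ncol = 3)
  nodes <- nodes[used, , drop = FALSE]
  m <- nrow(elements)
  rb_mesh(nodes, elements, fiber = fib, label = label,
          sigma_l = rep(sigma_l, m), sigma_t = rep(sigma_l / anisotropy, m))
}

#' Analytic vortex phase field
#'
#' Exact wrapped phase frames with singularities at prescribed centers, the
#' oracle input for phase-singularity detection and density tests. On flat
#' sheets each center contributes q_k * atan2(y - c_y, x - c_x). On closed
#' surfaces a single-valued field must carry zero total charge, so centers
#' are consumed as +1/-1 pairs, each contributing the azimuthal angle about
#' the axis through the pair (singular exactly at the two centers). The
#' whole field rotates at \code{omega}.
#'
#' @param mesh an \code{rb_mesh}.
#' @param centers k x 3 matrix of vortex centers (mm, on the surface).
#' @param charges integer vector in \{-1, +1\}; must sum to zero on closed
#'   meshes.
#' @param omega rotation rate, rad/s.
#' @param times_ms frame times.
#' @return nodes x frames matrix of wrapped phase in (-pi, pi].
#' @export
analytic_vortex_field <- function(mesh, centers, charges, omega = 0,
                                  times_ms = 0) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  stopifnot(all(charges %in% c(-1, 1)), nrow(centers) == length(charges))
  p <- mesh$nodes
  static <- numeric(nrow(p))
  closed <- nrow(mesh_boundary_edges(mesh)) == 0
  if (!closed) {
    for (k in seq_along(charges)) {
      ck <- centers[k, ]
      static <- static + charges[k] * atan2(p[, 2] - ck[2], p[, 1] - ck[1])
    }
  } else {
    if (sum(charges) != 0)
      stop("charges must sum to zero on a closed mesh")
    plus <- which(charges == 1)
    minus <- which(charges == -1)
    for (k in seq_along(plus)) {
      c1 <- centers[plus[k], ]; c2 <- centers[minus[k], ]
      d <- c2 - c1
      d <- d / sqrt(sum(d^2))
      seed_vec <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- seed_vec - d * sum(seed_vec * d)
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
              d[1] * e1[2] - d[2] * e1[1])
      rel <- sweep(p, 2, (c1 + c2) / 2)
      static <- static + atan2(rel %*% e2, rel %*% e1)
    }
  }
  out <- sapply(times_ms, function(tm) wrap_phase(static - omega * tm / 1000))
  matrix(out, nrow = nrow(p))
}

#' Seeded reentry scenario
#'
#' Returns a complete spiral-wave configuration: the mesh, the cell model,
#' the S1 protocol (a planar wave from the left edge), the premature S2
#' disc (center jittered by the seed) and the scan window used to find the
#' vulnerable S2 timing. \code{\link{run_reentry_fixture}} executes it.
#'
#' @param kind "SHEET_ROTOR" (an ATRIUM_ROTOR variant runs the same recipe
#'   on the ellipsoid surrogate).
#' @param seed integer seed controlling the S2 placement jitter.
#' @return a fixture configuration list.
#' @export
make_reentry_fixture <- function(kind = "SHEET_ROTOR", seed = 1) {
  if (!kind %in% c("SHEET_ROTOR", "ATRIUM_ROTOR"))
    stop("unknown reentry fixture kind: ", kind)
  set.seed(seed)
  model <- mitchell_schaeffer_model()
  n_attempts <- 4L
  if (kind == "SHEET_ROTOR") {
    mesh <- make_sheet(81, 81, 1, anisotropy = 4)
    jit <- matrix(stats::runif(2 * n_attempts, -4, 4), ncol = 2)
    s2_centers <- cbind(40 + jit[, 1], 52 + jit[, 2], 0)
    list(kind = kind, seed = seed, mesh = mesh, model = model,
         s1_protocol = stimulus_protocol(list(
           stim_nodes(which(mesh$nodes[, 1] < 1.5), onset = 1))),
         s2_centers = s2_centers, s2_radius = 5,
         s2_scan = c(240, 330), probe_ms = 1200)
  } else {
    mesh <- make_ellipsoid_atrium()
    jit <- matrix(stats::runif(2 * n_attempts, -4, 4), ncol = 2)
    p0 <- mesh$nodes[which.max(mesh$nodes[, 1]), ]
    list(kind = kind, seed = seed, mesh = mesh, model = model,
         s1_protocol = stimulus_protocol(list(
           stim_disc(p0, 5, onset = 1))),
         s2_centers = cbind(jit[, 1], jit[, 2], max(mesh$nodes[, 3]) * 0.9),
         s2_radius = 5, s2_scan = c(240, 330), probe_ms = 1200)
  }
}

#' Run a reentry fixture
#'
#' Performs the S1-S2 induction for a fixture configuration and continues
#' the successful run for \code{post_ms} more milliseconds (the recording
#' window of the downstream pipeline).
#'
#' @param fix a configuration from \code{\link{make_reentry_fixture}}.
#' @param post_ms extra simulated time after the induction probe.
#' @param dt_ms solver step override.
#' @return as \code{\link{induce_reentry}}, plus \code{digest}: rounded
#'   voltage checkpoints usable as a regression signature.
#' @export
run_reentry_fixture <- function(fix, post_ms = 2000, dt_ms = NULL) {
  diffusion <- assemble_diffusion(fix$mesh)
  for (a in seq_len(nrow(fix$s2_centers))) {
    ind <- induce_reentry(fix$mesh, fix$model, fix$s1_protocol,
                          s2_center = fix$s2_centers[a, ],
                          s2_radius = fix$s2_radius,
                          s2_scan = fix$s2_scan, probe_ms = fix$probe_ms,
                          post_ms = post_ms, dt_ms = dt_ms,
                          diffusion = diffusion)
    ind$s2_center <- fix$s2_centers[a, ]
    if (ind$reentry) break
  }
  if (ind$reentry) {
    vm <- ind$result$vm
    chk_t <- round(seq(1, ncol(vm), length.out = 5))
    chk_n <- round(seq(1, nrow(vm), length.out = 7))
    ind$digest <- round(c(vm[chk_n, chk_t]), 6)
  }
  ind
}
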