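# Phase-singularity detection and rotor tracking on the mesh.
#
# Electrode phases are pushed onto the mesh by nearest-neighbor assignment
# (no interpolation, 13 mm cutoff); singularities are found as elementary
# closed loops (ordered one-rings of interior nodes) whose wrapped phase
# differences wind by +-2*pi, contain one jump of at least pi, and are
# otherwise monotone.

#' Map electrode phases onto mesh nodes
#'
#' Each mesh node takes the phase of its nearest electrode if that electrode
#' lies within \code{cutoff} mm (Euclidean); farther nodes, and samples where
#' the electrode channel is invalid, are NA.
#'
#' @param phase_trace a \code{PhaseTrace} with one channel per electrode.
#' @param electrodes an \code{ElectrodeSet}.
#' @param mesh an \code{rb_mesh}.
#' @param cutoff mm (default 13).
#' @return list with \code{phase} (nodes x samples, NA = masked) and
#'   \code{time}.
#' @export
map_phase_to_mesh <- function(phase_trace, electrodes, mesh, cutoff = 13) {
  d <- cross_dist(mesh$nodes, electrodes$positions)
  nearest <- max.col(-d, ties.method = "first")
  mind <- d[cbind(seq_len(nrow(d)), nearest)]
  masked <- mind > cutoff
  ph <- t(phase_trace$phase)[nearest, , drop = FALSE]     # nodes x samples
  ok <- t(phase_trace$valid)[nearest, , drop = FALSE]
  ph[!ok] <- NA_real_
  ph[masked, ] <- NA_real_
  if (all(masked)) warning("all mesh nodes farther than the cutoff; output fully masked")
  list(phase = ph, time = phase_trace$time)
}

# Ordered one-ring loops around interior nodes. Triangles must be
# consistently oriented; the ring inherits that orientation, so winding
# sign equals topological charge. Returns a flattened edge representation:
# from/to node ids, loop id per edge, center node and ring-node list per loop.
node_one_rings <- function(mesh) {
  el <- mesh$elements
  n <- nrow(mesh$nodes)
  # directed opposite edge per (triangle, vertex)
  inc <- vector("list", n)
  for (v in 1:3) {
    a <- el[, (v %% 3) + 1L]
    b <- el[, ((v + 1L) %% 3) + 1L]
    ctr <- el[, v]
    sp <- split(seq_len(nrow(el)), ctr)
    for (nm in names(sp)) {
      i <- as.integer(nm)
      inc[[i]] <- rbind(inc[[i]], cbind(a[sp[[nm]]], b[sp[[nm]]]))
    }
  }
  loops <- vector("list", n)
  for (i in seq_len(n)) {
    ed <- inc[[i]]
    if (is.null(ed) || nrow(ed) < 3) next
    nxt <- stats::setNames(ed[, 2], ed[, 1])
    if (anyDuplicated(ed[, 1])) next          # non-manifold
    start <- ed[1, 1]
    ring <- start
    cur <- start
    closed <- FALSE
    for (s in seq_len(nrow(ed))) {
      nx <- nxt[as.character(cur)]
      if (is.na(nx)) break
      if (nx == start) { closed <- length(ring) == nrow(ed); break }
      ring <- c(ring, nx)
      cur <- nx
    }
    if (closed) loops[[i]] <- as.integer(ring)
  }
  centers <- which(!vapply(loops, is.null, TRUE))
  loops <- loops[centers]
  sizes <- lengths(loops)
  from <- unlist(loops)
  to <- unlist(lapply(loops, function(r) c(r[-1], r[1])))
  list(center = centers, loops = loops,
       from = from, to = to,
       loop_id = rep(seq_along(loops), sizes),
       n_loops = length(loops),
       centroid = do.call(rbind, lapply(loops, function(r)
         colMeans(mesh$nodes[r, , drop = FALSE]))))
}

#' Detect phase singularities in one phase frame
#'
#' Scans every elementary closed loop (the ordered one-ring of each interior
#' node, all nodes unmasked) for a wrapped-phase winding of +-2*pi with at
#' least one raw jump of magnitude >= pi and monotone remaining steps.
#' Detections closer than \code{merge_dist} with equal charge are merged at
#' their mean position.
#'
#' @param phases numeric vector of wrapped node phases (NA = masked).
#' @param mesh an \code{rb_mesh}.
#' @param rings precomputed \code{node_one_rings(mesh)} (built if NULL).
#' @param merge_dist mm; default one median element diameter.
#' @param mono_tol tolerance on the monotonicity of non-jump steps.
#' @return data.frame with columns x, y, z, charge (possibly 0 rows).
#' @export
detect_ps <- function(phases, mesh, rings = NULL, merge_dist = NULL,
                      mono_tol = 1e-9) {
  if (is.null(rings)) rings <- node_one_rings(mesh)
  if (is.null(merge_dist)) merge_dist <- 2 * mesh_edge_length(mesh)
  raw <- phases[rings$to] - phases[rings$from]
  wr <- wrap_phase(raw)
  bad <- is.na(raw)
  wr0 <- ifelse(bad, 0, wr)
  g <- rings$loop_id
  nl <- rings$n_loops
  winding <- rowsum_vec(wr0, g, nl)
  any_na <- rowsum_vec(as.numeric(bad), g, nl) > 0
  jump <- rowsum_vec(as.numeric(abs(raw) >= pi - 1e-12), g, nl) >= 1
  pos_bad <- rowsum_vec(as.numeric(!bad & wr < -mono_tol), g, nl)
  neg_bad <- rowsum_vec(as.numeric(!bad & wr > mono_tol), g, nl)
  plus <- !any_na & abs(winding - 2 * pi) < 1e-6 & jump & pos_bad == 0
  minus <- !any_na & abs(winding + 2 * pi) < 1e-6 & jump & neg_bad == 0
  sel <- which(plus | minus)
  if (!length(sel))
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      charge = integer(0)))
  obs <- data.frame(x = rings$centroid[sel, 1], y = rings$centroid[sel, 2],
                    z = rings$centroid[sel, 3],
                    charge = ifelse(plus[sel], 1L, -1L))
  merge_detections(obs, merge_dist)
}

rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

# Greedy same-charge clustering: detections within merge_dist of an existing
# cluster centroid are pooled and the centroid re-averaged.
merge_detections <- function(obs, merge_dist) {
  if (nrow(obs) <= 1) return(obs)
  out <- list()
  for (q in unique(obs$charge)) {
    sub <- obs[obs$charge == q, , drop = FALSE]
    cl_pos <- list(); cl_n <- integer(0)
    for (i in seq_len(nrow(sub))) {
      p <- c(sub$x[i], sub$y[i], sub$z[i])
      hit <- 0L
      if (length(cl_pos)) {
        dd <- vapply(cl_pos, function(cp) sqrt(sum((cp - p)^2)), 0)
        j <- which.min(dd)
        if (dd[j] <= merge_dist) hit <- j
      }
      if (hit > 0L) {
        cl_pos[[hit]] <- (cl_pos[[hit]] * cl_n[hit] + p) / (cl_n[hit] + 1L)
        cl_n[hit] <- cl_n[hit] + 1L
      } else {
        cl_pos[[length(cl_pos) + 1L]] <- p
        cl_n <- c(cl_n, 1L)
      }
    }
    m <- do.call(rbind, cl_pos)
    out[[length(out) + 1L]] <- data.frame(x = m[, 1], y = m[, 2], z = m[, 3],
                                          charge = q)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Detect phase singularities in every frame
#'
#' @param phase_matrix nodes x frames wrapped phase (NA = masked).
#' @param times_ms frame times.
#' @param mesh an \code{rb_mesh}.
#' @param ... passed to \code{\link{detect_ps}}.
#' @return data.frame with time_ms, x, y, z, charge.
#' @export
detect_ps_frames <- function(phase_matrix, times_ms, mesh, ...) {
  rings <- node_one_rings(mesh)
  res <- lapply(seq_along(times_ms), function(f) {
    obs <- detect_ps(phase_matrix[, f], mesh, rings = rings, ...)
    if (nrow(obs)) cbind(time_ms = times_ms[f], obs) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(time_ms = numeric(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), charge = integer(0))
  out
}

#' Track phase singularities over time
#'
#' Greedy frame-to-frame association: each open track is extended by the
#' nearest unclaimed same-charge observation within \code{threshold} mm
#' (global nearest pair first; ties by list order); unmatched observations
#' start new tracks; tracks unmatched for more than \code{gap_frames}
#' consecutive frames are closed.
#'
#' @param ps data.frame from \code{\link{detect_ps_frames}}.
#' @param threshold association distance, mm (8/17/20 for the 3 mm grid,
#'   6 mm grid and basket respectively).
#' @param gap_frames frames a track may go unobserved before closing.
#' @param times optional full frame-time grid (so frames with no detection
#'   still count toward a track's observation gap); default: the distinct
#'   observation times.
#' @return list of \code{RotorTrack}s: each has \code{obs} (data.frame),
#'   \code{birth}, \code{death}, \code{lifespan} (ms), \code{mean_position}.
#' @export
track_ps <- function(ps, threshold, gap_frames = 1, times = NULL) {
  stopifnot(threshold > 0)
  if (is.unsorted(ps$time_ms)) stop("non-monotone frame times")
  frames <- if (is.null(times)) unique(ps$time_ms) else sort(unique(times))
  active <- list()   # each: obs rows, last position, charge, last frame index
  done <- list()
  for (fi in seq_along(frames)) {
    cur <- ps[ps$time_ms == frames[fi], , drop = FALSE]
    claimed <- rep(FALSE, nrow(cur))
    extended <- rep(FALSE, length(active))
    if (length(active) && nrow(cur)) {
      dmat <- matrix(Inf, length(active), nrow(cur))
      for (a in seq_along(active)) {
        same <- cur$charge == active[[a]]$charge
        if (any(same)) {
          dd <- sqrt((cur$x - active[[a]]$pos[1])^2 +
                     (cur$y - active[[a]]$pos[2])^2 +
                     (cur$z - active[[a]]$pos[3])^2)
          dmat[a, same] <- dd[same]
        }
      }
      repeat {
        mn <- min(dmat)
        if (!is.finite(mn) || mn > threshold) break
        hit <- which(dmat == mn, arr.ind = TRUE)[1, , drop = TRUE]
        a <- hit[1]; j <- hit[2]
        active[[a]]$obs <- rbind(active[[a]]$obs, cur[j, , drop = FALSE])
        active[[a]]$pos <- c(cur$x[j], cur$y[j], cur$z[j])
        active[[a]]$last_fi <- fi
        extended[a] <- TRUE
        claimed[j] <- TRUE
        dmat[a, ] <- Inf
        dmat[, j] <- Inf
      }
    }
    # close stale tracks
    if (length(active)) {
      stale <- vapply(active, function(tr) fi - tr$last_fi > gap_frames, TRUE)
      done <- c(done, active[stale])
      active <- active[!stale]
    }
    # new tracks
    for (j in which(!claimed)) {
      active[[length(active) + 1L]] <- list(
        obs = cur[j, , drop = FALSE],
        pos = c(cur$x[j], cur$y[j], cur$z[j]),
        charge = cur$charge[j], last_fi = fi)
    }
  }
  done <- c(done, active)
  lapply(done, function(tr) {
    obs <- tr$obs
    rownames(obs) <- NULL
    structure(list(obs = obs, charge = tr$charge,
                   birth = obs$time_ms[1],
                   death = obs$time_ms[nrow(obs)],
                   lifespan = obs$time_ms[nrow(obs)] - obs$time_ms[1],
                   mean_position = c(mean(obs$x), mean(obs$y), mean(obs$z))),
              class = "rb_track")
  })
}

#' @export
print.rb_track <- function(x, ...) {
  cat("<rb_track> charge ", x$charge, ", [", x$birth, ", ", x$death,
      "] ms (lifespan ", x$lifespan, " ms), ", nrow(x$obs),
      " observations\n", sep = "")
  invisible(x)
}

#' Select the ablation-target track
#'
#' The track with the longest lifespan; ties broken by earliest birth, then
#' list order.
#'
#' @param tracks list of \code{RotorTrack}s.
#' @return one \code{RotorTrack}.
#' @export
select_target <- function(tracks) {
  if (!length(tracks)) stop("no rotor found: empty track list")
  life <- vapply(tracks, function(t) t$lifespan, 0)
  birth <- vapply(tracks, function(t) t$birth, 0)
  best <- which(life == max(life))
  if (length(best) > 1) best <- best[birth[best] == min(birth[best])]
  tracks[[best[1]]]
}
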