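# Independent brute-force oracles used to cross-check the implementation.

# Wrap an angle difference into (-pi, pi] via atan2 (independent of the
# package's floor-based wrap).
oracle_wrap <- function(x) atan2(sin(x), cos(x))

# Brute-force topological-charge scan: for every interior node, order its
# one-ring neighbors by angle around the node (flat meshes only), sum the
# wrapped phase differences, and report loops with winding +-2*pi.
oracle_ps_scan <- function(phases, mesh) {
  el <- mesh$elements
  n <- nrow(mesh$nodes)
  nb <- vector("list", n)
  for (k in 1:3) {
    a <- el[, k]; b <- el[, (k %% 3) + 1L]
    for (i in seq_along(a)) {
      nb[[a[i]]] <- c(nb[[a[i]]], b[i])
      nb[[b[i]]] <- c(nb[[b[i]]], a[i])
    }
  }
  bnd <- unique(as.vector(rb_boundary_nodes(mesh)))
  out <- NULL
  for (v in seq_len(n)) {
    ring <- unique(nb[[v]])
    if (length(ring) < 3 || v %in% bnd || any(ring %in% NA)) next
    if (any(is.na(phases[ring])) || is.na(phases[v])) next
    rel <- sweep(mesh$nodes[ring, , drop = FALSE], 2, mesh$nodes[v, ])
    ang <- atan2(rel[, 2], rel[, 1])
    ring <- ring[order(ang)]
    ph <- phases[ring]
    w <- sum(oracle_wrap(diff(c(ph, ph[1]))))
    q <- round(w / (2 * pi))
    if (q != 0 && abs(w - 2 * pi * q) < 1e-6) {
      ctr <- colMeans(mesh$nodes[ring, , drop = FALSE])
      out <- rbind(out, data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
                                   charge = q))
    }
  }
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      charge = integer(0))
  out
}

# Nodes on boundary edges (edges belonging to exactly one triangle).
rb_boundary_nodes <- function(mesh) {
  el <- mesh$elements
  e <- rbind(el[, c(1, 2)], el[, c(2, 3)], el[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  unique(as.vector(e[key %in% names(tab)[tab == 1], ]))
}

# Greedy-clustered reference positions: matches each oracle detection to the
# nearest implementation detection; returns max distance (Inf on a count or
# charge mismatch).
match_ps <- function(impl, oracle, merge_dist) {
  # cluster oracle detections like the implementation merges neighbors
  if (nrow(oracle)) {
    merged <- NULL
    for (q in unique(oracle$charge)) {
      sub <- oracle[oracle$charge == q, , drop = FALSE]
      cl <- list()
      for (i in seq_len(nrow(sub))) {
        p <- c(sub$x[i], sub$y[i], sub$z[i])
        placed <- FALSE
        for (j in seq_along(cl)) {
          if (sqrt(sum((cl[[j]]$c - p)^2)) <= merge_dist) {
            cl[[j]]$c <- (cl[[j]]$c * cl[[j]]$n + p) / (cl[[j]]$n + 1)
            cl[[j]]$n <- cl[[j]]$n + 1
            placed <- TRUE
            break
          }
        }
        if (!placed) cl[[length(cl) + 1]] <- list(c = p, n = 1)
      }
      for (j in seq_along(cl))
        merged <- rbind(merged, data.frame(x = cl[[j]]$c[1], y = cl[[j]]$c[2],
                                           z = cl[[j]]$c[3], charge = q))
    }
    oracle <- merged
  }
  if (nrow(impl) != nrow(oracle)) return(Inf)
  if (!nrow(impl)) return(0)
  used <- rep(FALSE, nrow(oracle))
  worst <- 0
  for (i in seq_len(nrow(impl))) {
    d <- sqrt((oracle$x - impl$x[i])^2 + (oracle$y - impl$y[i])^2 +
              (oracle$z - impl$z[i])^2)
    d[used | oracle$charge != impl$charge[i]] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j])) return(Inf)
    used[j] <- TRUE
    worst <- max(worst, d[j])
  }
  worst
}
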