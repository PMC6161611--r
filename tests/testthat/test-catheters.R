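# Grid and basket catheter construction and placement.

test_that("grid construction spans the clinical 24 x 24 mm patch", {
  g9 <- build_grid(9, 3)
  expect_equal(nrow(g9$positions), 81)
  expect_equal(diff(range(g9$positions[, 1])), 24)
  expect_equal(diff(range(g9$positions[, 2])), 24)
  g5 <- build_grid(5, 6)
  expect_equal(nrow(g5$positions), 25)
  expect_equal(diff(range(g5$positions[, 1])), 24)
  g2 <- build_grid(2, 1)
  expect_equal(nrow(g2$positions), 4)
  expect_equal(sort(unique(abs(g2$positions[, 1]))), 0.5)
  expect_error(build_grid(1, 3), "at least 2")
  expect_false(anyDuplicated(g9$labels) > 0)
})

test_that("flat-sheet placement preserves spacing and applies wall offsets", {
  m <- make_sheet(41, 41, 1)
  g <- build_grid(9, 3)
  placed <- place_grid(m, g, c(20, 20, 0), wall_distance = 0,
                       inward = c(0, 0, 1))
  expect_lt(max(abs(placed$positions[, 3])), 1e-9)
  d <- as.matrix(dist(placed$positions))
  diag(d) <- Inf
  expect_lt(max(abs(apply(d, 1, min) - 3)), 1e-6)
  up <- place_grid(m, g, c(20, 20, 0), wall_distance = 5, inward = c(0, 0, 1))
  expect_lt(max(abs(up$positions[, 3] - 5)), 1e-9)
  expect_lt(max(abs(up$wall_distance - 5)), 1 + 1e-9)  # within one edge length
  expect_error(place_grid(m, g, c(500, 500, 0), 0), "geometry error")
})

test_that("sphere placement projects onto the surface and offsets inward", {
  sph <- make_sphere(30, resolution = 2.5)
  edge <- rotorbench:::mesh_edge_length(sph)
  roi <- sph$nodes[which.max(sph$nodes[, 3]), ]
  g <- build_grid(5, 3)
  on_wall <- place_grid(sph, g, roi, wall_distance = 0)
  r0 <- sqrt(rowSums(on_wall$positions^2))
  expect_lt(max(abs(r0 - 30)), edge)
  off <- place_grid(sph, g, roi, wall_distance = 5)
  r5 <- sqrt(rowSums(off$positions^2))
  expect_lt(max(abs(r5 - 25)), edge)
  expect_lt(max(abs(off$wall_distance - 5)), edge)
})

test_that("grid placement is equivariant under rigid transforms", {
  m <- make_sheet(31, 31, 1)
  g <- build_grid(5, 3)
  roi <- c(15, 15, 0)
  base <- place_grid(m, g, roi, wall_distance = 3, inward = c(0, 0, 1))
  th <- 0.6
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  shift <- c(3, -2, 7)
  m2 <- m
  m2$nodes <- sweep(m$nodes %*% t(R), 2, shift, `+`)
  m2$fiber <- m$fiber %*% t(R)
  moved <- place_grid(m2, g, as.numeric(R %*% roi) + shift, wall_distance = 3,
                      inward = as.numeric(R %*% c(0, 0, 1)))
  expected <- sweep(base$positions %*% t(R), 2, shift, `+`)
  expect_lt(max(abs(moved$positions - expected)), 1e-6)
})

test_that("basket has 64 electrodes and sits on its nominal sphere in a large cavity", {
  sph <- make_sphere(35, resolution = 3)
  b <- place_basket(sph, center = c(0, 0, 0))
  expect_equal(nrow(b$positions), 64)
  r <- sqrt(rowSums(b$positions^2))
  expect_lt(max(abs(r - 24)), 1e-9)
  # uniform intra-spline arc spacing and monotone pole angle per spline
  for (s in LETTERS[1:8]) {
    idx <- grep(paste0("^", s), b$labels)
    ang <- acos(pmin(1, pmax(-1, b$positions[idx, 3] / r[idx])))
    expect_true(all(diff(ang) > 0))
    expect_lt(max(abs(diff(diff(ang)))), 1e-6)
  }
  expect_error(place_basket(sph, center = c(0, 0, 100)), "geometry error")
})

test_that("basket contracts inside narrow cavities keeping wall clearance", {
  ell <- make_ellipsoid_atrium(semi_axes = c(32, 32, 20), resolution = 3)
  edge <- rotorbench:::mesh_edge_length(ell)
  b <- place_basket(ell, center = c(0, 0, 0))
  # strictly inside: signed containment via the ellipsoid equation
  rr <- sqrt(rowSums(sweep(b$positions, 2, c(32, 32, 20), `/`)^2))
  expect_true(all(rr < 1))
  expect_gt(min(b$wall_distance), 1 - edge)
  # spline ordering preserved after contraction
  for (s in LETTERS[1:8]) {
    idx <- grep(paste0("^", s), b$labels)
    u <- sweep(b$positions[idx, ], 2, c(0, 0, 0))
    ang <- acos(pmin(1, pmax(-1, u[, 3] / sqrt(rowSums(u^2)))))
    expect_true(all(diff(ang) > 0))
  }
})
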