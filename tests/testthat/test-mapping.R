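# Nearest-neighbor phase mapping, singularity detection, and tracking.

test_that("nearest-neighbor mapping respects the 13 mm cutoff", {
  m <- make_sheet(31, 31, 1)
  elecs <- build_grid(2, 6)
  elecs$positions <- rbind(c(5, 5, 0), c(25, 25, 2))
  elecs$labels <- c("A", "B")
  time <- 0:9
  pt <- hilbert_phase(cbind(sin(time / 2), cos(time / 2)), time)
  pt$valid[] <- TRUE
  mapped <- map_phase_to_mesh(pt, elecs, m)
  # node coincident with electrode A
  iA <- which(m$nodes[, 1] == 5 & m$nodes[, 2] == 5)
  expect_equal(mapped$phase[iA, ], pt$phase[, 1])
  # nodes farther than 13 mm from both electrodes are masked
  d <- cross_dist(m$nodes, elecs$positions)
  expect_true(all(is.na(mapped$phase[apply(d, 1, min) > 13, ])))
  expect_false(anyNA(mapped$phase[apply(d, 1, min) <= 13, ]))
  # brute-force nearest-neighbor oracle
  nn_oracle <- apply(d, 1, which.min)
  for (i in c(1, 200, 500, 961)) {
    if (min(d[i, ]) <= 13)
      expect_equal(mapped$phase[i, ], pt$phase[, nn_oracle[i]])
  }
  # invalid electrode samples propagate as masks
  pt$valid[3, 1] <- FALSE
  mapped2 <- map_phase_to_mesh(pt, elecs, m)
  expect_true(is.na(mapped2$phase[iA, 3]))
})

test_that("a planar vortex yields exactly one positive singularity at its center", {
  m <- make_sheet(21, 21, 1)
  ph <- analytic_vortex_field(m, centers = c(10.3, 9.6, 0), charges = 1)
  obs <- detect_ps(ph[, 1], m)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$charge, 1)
  edge <- rotorbench:::mesh_edge_length(m)
  expect_lt(sqrt((obs$x - 10.3)^2 + (obs$y - 9.6)^2), 2 * edge)
  # oracle cross-check
  oracle <- oracle_ps_scan(ph[, 1], m)
  expect_lt(match_ps(obs, oracle, 2 * edge), 2 * edge)
  # uniform phase: nothing
  expect_equal(nrow(detect_ps(rep(0.3, nrow(m$nodes)), m)), 0)
})

test_that("an opposite-charge vortex pair is detected with both charges", {
  m <- make_sheet(31, 31, 1)
  ph <- analytic_vortex_field(m, centers = rbind(c(8.2, 15.1, 0),
                                                 c(22.7, 15.4, 0)),
                              charges = c(1, -1))
  obs <- detect_ps(ph[, 1], m)
  expect_equal(sort(obs$charge), c(-1L, 1L))
  expect_equal(sum(obs$charge), 0)
  i_plus <- which(obs$charge == 1)
  expect_lt(abs(obs$x[i_plus] - 8.2), 2)
  # total winding around a loop enclosing both vortices is zero:
  # the charge sum over all detections vanishes (checked above)
})

test_that("charges sum to zero on a closed surface", {
  sph <- make_sphere(20, resolution = 4)
  ph <- analytic_vortex_field(sph, centers = rbind(c(0, 0, 20), c(0, 0, -20)),
                              charges = c(1, -1))
  obs <- detect_ps(ph[, 1], sph)
  expect_equal(sum(obs$charge), 0)
  expect_equal(nrow(obs), 2)
  expect_gt(max(abs(obs$z)), 15)   # both detections sit at the poles
})

test_that("rotating vortex frames freeze when omega is zero", {
  m <- make_sheet(15, 15, 1)
  fr0 <- analytic_vortex_field(m, c(7, 7, 0), 1, omega = 0, times_ms = c(0, 50, 100))
  expect_true(all(fr0[, 1] == fr0[, 2] & fr0[, 2] == fr0[, 3]))
  frw <- analytic_vortex_field(m, c(7, 7, 0), 1, omega = 2 * pi,
                               times_ms = c(0, 250))
  d <- rotorbench:::wrap_phase(frw[, 2] - frw[, 1])
  expect_lt(max(abs(d + pi / 2)), 1e-9)
})

test_that("greedy tracking associates, gates by charge, and respects the threshold", {
  mk <- function(t, x, y, q) data.frame(time_ms = t, x = x, y = y, z = 0,
                                        charge = q)
  # stationary PS over 10 frames -> one full-span track
  ps <- do.call(rbind, lapply(1:10, function(f) mk(f * 10, 5, 5, 1)))
  tr <- track_ps(ps, threshold = 8)
  expect_equal(length(tr), 1)
  expect_equal(tr[[1]]$lifespan, 90)
  # displacement beyond the threshold splits the track
  ps2 <- rbind(mk(10, 0, 0, 1), mk(20, 25, 0, 1))
  expect_equal(length(track_ps(ps2, threshold = 20)), 2)
  expect_equal(length(track_ps(ps2, threshold = 26)), 1)
  # opposite charges never associate
  ps3 <- rbind(mk(10, 5, 5, 1), mk(20, 5, 5, -1))
  expect_equal(length(track_ps(ps3, threshold = 8)), 2)
  # a gap longer than gap_frames closes the track
  ps4 <- rbind(mk(10, 5, 5, 1), mk(20, 5, 5, 1), mk(50, 5, 5, 1))
  expect_equal(length(track_ps(ps4, threshold = 8, gap_frames = 1,
                               times = seq(10, 50, 10))), 2)
  expect_error(track_ps(ps2[2:1, ], threshold = 8), "non-monotone")
})

test_that("target selection prefers lifespan, then earliest birth", {
  mk_track <- function(birth, death) {
    obs <- data.frame(time_ms = c(birth, death), x = 0, y = 0, z = 0, charge = 1)
    structure(list(obs = obs, charge = 1, birth = birth, death = death,
                   lifespan = death - birth, mean_position = c(0, 0, 0)),
              class = "rb_track")
  }
  a <- mk_track(100, 600)   # 0.5 s
  b <- mk_track(300, 1500)  # 1.2 s
  expect_identical(select_target(list(a, b)), b)
  c1 <- mk_track(100, 900)
  c2 <- mk_track(300, 1100)
  expect_identical(select_target(list(c2, c1)), c1)  # tie -> earliest birth
  expect_identical(select_target(list(a)), a)
  expect_error(select_target(list()), "no rotor")
})

test_that("detection agrees with the brute-force winding oracle on random vortex fields", {
  set.seed(42)
  m <- make_sheet(21, 21, 1)
  edge <- rotorbench:::mesh_edge_length(m)
  for (rep in 1:20) {
    k <- sample(1:2, 1)
    ctr <- cbind(runif(k, 4, 16), runif(k, 4, 16), 0)
    q <- sample(c(-1, 1), k, replace = TRUE)
    if (k == 2 && sqrt(sum((ctr[1, ] - ctr[2, ])^2)) < 4 * edge) next
    smooth <- outer(m$nodes[, 1] / 30, rep(1, 1)) + 0.3 * sin(m$nodes[, 2] / 5)
    ph <- rotorbench:::wrap_phase(analytic_vortex_field(m, ctr, q)[, 1] + smooth)
    obs <- detect_ps(ph, m)
    oracle <- oracle_ps_scan(ph, m)
    expect_lt(match_ps(obs, oracle, 2 * edge), 2 * edge)
  }
})
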