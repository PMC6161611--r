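# Unipolar electrogram forward model: sources and monopole superposition.

test_that("current sources vanish for uniform voltage and on lesions, and sum to zero on closed surfaces", {
  sph <- make_sphere(20, resolution = 3)
  nt <- 5
  fake <- function(vm) structure(list(vm = vm, mesh = sph,
                                      time = seq_len(ncol(vm)) - 1),
                                 class = "rb_simulation")
  n <- nrow(sph$nodes)
  # uniform voltage -> zero everywhere
  src0 <- current_sources(fake(matrix(-80, n, nt)))
  expect_lt(max(abs(src0)), 1e-9)
  # smooth non-uniform field: discrete divergence theorem
  vm <- outer(sin(sph$nodes[, 3] / 5) * 40 - 60, seq_len(nt) / nt)
  src <- current_sources(fake(vm))
  expect_lt(max(abs(colSums(src)) / colSums(abs(src))), 1e-6)
  # lesioned elements are exactly zero
  les <- apply_circular_lesion(sph, sph$nodes[1, ], 5)
  fl <- fake(vm); fl$mesh <- les
  srcl <- current_sources(fl)
  expect_true(all(srcl[les$label == "LESION", ] == 0))
})

test_that("monopole superposition matches the closed form and is linear", {
  tri <- rb_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 matrix(c(1L, 2L, 3L), 1))
  elec <- build_grid(2, 1)
  ctr <- colMeans(tri$nodes)
  elec$positions <- rbind(ctr + c(0, 0, 1),    # 1 mm from the centroid
                          ctr + c(0, 0, 2),
                          ctr + c(0, 0, 4),
                          ctr + c(0, 0, 8))
  sigma <- 0.7
  src <- matrix(4 * pi * sigma, 1, 1)
  egm <- compute_egms(src, elec, tri, time = 0, sigma_blood = sigma)
  expect_equal(egm$phi[1, 1], 1)
  expect_equal(egm$phi[1, 2], 0.5)       # 1/r decay
  # linearity
  egm2 <- compute_egms(2 * src, elec, tri, time = 0, sigma_blood = sigma)
  expect_equal(egm2$phi, 2 * egm$phi)
  # zero sources -> identically zero
  egm0 <- compute_egms(0 * src, elec, tri, time = 0, sigma_blood = sigma)
  expect_true(all(egm0$phi == 0))
  expect_error(compute_egms(src, elec, tri, 0, sigma_blood = -1), "sigma_blood")
})

test_that("decimation to 1 kHz preserves band-limited peak-to-peak amplitude", {
  tri <- rb_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 matrix(c(1L, 2L, 3L), 1))
  elec <- build_grid(2, 1)
  elec$positions <- matrix(colMeans(tri$nodes) + c(0, 0, 5), 1)
  elec$labels <- "E1"
  time <- seq(0, 500, by = 0.1)          # 10 kHz solver grid
  src <- matrix(sin(2 * pi * 40 * time / 1000), 1)  # 40 Hz, band-limited
  egm <- compute_egms(src, elec, tri, time, fs_hz = 1000)
  expect_equal(diff(egm$time[1:2]), 1)
  p2p_in <- diff(range(src))
  p2p_out <- diff(range(egm$phi))
  expect_lt(abs(p2p_out * max(cross_dist(elec$positions, mesh_centroids(tri))) *
                4 * pi * 0.7 - p2p_in) / p2p_in, 0.05)
})

# shared planar-wave simulation for the sign-convention and decay tests
wave_sim <- local({
  m <- make_sheet(41, 21, 1)
  model <- mitchell_schaeffer_model()
  prot <- stimulus_protocol(list(stim_nodes(which(m$nodes[, 1] < 1.5), onset = 1)))
  run_monodomain(m, model, prot, 200)
})

test_that("a passing planar wavefront yields a biphasic positive-then-negative deflection", {
  m <- wave_sim$mesh
  elec <- build_grid(2, 1)
  elec$positions <- matrix(c(20, 10, 0.5), 1)
  elec$labels <- "E1"
  egm <- record_egms(wave_sim, elec)
  tr <- egm$phi[, 1]
  expect_gt(max(tr), 0)
  expect_lt(min(tr), 0)
  expect_lt(egm$time[which.max(tr)], egm$time[which.min(tr)])
})

test_that("potential amplitude decays with distance in the far field", {
  elec <- build_grid(2, 1)
  ds <- c(20, 40, 80)
  elec$positions <- cbind(20, 10, ds)
  elec$labels <- paste0("E", seq_along(ds))
  egm <- record_egms(wave_sim, elec)
  amp <- apply(egm$phi, 2, function(x) diff(range(x)))
  expect_true(all(diff(amp) < 0))
  # faster than 1/r (no net monopole)
  expect_lt(amp[2] / amp[1], 0.5)
})
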