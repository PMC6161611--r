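# Cell model, steady-state pacing, and the monodomain solver.

model <- mitchell_schaeffer_model()

test_that("rest state is a fixed point and steady-state pacing converges", {
  r <- model$rates(model$rest_state())
  expect_lt(sqrt(sum(unlist(r)^2)), 1e-12)
  ss <- init_steady_state(model, bcl = 800)
  expect_true(ss$converged)
  expect_gt(ss$apd90, 120)
  expect_lt(ss$apd90, 180)
  # one more paced beat changes APD90 by < 1 ms
  r1 <- rotorbench:::single_cell_run(model, 800, stim_onsets = 1,
                                     init_state = ss$state)
  expect_lt(abs(rotorbench:::apd90(r1$time, r1$vm) - ss$apd90), 1)
  # no pacing returns rest unchanged; identical calls are bit-identical
  expect_identical(init_steady_state(model, max_beats = 0)$state,
                   model$rest_state())
  expect_identical(init_steady_state(model), init_steady_state(model))
})

test_that("resting tissue is stable and zero conductivity stops propagation", {
  m <- make_sheet(15, 15, 1)
  quiet <- run_monodomain(m, model, stimulus_protocol(list()), 1000)
  rest_mv <- model$v_rest_mv
  expect_lt(max(abs(quiet$vm - rest_mv)), 0.1)
  # zero-conductivity mesh: stimulus stays confined to the disc
  m0 <- m
  m0$sigma_l[] <- 0; m0$sigma_t[] <- 0
  prot <- stimulus_protocol(list(stim_disc(c(7, 7, 0), 2, onset = 1)))
  r <- run_monodomain(m0, model, prot, 200)
  d <- sqrt(colSums((t(m0$nodes) - c(7, 7, 0))^2))
  outside <- d > 2
  expect_lt(max(abs(r$vm[outside, ] - rest_mv)), 1)
  expect_gt(max(r$vm[!outside, ]), 0)
})

cable_cv <- function(spacing, n_mm = 60, dt_ms = NULL) {
  cab <- make_cable(round(n_mm / spacing) + 1, spacing)
  # fixed 2 mm stimulated segment so the source size does not shrink with the
  # spatial refinement
  prot <- stimulus_protocol(list(stim_nodes(which(cab$nodes[, 1] < 2),
                                            onset = 1)))
  r <- run_monodomain(cab, model, prot, 250, dt_ms = dt_ms)
  at <- function(xmm) {
    i <- which(abs(cab$nodes[, 1] - xmm) < spacing / 2 & cab$nodes[, 2] == 0)[1]
    r$time[which(r$vm[i, ] > -30)[1]]
  }
  (0.5 * n_mm) / (at(0.75 * n_mm) - at(0.25 * n_mm))
}

test_that("conduction velocity converges in space and time", {
  cv1 <- cable_cv(1)
  cv_half <- cable_cv(0.5)
  expect_lt(abs(cv1 - cv_half) / cv_half, 0.10)
  # physiological band for the remodeled substrate
  expect_gt(cv1, 0.3)
  expect_lt(cv1, 0.6)
  # halving dt barely moves the wavefront: activation times shift by at most
  # one output sample everywhere (a pointwise max-norm on vm is meaningless
  # for a propagating ~100 mV upstroke, where a sub-ms front shift already
  # produces tens of mV locally)
  cab <- make_cable(61, 1)
  prot <- stimulus_protocol(list(stim_nodes(which(cab$nodes[, 1] < 2), onset = 1)))
  ra <- run_monodomain(cab, model, prot, 150, dt_ms = 0.1)
  rb <- run_monodomain(cab, model, prot, 150, dt_ms = 0.05)
  act <- function(r) apply(r$vm, 1, function(v) r$time[which(v > -30)[1]])
  aa <- act(ra); ab <- act(rb)
  expect_false(anyNA(aa) || anyNA(ab))
  expect_lte(max(abs(aa - ab)), 2)
})

test_that("planar-wave anisotropy follows the square root of the conductivity ratio", {
  m <- make_sheet(61, 61, 1, anisotropy = 4)
  prot_x <- stimulus_protocol(list(stim_nodes(which(m$nodes[, 1] < 1.5), onset = 1)))
  prot_y <- stimulus_protocol(list(stim_nodes(which(m$nodes[, 2] < 1.5), onset = 1)))
  cv_dir <- function(prot, axis) {
    r <- run_monodomain(m, model, prot, 300)
    mid <- if (axis == 1) m$nodes[, 2] == 30 else m$nodes[, 1] == 30
    at <- function(xmm) {
      i <- which(mid & abs(m$nodes[, axis] - xmm) < 0.5)[1]
      r$time[which(r$vm[i, ] > -30)[1]]
    }
    30 / (at(45) - at(15))
  }
  ratio <- cv_dir(prot_x, 1) / cv_dir(prot_y, 2)
  expect_lt(abs(ratio - 2) / 2, 0.15)
})

test_that("solver is deterministic and a transmural lesion line blocks conduction", {
  cab <- make_cable(61, 1)
  prot <- stimulus_protocol(list(stim_nodes(which(cab$nodes[, 1] < 1.5), onset = 1)))
  r1 <- run_monodomain(cab, model, prot, 100)
  r2 <- run_monodomain(cab, model, prot, 100)
  expect_identical(r1$vm, r2$vm)
  # lesion line fully crossing the cable
  les <- apply_linear_lesion(cab, rbind(c(30, -1, 0), c(30, 2, 0)), 1)
  rl <- run_monodomain(les, model, prot, 250)
  downstream <- les$nodes[, 1] > 33
  expect_lt(max(abs(rl$vm[downstream, ] - model$v_rest_mv)), 1)
})

test_that("sinus protocol encodes the inter-site delay", {
  bb <- list(center = c(5, 5, 0), radius = 2)
  fo <- list(center = c(15, 15, 0), radius = 2)
  p <- sinus_protocol(bb, fo)
  expect_equal(p$stimuli[[2]]$onset - p$stimuli[[1]]$onset, 26)
  p0 <- sinus_protocol(bb, fo, delay = 0)
  expect_equal(p0$stimuli[[2]]$onset, p0$stimuli[[1]]$onset)
  pneg <- sinus_protocol(bb, fo, delay = -10)
  expect_lt(pneg$stimuli[[2]]$onset, pneg$stimuli[[1]]$onset)
})

test_that("reentry induction validates its arguments", {
  m <- make_sheet(5, 5, 1)
  prot <- stimulus_protocol(list(stim_nodes(1L, onset = 1)))
  expect_error(induce_reentry(m, model, prot, c(2, 2, 0), s2_radius = 0,
                              s2_scan = c(10, 20)), "s2_radius")
  expect_error(induce_reentry(m, model, prot, c(2, 2, 0),
                              s2_scan = c(20, 10)), "scan")
  expect_error(stim_disc(c(0, 0, 0), radius = -1, onset = 0), "radius")
})
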