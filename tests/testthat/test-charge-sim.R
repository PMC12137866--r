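make_tau_phantom <- function(n, tau) {
  ph <- make_phantom("homogeneous", n, n, seed = 1)
  ph$tau_map[] <- tau
  ph
}

test_that("evolve_charge leaves the state unchanged for dt = 0 and rejects dt < 0", {
  ph <- make_tau_phantom(32, 1000)
  st <- leapscan:::new_charge_state(32, 32)
  st$C[10, 10] <- 5
  expect_identical(evolve_charge(st, 0, ph)$C, st$C)
  expect_error(evolve_charge(st, -1, ph), "non-negative")
})

test_that("pure leak follows the exponential closed form", {
  ph <- make_tau_phantom(32, 1000)
  st <- leapscan:::new_charge_state(32, 32)
  st$C[16, 16] <- 100
  p <- sim_params(D_px2_per_ns = 0)
  out <- evolve_charge(st, 1000, ph, p)
  expect_lt(abs(out$C[16, 16] - 100 * exp(-1)), 1e-9)
  expect_equal(sum(out$C != 0), 1)
})

test_that("diffusion with infinite tau conserves total charge to 1e-9", {
  ph <- make_tau_phantom(32, Inf)
  st <- leapscan:::new_charge_state(32, 32)
  st$C[5, 7] <- 50
  p <- sim_params(D_px2_per_ns = 0.01)
  s <- st
  for (i in 1:100) s <- evolve_charge(s, 100, ph, p)
  expect_lt(abs(sum(s$C) - 50), 1e-9 * 50)
  expect_true(all(s$C >= 0))
  # charge spreads
  expect_lt(max(s$C), 50)
})

test_that("detect_signal is exact without charging and decreases with charge", {
  ph <- make_phantom("cell", 64, 64, seed = 2)
  st <- leapscan:::new_charge_state(64, 64)
  p0 <- sim_params(alpha = 0, noise_std = 0)
  s <- detect_signal(ph, st, c(3, 4), p0)
  expect_equal(as.numeric(s),
               p0$detector_gain * ph$yield_map[5, 4] + p0$detector_offset)
  # zero charge, alpha > 0: same value
  p1 <- sim_params(alpha = 1, noise_std = 0)
  expect_equal(as.numeric(detect_signal(ph, st, c(3, 4), p1)), as.numeric(s))
  # higher local charge strictly darkens
  st2 <- st; st2$C[5, 4] <- 10
  st3 <- st; st3$C[5, 4] <- 40
  v2 <- as.numeric(detect_signal(ph, st2, c(3, 4), p1))
  v3 <- as.numeric(detect_signal(ph, st3, c(3, 4), p1))
  expect_lt(v2, as.numeric(s))
  expect_lt(v3, v2)
  expect_error(detect_signal(ph, st, c(64, 0), p1), "outside")
})

test_that("acquisition without charging reproduces gain * yield + offset exactly", {
  ph <- make_phantom("cell", 64, 64, seed = 2)
  p <- sim_params(alpha = 0, noise_std = 0)
  stk <- simulate_acquisition(ph, make_raster_pattern(64, 64, 100, 2), p, 1)
  for (f in 1:2)
    expect_equal(stk$frames[, , f],
                 round(p$detector_gain * ph$yield_map + p$detector_offset))
  # line integration gives the same single frame
  stk_li <- simulate_acquisition(
    ph, make_raster_pattern(64, 64, 100, 3, "line", 1000), p, 1)
  expect_equal(dim(stk_li$frames)[3], 1)
  expect_equal(stk_li$frames[, , 1],
               round(p$detector_gain * ph$yield_map + p$detector_offset))
})

test_that("total deposited charge is conserved with tau = Inf and D = 0", {
  ph <- make_tau_phantom(32, Inf)
  p <- sim_params(q0_electrons = 3, D_px2_per_ns = 0, noise_std = 0)
  stk <- simulate_acquisition(ph, make_raster_pattern(32, 32, 100, 1), p, 1)
  expect_equal(sum(stk$charge), 32 * 32 * 3)
  # and with diffusion on, to 1e-9 relative
  p2 <- sim_params(q0_electrons = 3, D_px2_per_ns = 0.005, noise_std = 0)
  stk2 <- simulate_acquisition(ph, make_interleaved_pattern(32, 32, 2, 2, 100, 2),
                               p2, 1)
  expect_lt(abs(sum(stk2$charge) - 2 * 32 * 32 * 3), 1e-9 * 2 * 32 * 32 * 3)
})

test_that("dissipation batching is a numerical convenience, not a model change", {
  ph <- make_phantom("cell", 64, 64, seed = 4)
  pat <- make_raster_pattern(64, 64, 100, 3)
  base <- sim_params(noise_std = 0)
  dev <- vapply(c(1L, 64L), function(K) {
    p <- sim_params(noise_std = 0, batch_visits = K)
    img <- integrate_frames(convert_to_uint8(
      simulate_acquisition(ph, pat, p, 1)))
    histogram_mean(img)$charging_deviation
  }, 0)
  expect_lt(abs(dev[1] - dev[2]), 0.05 * max(abs(dev)))
})

test_that("peak charge trace is non-negative, zero without deposition, and ordered by strategy", {
  # tau between the line-pass period and the frame time: the regime where line
  # integration concentrates charge locally while interleaving lets each
  # neighbourhood drain between sub-lattice passes
  ph <- make_tau_phantom(48, 5e4)
  p0 <- sim_params(q0_electrons = 0, noise_std = 0)
  tr0 <- peak_charge_trace(ph, make_raster_pattern(48, 48, 100, 2), p0, 1)
  expect_true(all(tr0$peak_charge == 0))
  p <- sim_params(noise_std = 0)
  tr_li <- peak_charge_trace(ph, make_raster_pattern(48, 48, 100, 4, "line",
                                                     2000), p, 1)
  tr_il <- peak_charge_trace(ph, make_interleaved_pattern(48, 48, 2, 2, 100, 4),
                             p, 1)
  expect_true(all(tr_li$peak_charge >= 0))
  expect_gte(max(tr_li$peak_charge), max(tr_il$peak_charge))
})

test_that("peak charge is non-increasing in the skip count", {
  ph <- make_tau_phantom(48, 5e4)
  p <- sim_params(noise_std = 0)
  peaks <- vapply(c(0, 2, 4), function(s) {
    max(peak_charge_trace(ph, make_interleaved_pattern(48, 48, s, s, 100, 2),
                          p, 1)$peak_charge)
  }, 0)
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("grid mismatch is rejected", {
  ph <- make_phantom("homogeneous", 32, 32, seed = 1)
  expect_error(simulate_acquisition(ph, make_raster_pattern(16, 16, 100, 1),
                                    sim_params(), 1), "match")
})
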