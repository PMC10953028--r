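test_that("synthesized waveforms have the prescribed shape, frequency and amplitude", {
  wp <- wave_params(g_max = 10, n_cyc = 15, bw_per_pixel = 121, n_read = 256,
                    os_factor = 6)
  wf <- synthesize_waveforms(wp)
  expect_length(wf$t, 256 * 6)
  expect_equal(max(wf$t), 1e3 / 121, tolerance = 1e-12)
  expect_equal(max(abs(wf$gy)), 10, tolerance = 1e-4)
  expect_equal(wf$gy[1], 0)                        # sine starts at zero
  expect_equal(wf$gz[1], 10)                       # cosine starts at extremum
  # pi/2 phase offset: the waveforms are exact sine/cosine at f = 15/T
  f_khz <- 15 * 121 * 1e-3
  expect_equal(wf$gy, 10 * sin(2 * pi * f_khz * wf$t), tolerance = 1e-12)
  expect_equal(wf$gz, 10 * cos(2 * pi * f_khz * wf$t), tolerance = 1e-12)
  # zero amplitude -> all-zero waveforms
  wf0 <- synthesize_waveforms(wave_params(0, 15, 121, 256))
  expect_true(all(wf0$gy == 0) && all(wf0$gz == 0))
})

test_that("waveform validation rejects non-integer cycles and slew violations", {
  expect_error(wave_params(10, 7.5, 121, 256), "integer")
  expect_error(wave_params(-1, 6, 121, 256), "non-negative")
  # 25 mT/m at very high frequency exceeds a 200 T/m/s slew limit
  wp <- wave_params(g_max = 25, n_cyc = 40, bw_per_pixel = 500, n_read = 256)
  expect_error(synthesize_waveforms(wp), "slew")
})

test_that("moments match high-resolution quadrature and are linear in amplitude", {
  wp <- wave_params(g_max = 25, n_cyc = 6, bw_per_pixel = 121, n_read = 256,
                    os_factor = 6)
  mom <- compute_moments(synthesize_waveforms(wp))
  # oracle: 10x finer uniform grid, same analytic waveform
  t_fine <- seq(0, 1e3 / 121, length.out = 10 * length(mom$t) - 9)
  f <- 6 * 121 * 1e-3
  gy_f <- 25 * sin(2 * pi * f * t_fine)
  m1_oracle <- pracma::cumtrapz(t_fine, gy_f * t_fine)[, 1]
  at <- seq(1, length(t_fine), by = 10)
  expect_lt(max(abs(mom$m1[, "y"] - m1_oracle[at])) / max(abs(m1_oracle)),
            1e-6)
  # linearity: halving g_max halves both moments pointwise
  mom_h <- compute_moments(synthesize_waveforms(
    wave_params(12.5, 6, 121, 256, os_factor = 6)))
  expect_equal(mom_h$m0, mom$m0 / 2, tolerance = 1e-12)
  expect_equal(mom_h$m1, mom$m1 / 2, tolerance = 1e-12)
})

test_that("m0 of whole sine cycles returns to zero and the m1 envelope grows", {
  wp <- wave_params(10, 15, 121, 256, os_factor = 6)
  mom <- compute_moments(synthesize_waveforms(wp))
  n <- length(mom$t)
  expect_lt(abs(mom$m0[n, "y"]) / max(abs(mom$m0[, "y"])), 1e-9)
  # per-cycle m1 envelope is non-decreasing
  per_cycle <- split(abs(mom$m1[, "y"]),
                     cut(mom$t, 15, labels = FALSE))
  env <- vapply(per_cycle, max, numeric(1))
  expect_true(all(diff(env) > -1e-12))
  # m0 oscillates with a constant envelope (cycle maxima agree within 1%)
  env0 <- vapply(split(abs(mom$m0[, "y"]), cut(mom$t, 15, labels = FALSE)),
                 max, numeric(1))
  expect_lt(diff(range(env0)) / max(env0), 0.01)
})

test_that("large-amplitude few-cycle waveforms carry the larger first moment", {
  momA <- compute_moments(synthesize_waveforms(
    wave_params(25, 6, 121, 256, os_factor = 6)))
  momC <- compute_moments(synthesize_waveforms(
    wave_params(10, 15, 121, 256, os_factor = 6)))
  expect_gt(max(abs(momA$m1)), max(abs(momC$m1)))
})

test_that("flow phase is linear in velocity, zero at rest, and ordered by m1", {
  momA <- compute_moments(synthesize_waveforms(
    wave_params(25, 6, 121, 256, os_factor = 6)))
  momC <- compute_moments(synthesize_waveforms(
    wave_params(10, 15, 121, 256, os_factor = 6)))
  expect_true(all(flow_phase_series(momA, c(0, 0)) == 0))
  p1 <- flow_phase_series(momA, c(50, 100))
  p2 <- flow_phase_series(momA, c(100, 200))
  expect_equal(p2, 2 * p1, tolerance = 1e-12)
  v <- c(0, 200)
  expect_gt(max(abs(flow_phase_series(momA, v))),
            max(abs(flow_phase_series(momC, v))))
})

test_that("hardware limit report matches the analytic peak slew", {
  wf <- synthesize_waveforms(wave_params(10, 15, 121, 256, os_factor = 6))
  rep <- check_hardware_limits(wf, slew_limit = 200, amp_limit = 80)
  # analytic 2 pi f G_max = 114 T/m/s for the protocol waveform
  expect_equal(rep$peak_slew, 10e-3 * 2 * pi * 15 * 121, tolerance = 1e-3)
  expect_true(rep$pass)
  # the large-amplitude variant has the same frequency-amplitude product
  wfA <- synthesize_waveforms(wave_params(25, 6, 121, 256, os_factor = 6))
  repA <- check_hardware_limits(wfA)
  expect_equal(repA$peak_slew, rep$peak_slew, tolerance = 1e-3)
  wf0 <- synthesize_waveforms(wave_params(0, 6, 121, 256))
  rep0 <- check_hardware_limits(wf0)
  expect_true(rep0$pass && rep0$peak_amp == 0 && rep0$peak_slew == 0)
})

test_that("PSF spread is zero iff amplitude is zero and monotone in g_max and FOV_y", {
  expect_equal(psf_spread_extent(wave_params(0, 15, 121, 256), 200, 200, 26.4), 0)
  s1 <- psf_spread_extent(wave_params(5, 15, 121, 256), 200, 200, 26.4)
  s2 <- psf_spread_extent(wave_params(10, 15, 121, 256), 200, 200, 26.4)
  expect_gt(s1, 0)
  expect_equal(s2, 2 * s1, tolerance = 1e-9)     # linear in g_max
  s3 <- psf_spread_extent(wave_params(5, 15, 121, 256), 200, 300, 26.4)
  expect_gt(s3, s1)                              # monotone in FOV_y
})

test_that("brute-force point-source displacement respects the closed-form spread bound", {
  wp <- wave_params(10, 15, 121, 256, os_factor = 6)
  wf <- synthesize_waveforms(wp)
  g_read <- wavemra:::readout_gradient(wp, 200)
  # displacement of corner voxels, sample-wise from the actual waveform
  corners <- expand.grid(y = c(-100, 100), z = c(-13.2, 13.2))
  disp <- apply(corners, 1, function(cc)
    max(abs(wf$gy * cc["y"] + wf$gz * cc["z"])) / g_read)
  bound <- psf_spread_extent(wp, 200, 200, 26.4)
  expect_true(all(disp <= bound + 1e-9))
  expect_gt(max(disp), 0.85 * bound)
})

test_that("waveform CSV export round-trips", {
  wf <- synthesize_waveforms(wave_params(10, 3, 500, 32, os_factor = 2))
  fy <- tempfile(fileext = ".csv"); fz <- tempfile(fileext = ".csv")
  write_waveform_csv(wf, fy, fz)
  back <- utils::read.csv(fy)
  expect_equal(back$g_mT_per_m, wf$gy, tolerance = 1e-12)
  expect_equal(names(back), c("t_ms", "g_mT_per_m"))
  unlink(c(fy, fz))
})
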