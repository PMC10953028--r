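test_that("phantom generation is deterministic and honours the specification", {
  spec <- phantom_spec(dims = c(32, 32, 16), n_vessels = 4,
                       vessel_radius = c(6, 10), seed = 11)
  p1 <- make_vessel_phantom(spec)
  p2 <- make_vessel_phantom(spec)
  expect_identical(p1$magnitude, p2$magnitude)
  expect_identical(p1$velocity, p2$velocity)
  # velocity confined to vessels; magnitude non-negative
  vmat <- matrix(p1$velocity, ncol = 3)
  moving <- rowSums(vmat^2) > 0
  expect_true(all(p1$vessel_labels[moving]))
  expect_true(all(p1$magnitude >= 0))
  expect_true(all(p1$magnitude[!p1$support] == 0))
  # vessels are brighter than the background (TOF contrast)
  expect_gt(mean(p1$magnitude[p1$vessel_labels]),
            2 * mean(p1$magnitude[p1$support & !p1$vessel_labels]))
  # no vessels requested
  p0 <- make_vessel_phantom(phantom_spec(dims = c(16, 16, 16), n_vessels = 0))
  expect_false(any(p0$vessel_labels))
  expect_true(all(p0$velocity == 0))
  expect_error(phantom_spec(dims = c(8, 16, 16)), ">= 16")
  expect_error(phantom_spec(vessel_intensity = 0.1,
                            background_intensity = 0.25), "contrast")
})

test_that("vessel volume fraction agrees with the analytic tube estimate", {
  spec <- phantom_spec(dims = c(32, 32, 16), fov = c(200, 200, 48),
                       n_vessels = 5, vessel_radius = c(8, 12), seed = 21)
  ph <- make_vessel_phantom(spec)
  # tubes run through the slab: sum of pi r_mean^2 L over vessels, with the
  # default taper to 0.6 r0 giving a mean squared radius of ~0.66 r0^2
  r_mean2 <- mean(seq(1, 0.6, length.out = 100)^2) * mean(c(8, 12))^2
  est <- spec$n_vessels * pi * r_mean2 * spec$fov[3] / prod(spec$fov)
  got <- mean(ph$vessel_labels)
  expect_gt(got, 0.5 * est)
  expect_lt(got, 2 * est)
})

test_that("simulated coil maps are normalized, distinct and degenerate to a single coil", {
  dims <- c(16, 16, 16)
  supp <- array(TRUE, dims)
  cm <- make_coil_maps(8, dims, supp, c(160, 160, 48))
  rss <- sqrt(apply(Mod(cm$maps)^2, 1:3, sum))
  expect_lt(max(abs(rss[supp] - 1)), 1e-6)
  # pairwise correlation below 0.999: distinct spatial profiles
  flat <- matrix(Mod(cm$maps), ncol = 8)
  cc <- cor(flat)
  expect_lt(max(cc[upper.tri(cc)]), 0.999)
  cm1 <- make_coil_maps(1, dims, supp, c(160, 160, 48))
  expect_true(all(cm1$maps[, , , 1][supp] == 1 + 0i))
})

test_that("low-resolution calibration recovers the coil maps", {
  # broad sensitivity profiles, the regime of a low-resolution reference
  # scan whose k-space support fits inside the calibration block
  dims <- c(32, 32, 16); fov <- c(200, 200, 48)
  spec <- phantom_spec(dims = dims, fov = fov, n_vessels = 3,
                       vessel_radius = c(6, 10), seed = 2)
  ph <- make_vessel_phantom(spec)
  co <- wavemra:::voxel_coords(dims, fov)
  maps <- array(0i, c(dims, 4))
  for (c in 1:4) {
    th <- 2 * pi * (c - 1) / 4
    d2 <- outer(outer((co[[1]] - 130 * cos(th))^2,
                      (co[[2]] - 130 * sin(th))^2, "+"), 0 * co[[3]], "+")
    maps[, , , c] <- exp(-d2 / (2 * 150^2)) * exp(2i * pi * (c - 1) / 4)
  }
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  for (c in 1:4) {
    m <- maps[, , , c] / rss; m[!ph$support] <- 0i; maps[, , , c] <- m
  }
  cm <- coil_maps(maps, ph$support)
  sim <- simulate_acquisition(ph, cm, wave = NULL, mask = NULL,
                              noise_sigma = 0, flow_on = FALSE)
  est <- estimate_coil_maps_lowres(sim$data, calib_size = 16)
  rss_e <- sqrt(apply(Mod(est$maps)^2, 1:3, sum))
  expect_lt(max(abs(rss_e[est$support] - 1)), 1e-6)
  # compare inside the common support, modulo a global phase per coil
  common <- est$support & ph$support
  errs <- sapply(1:4, function(c) {
    a <- est$maps[, , , c][common]; b <- cm$maps[, , , c][common]
    phs <- sum(Conj(a) * b); phs <- phs / Mod(phs)
    sqrt(sum(Mod(a * phs - b)^2) / sum(Mod(b)^2))
  })
  expect_lt(max(errs), 0.05)
  # a single uniform coil comes back as a unit map on the support
  m1 <- array(0i, c(dims, 1)); m1[, , , 1][ph$support] <- 1 + 0i
  cm1 <- coil_maps(m1, ph$support)
  sim1 <- simulate_acquisition(ph, cm1, wave = NULL, mask = NULL,
                               noise_sigma = 0, flow_on = FALSE)
  est1 <- estimate_coil_maps_lowres(sim1$data, calib_size = 16)
  inner <- !wavemra:::dilate_mask(!ph$support, 2) & est1$support
  a <- est1$maps[, , , 1][inner]
  phs <- sum(Conj(a)); phs <- phs / Mod(phs)
  expect_lt(max(Mod(a * phs - 1)), 0.05)
  expect_error(estimate_coil_maps_lowres(sim$data, calib_size = 4), "small")
})

test_that("acquisition simulation matches the encoding operator without flow", {
  sp <- small_phantom(dims = c(16, 16, 16), n_coils = 4, noise_sigma = 0)
  wp <- wave_params(1, 4, 250, 16, os_factor = 2, slew_limit = 1e5)
  sim <- simulate_acquisition(sp$phantom, sp$coils, wave = wp, mask = NULL,
                              noise_sigma = 0, flow_on = FALSE)
  direct <- encode_forward(sp$phantom$magnitude + 0i, sim$op)
  expect_identical(sim$data, direct)
  # flow flag with zero velocities changes nothing
  ph0 <- sp$phantom
  ph0$velocity[] <- 0
  sim0 <- simulate_acquisition(ph0, sp$coils, wave = wp, mask = NULL,
                               noise_sigma = 0, flow_on = TRUE)
  expect_equal(sim0$data, direct, tolerance = 1e-12)
  # fixed seed reproduces the noisy acquisition bit-identically
  simn1 <- simulate_acquisition(sp$phantom, sp$coils, wave = wp, mask = NULL,
                                noise_sigma = 0.05, flow_on = FALSE, seed = 3)
  simn2 <- simulate_acquisition(sp$phantom, sp$coils, wave = wp, mask = NULL,
                                noise_sigma = 0.05, flow_on = FALSE, seed = 3)
  expect_identical(simn1$data, simn2$data)
})

test_that("flow simulation matches a hand-rolled per-sample signal oracle", {
  # two-voxel toy: one static, one flowing
  dims <- c(8, 8, 4)
  fov <- c(80, 80, 40)
  supp <- array(TRUE, dims)
  maps <- array(0i, c(dims, 1)); maps[, , , 1] <- 1 + 0i
  cm <- coil_maps(maps, supp)
  spec <- phantom_spec(dims = c(16, 16, 16))   # only for class shape
  wp <- wave_params(5, 3, 500, 8, os_factor = 2, slew_limit = 1e5)
  ph <- structure(list(
    magnitude = array(0, dims), vessel_labels = array(FALSE, dims),
    velocity = array(0, c(dims, 3)), support = supp,
    spec = structure(list(dims = dims, fov = fov, noise_sigma = 0),
                     class = "phantom_spec")), class = "digital_phantom")
  ph$magnitude[3, 4, 2] <- 1          # static voxel
  ph$magnitude[6, 7, 3] <- 0.8        # flowing voxel
  ph$vessel_labels[6, 7, 3] <- TRUE
  ph$velocity[6, 7, 3, ] <- c(0, 150, 250)
  sim <- simulate_acquisition(ph, cm, wave = wp, mask = NULL,
                              noise_sigma = 0, flow_on = TRUE)
  # oracle: direct per-sample DFT sum with the flow phase inserted
  tr <- nominal_trajectory(wp, fov[1])
  mom <- compute_moments(synthesize_waveforms(wp))
  phi <- flow_phase_series(mom, c(150, 250))
  nkx <- 16
  cx <- floor(nkx / 2); cy <- 4; cz <- 2
  dy <- fov[2] / 8 * 1e-3; dz <- fov[3] / 4 * 1e-3
  off <- (nkx - 8) / 2
  vox <- list(list(p = c(3, 4, 2), a = 1, fl = 0),
              list(p = c(6, 7, 3), a = 0.8, fl = 1))
  Ko <- array(0i, c(nkx, 8, 4, 1))
  for (i in 1:nkx) for (j in 1:8) for (l in 1:4) {
    s <- 0i
    for (v in vox) {
      phse <- (i - 1 - cx) * (v$p[1] + off - 1 - cx) / nkx +
        (j - 1 - cy) * (v$p[2] - 1 - cy) / 8 +
        (l - 1 - cz) * (v$p[3] - 1 - cz) / 4 +
        tr$ky_wave[i] * (v$p[2] - 1 - cy) * dy +
        tr$kz_wave[i] * (v$p[3] - 1 - cz) * dz
      s <- s + v$a * exp(-2i * pi * phse) * exp(1i * phi[i] * v$fl)
    }
    Ko[i, j, l, 1] <- s / sqrt(nkx * 8 * 4)
  }
  expect_lt(max(Mod(sim$data - Ko)), 1e-10)
})

test_that("background noise level propagates through the orthonormal pipeline", {
  dims <- c(16, 16, 16)
  supp <- array(TRUE, dims)
  maps <- array(0i, c(dims, 1)); maps[, , , 1] <- 1 + 0i
  cm <- coil_maps(maps, supp)
  empty <- structure(list(
    magnitude = array(0, dims), vessel_labels = array(FALSE, dims),
    velocity = array(0, c(dims, 3)), support = supp,
    spec = structure(list(dims = dims, fov = c(160, 160, 160),
                          noise_sigma = 0.04), class = "phantom_spec")),
    class = "digital_phantom")
  sim <- simulate_acquisition(empty, cm, wave = NULL, mask = NULL,
                              flow_on = FALSE, seed = 9)
  img <- zero_filled_recon(sim$data, sim$op)
  sd_img <- sqrt(mean(Mod(img)^2))
  expect_lt(abs(sd_img / 0.04 - 1), 0.05)
})

test_that("full pipeline recovers the phantom in wave and Cartesian modes", {
  sp <- small_phantom(dims = c(32, 32, 16), n_coils = 8, noise_sigma = 0)
  wp <- desk_wave_params(sp$spec, spread_frac = 0.45)
  for (wav in list(wp, NULL)) {
    sim <- simulate_acquisition(sp$phantom, sp$coils, wave = wav,
                                mask = NULL, noise_sigma = 0, flow_on = FALSE)
    rec <- recon_least_squares(sim$data, sim$op,
                               recon_params(ls_tol = 1e-6, ls_maxiter = 50))
    expect_lt(nrmse(rec$image[sp$phantom$support],
                    sp$phantom$magnitude[sp$phantom$support]), 0.005)
  }
})

test_that("ghost-to-signal ratio isolates readout-line ghosting", {
  dims <- c(16, 16, 16)
  supp <- array(TRUE, dims)
  vessel <- array(FALSE, dims); vessel[8:9, 8, 8] <- TRUE
  vol <- array(0.001, dims)
  vol[vessel] <- 1
  base <- ghost_to_signal_ratio(vol, vessel, supp, margin = 2)
  expect_lt(base, 0.01)
  # put energy on the same readout line outside the margin -> ratio rises
  vol2 <- vol; vol2[c(2, 14), 8, 8] <- 0.3
  expect_gt(ghost_to_signal_ratio(vol2, vessel, supp, margin = 2), base)
  # energy on other lines does not count
  vol3 <- vol; vol3[2, 2, 2] <- 0.5
  expect_equal(ghost_to_signal_ratio(vol3, vessel, supp, margin = 2), base)
  expect_error(ghost_to_signal_ratio(vol, array(FALSE, dims), supp), "empty")
})
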