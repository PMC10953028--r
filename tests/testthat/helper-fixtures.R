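# Shared fixtures: all built in code at test time.

nrmse <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

cplx_array <- function(dims, seed = 1) {
  withr::with_seed(seed, {
    array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
          dims)
  })
}

# Random RSS-normalized coil maps on a full support (for operator algebra
# tests; smoothness is irrelevant there).
random_coils <- function(dims, n_coil, seed = 1) {
  maps <- cplx_array(c(dims, n_coil), seed)
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  for (c in seq_len(n_coil)) maps[, , , c] <- maps[, , , c] / rss
  coil_maps(maps, array(TRUE, dims))
}

# Small wave operator used across encoding/recon tests.
tiny_wave_op <- function(dims = c(8, 8, 4), n_coil = 2, os = 2,
                         fov = c(160, 160, 40), R_y = 1, R_z = 1, shift = 0,
                         g_max = 6, n_cyc = 3, seed = 1) {
  cm <- random_coils(dims, n_coil, seed)
  wp <- wave_params(g_max = g_max, n_cyc = n_cyc, bw_per_pixel = 500,
                    n_read = dims[1], os_factor = os, slew_limit = 1e5)
  tr <- nominal_trajectory(wp, fov_x = fov[1])
  psf <- build_psf(tr, fov[2], fov[3], dims[2], dims[3])
  msk <- caipi_mask(dims[2], dims[3], R_y, R_z, shift)
  encoding_operator(cm, msk, psf, os, fov)
}

# Small phantom + smooth coils for pipeline-level tests.
small_phantom <- function(dims = c(32, 32, 16), n_coils = 8,
                          noise_sigma = 0.01, seed = 1, n_vessels = 4,
                          vessel_radius = c(5, 8), fov = c(200, 200, 48)) {
  spec <- phantom_spec(dims = dims, fov = fov, n_vessels = n_vessels,
                       vessel_radius = vessel_radius, n_coils = n_coils,
                       noise_sigma = noise_sigma, seed = seed)
  ph <- make_vessel_phantom(spec)
  coils <- make_coil_maps(n_coils, dims, ph$support, fov)
  list(spec = spec, phantom = ph, coils = coils)
}

# Deterministic structured test image pair shared with the SSIM oracle
# cross-check (values frozen from an independent reference implementation).
ssim_fixture <- function() {
  withr::with_seed(99, {
    n <- 40
    a <- matrix(0, n, n)
    for (k in 1:6) {
      cx <- runif(1, 8, n - 8); cy <- runif(1, 8, n - 8); s <- runif(1, 2, 6)
      xg <- outer((1:n - cx)^2, (1:n - cy)^2, "+")
      a <- a + runif(1, 0.3, 1) * exp(-xg / (2 * s^2))
    }
    b <- a + matrix(rnorm(n * n, sd = 0.1), n, n)
    list(a = a, b = b, neg = max(a) - a)
  })
}
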