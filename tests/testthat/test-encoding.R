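test_that("hybrid PSF is unit-modulus and trivial for a zero trajectory", {
  wp <- wave_params(6, 3, 500, 8, os_factor = 2, slew_limit = 1e5)
  tr <- nominal_trajectory(wp, 160)
  psf <- build_psf(tr, 160, 40, 8, 4)
  expect_equal(dim(psf$psf), c(16, 8, 4))
  expect_lt(max(abs(Mod(psf$psf) - 1)), 1e-12)
  tr0 <- nominal_trajectory(wave_params(0, 3, 500, 8), 160)
  psf0 <- build_psf(tr0, 160, 40, 8, 4)
  expect_true(all(psf0$psf == 1 + 0i))
})

test_that("forward encoding matches a brute-force non-uniform DFT oracle", {
  dims <- c(8, 8, 4); os <- 2; nkx <- dims[1] * os
  fov <- c(160, 160, 40)
  op <- tiny_wave_op(dims, n_coil = 2, os = os, fov = fov, R_y = 2, R_z = 2,
                     shift = 1)
  tr <- op$psf$traj
  img <- cplx_array(dims, seed = 4)
  K <- encode_forward(img, op)
  cx <- floor(nkx / 2); cy <- floor(dims[2] / 2); cz <- floor(dims[3] / 2)
  dy <- fov[2] / dims[2] * 1e-3; dz <- fov[3] / dims[3] * 1e-3
  off <- (nkx - dims[1]) / 2
  Ko <- array(0i, dim(K))
  for (co in 1:2) for (i in 1:nkx) for (j in 1:dims[2]) for (l in 1:dims[3]) {
    if (op$mask$grid[j, l] == 0) next
    s <- 0i
    for (p in 1:dims[1]) for (q in 1:dims[2]) for (r in 1:dims[3]) {
      ph <- (i - 1 - cx) * (p + off - 1 - cx) / nkx +
        (j - 1 - cy) * (q - 1 - cy) / dims[2] +
        (l - 1 - cz) * (r - 1 - cz) / dims[3] +
        tr$ky_wave[i] * (q - 1 - cy) * dy +
        tr$kz_wave[i] * (r - 1 - cz) * dz
      s <- s + op$coils$maps[p, q, r, co] * img[p, q, r] * exp(-2i * pi * ph)
    }
    Ko[i, j, l, co] <- s / sqrt(nkx * dims[2] * dims[3])
  }
  expect_lt(max(Mod(K - Ko)), 1e-10)
  # masked-out columns are exactly zero
  Km <- matrix(K, nrow = nkx)
  sel <- rep(as.vector(op$mask$grid) == 0, 2)    # per coil
  expect_true(all(Km[, sel] == 0i))
  # linearity
  img2 <- cplx_array(dims, seed = 9)
  expect_lt(max(Mod(encode_forward(img + 2i * img2, op) -
                      (K + 2i * encode_forward(img2, op)))), 1e-12)
})

test_that("adjoint passes the inner-product test and matches the dense conjugate transpose", {
  op <- tiny_wave_op(c(4, 4, 2), n_coil = 2, os = 2, R_y = 2, R_z = 1,
                     shift = 0)
  n_img <- 4 * 4 * 2
  kd <- c(8, 4, 2, 2)
  # dense matrix from forward applied to unit vectors
  A <- matrix(0i, prod(kd), n_img)
  for (j in seq_len(n_img)) {
    e <- array(0i, c(4, 4, 2)); e[j] <- 1
    A[, j] <- as.vector(encode_forward(e, op))
  }
  # adjoint from the conjugate transpose
  y <- cplx_array(kd, seed = 3)
  adj_dense <- array(Conj(t(A)) %*% as.vector(y), c(4, 4, 2))
  expect_lt(max(Mod(encode_adjoint(y, op) - adj_dense)), 1e-10)
  # inner-product identity on random vectors
  x <- cplx_array(c(4, 4, 2), seed = 5)
  ip1 <- sum(Conj(encode_forward(x, op)) * y)
  ip2 <- sum(Conj(x) * encode_adjoint(y, op))
  expect_lt(Mod(ip1 - ip2) / Mod(ip1), 1e-10)
})

test_that("a delta image round-trips through forward/adjoint at full sampling", {
  dims <- c(8, 8, 4)
  cm <- coil_maps({
    m <- array(0i, c(dims, 1)); m[, , , 1] <- 1 + 0i; m
  }, array(TRUE, dims))
  wp <- wave_params(6, 3, 500, 8, os_factor = 2, slew_limit = 1e5)
  tr <- nominal_trajectory(wp, 160)
  psf <- build_psf(tr, 160, 40, 8, 4)
  op <- encoding_operator(cm, NULL, psf, 2, c(160, 160, 40))
  delta <- array(0i, dims); delta[3, 5, 2] <- 1
  img <- encode_adjoint(encode_forward(delta, op), op)
  expect_equal(which.max(Mod(img)), which.max(Mod(delta)))
  # with unit coil and full sampling the operator is an isometry
  expect_lt(max(Mod(img - delta)), 1e-12)
})

test_that("degenerate wave reduces to the standard Fourier transform", {
  dims <- c(8, 8, 4)
  cm <- coil_maps({
    m <- array(0i, c(dims, 1)); m[, , , 1] <- 1 + 0i; m
  }, array(TRUE, dims))
  op <- encoding_operator(cm, NULL, NULL, 1, c(160, 160, 40))
  img <- cplx_array(dims, seed = 7)
  K <- encode_forward(img, op)
  oracle <- wavemra:::fft_axis(
    wavemra:::fft_axis(wavemra:::fft_axis(img, 1), 2), 3)
  expect_lt(max(Mod(array(K, dims) - oracle)), 1e-12)
})

test_that("PSF deconvolution synthesizes the Cartesian dataset exactly", {
  dims <- c(8, 8, 4)
  op <- tiny_wave_op(dims, n_coil = 2, os = 2)
  img <- cplx_array(dims, seed = 11)
  K <- encode_forward(img, op)
  kc <- deconvolve_to_cartesian(K, op)
  opc <- cartesian_operator(op)
  Kc_direct <- encode_forward(img, opc)
  expect_lt(max(Mod(kc - Kc_direct)), 1e-12)
  # identity PSF: deconvolution only crops the readout oversampling
  opn <- encoding_operator(op$coils, NULL, NULL, 2, op$fov)
  Kn <- encode_forward(img, opn)
  kc2 <- deconvolve_to_cartesian(Kn, opn)
  expect_lt(max(Mod(kc2 - encode_forward(img, cartesian_operator(opn)))),
            1e-12)
  # refuses undersampled input
  opm <- tiny_wave_op(dims, n_coil = 2, os = 2, R_y = 2)
  expect_error(deconvolve_to_cartesian(K, opm), "fully sampled")
})

test_that("readout oversampling prevents wrap-around of edge point sources", {
  dims <- c(16, 16, 4)
  fov <- c(160, 160, 40)
  cm <- coil_maps({
    m <- array(0i, c(dims, 1)); m[, , , 1] <- 1 + 0i; m
  }, array(TRUE, dims))
  # spread chosen below (os - 1) * fov_x / 2 so nothing wraps at os = 2
  wp <- wave_params(0.7, 3, 500, 16, os_factor = 2, slew_limit = 1e5)
  spread <- psf_spread_extent(wp, fov[1], fov[2], fov[3])
  expect_lt(spread, (2 - 1) * fov[1] / 2)
  tr <- nominal_trajectory(wp, fov[1])
  psf <- build_psf(tr, fov[2], fov[3], dims[2], dims[3])
  op <- encoding_operator(cm, NULL, psf, 2, fov)
  src <- array(0i, dims); src[1, 16, 4] <- 1      # corner voxel
  # energy in the physical window x in [20, 80] mm, where displaced copies
  # of the corner source (spread range [-140, -20] mm) would wrap to
  band_energy <- function(K, os) {
    h <- wavemra:::fft_axis(wavemra:::fft_axis(K, 3, TRUE), 2, TRUE)
    prof <- apply(Mod(wavemra:::fft_axis(h, 1, TRUE))^2, 1, sum)
    n <- length(prof)
    x <- ((0:(n - 1)) - floor(n / 2)) * 10   # mm, voxel pitch 10
    sum(prof[x >= 20 & x <= 80]) / sum(prof)
  }
  r2 <- band_energy(encode_forward(src, op), 2)
  # only finite-aperture leakage remains there when oversampling covers
  # the spread
  expect_lt(r2, 1e-2)
  # without oversampling the displaced corner source wraps outright
  psf1 <- build_psf(tr, fov[2], fov[3], dims[2], dims[3])
  psf1$psf <- psf1$psf[seq(1, 32, by = 2), , , drop = FALSE]
  op1 <- encoding_operator(cm, NULL, psf1, 1, fov)
  r1 <- band_energy(encode_forward(src, op1), 1)
  expect_gt(r1, 20 * r2)
})

test_that("masking in the operator is idempotent", {
  op <- tiny_wave_op(c(8, 8, 4), n_coil = 2, os = 2, R_y = 2, R_z = 2,
                     shift = 1)
  img <- cplx_array(c(8, 8, 4), seed = 2)
  K <- encode_forward(img, op)
  expect_identical(wavemra:::apply_mask(K, op$mask$grid), K)
})
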