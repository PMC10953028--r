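# The wave encoding forward model
#
#   k = M . F_z . F_y . PSF . F_x . C . s
#
# Coil weighting (C), readout FFT into hybrid (kx, y, z) space (F_x), the
# unit-modulus wave PSF modulation, phase/partition FFTs (F_y, F_z) and the
# (ky, kz) sampling mask (M).  All FFTs are centered and orthonormal, so the
# adjoint used by the iterative solvers is exact.

#' Coil sensitivity map container
#'
#' @param maps Complex array (nx, ny, nz, n_coil).
#' @param support Logical array (nx, ny, nz): object support. Maps are zero
#'   outside support and root-sum-of-squares normalized on it.
#' @return Object of class `coil_maps`.
#' @export
coil_maps <- function(maps, support) {
  d <- dim(maps)
  stopifnot(length(d) == 4, all(dim(support) == d[1:3]))
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  if (max(rss) > 1 + 1e-6)
    stop("coil maps must have root-sum-of-squares <= 1")
  structure(list(maps = maps, support = (support != 0), n_coil = d[4]),
            class = "coil_maps")
}

#' @export
print.coil_maps <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("Coil maps: %d coils on a %d x %d x %d grid (%.1f%% support)\n",
              d[4], d[1], d[2], d[3], 100 * mean(x$support)))
  invisible(x)
}

#' Hybrid-space point spread function of the wave gradients
#'
#' The PSF is the unit-modulus modulation
#' `psf[kx, y, z] = exp(-i 2 pi (ky_wave(kx) y + kz_wave(kx) z))`
#' applied in hybrid (kx, y, z) space, where (y, z) are the physical voxel
#' coordinates centered on the FOV.  It is identically 1 when the trajectory
#' deflections vanish.
#'
#' @param traj A `wave_trajectory` (nominal or calibrated).
#' @param fov_y,fov_z Fields of view in mm.
#' @param n_y,n_z Grid sizes along y and z.
#' @return Object of class `hybrid_psf` holding the complex array
#'   (n_kx, n_y, n_z).
#' @export
build_psf <- function(traj, fov_y, fov_z, n_y, n_z) {
  stopifnot(inherits(traj, "wave_trajectory"))
  nk <- length(traj$ky_wave)
  y <- ((0:(n_y - 1)) - floor(n_y / 2)) * (fov_y / n_y) * 1e-3   # m
  z <- ((0:(n_z - 1)) - floor(n_z / 2)) * (fov_z / n_z) * 1e-3
  phy <- outer(traj$ky_wave, y)                 # nk x ny, cycles
  phz <- outer(traj$kz_wave, z)                 # nk x nz
  psf <- array(0i, c(nk, n_y, n_z))
  for (l in seq_len(n_z))
    psf[, , l] <- exp(-2i * pi * (phy + phz[, l]))
  structure(list(psf = psf, fov_y = fov_y, fov_z = fov_z, traj = traj),
            class = "hybrid_psf")
}

#' @export
print.hybrid_psf <- function(x, ...) {
  d <- dim(x$psf)
  cat(sprintf("Hybrid-space wave PSF on a %d x %d x %d (kx, y, z) grid\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Wave/Cartesian SENSE encoding operator
#'
#' Bundles the sampling mask, the hybrid-space PSF (or `NULL` for Cartesian
#' encoding), the coil maps and the grid geometry into the linear operator of
#' the reconstruction problem.  With `psf = NULL` and full sampling the
#' operator reduces to ordinary Cartesian SENSE encoding.
#'
#' @param coils A [coil_maps()] object on the nominal grid.
#' @param mask A `sampling_mask` over (ky, kz), or `NULL` for full sampling.
#' @param psf A `hybrid_psf`, or `NULL` for Cartesian (no wave) encoding.
#' @param os_factor Readout oversampling factor of the k-space data; must
#'   match the PSF's kx length when a PSF is given.
#' @param fov Length-3 numeric FOV in mm (x, y, z).
#' @return Object of class `encoding_operator`.
#' @export
encoding_operator <- function(coils, mask = NULL, psf = NULL, os_factor = 1,
                              fov = c(200, 200, 48)) {
  stopifnot(inherits(coils, "coil_maps"))
  d <- dim(coils$maps)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  if (is.null(mask)) mask <- new_sampling_mask(matrix(1L, ny, nz), 1, "full")
  stopifnot(inherits(mask, "sampling_mask"),
            nrow(mask$grid) == ny, ncol(mask$grid) == nz)
  nkx <- as.integer(round(nx * os_factor))
  if (!is.null(psf)) {
    stopifnot(inherits(psf, "hybrid_psf"))
    dp <- dim(psf$psf)
    if (dp[1] != nkx || dp[2] != ny || dp[3] != nz)
      stop(sprintf("PSF grid (%d, %d, %d) does not match operator grid (%d, %d, %d)",
                   dp[1], dp[2], dp[3], nkx, ny, nz))
    if (max(abs(Mod(psf$psf) - 1)) > 1e-9)
      stop("PSF must be unit-modulus")
  }
  structure(list(coils = coils, mask = mask, psf = psf,
                 nx = nx, ny = ny, nz = nz, nkx = nkx,
                 os_factor = os_factor, n_coil = coils$n_coil, fov = fov),
            class = "encoding_operator")
}

#' @export
print.encoding_operator <- function(x, ...) {
  cat(sprintf("%s encoding operator: %d x %d x %d grid, %d coils, kx oversampling x%g, R = %.3g\n",
              if (is.null(x$psf)) "Cartesian" else "Wave",
              x$nx, x$ny, x$nz, x$n_coil, x$os_factor, x$mask$R_achieved))
  invisible(x)
}

#' @keywords internal
apply_mask <- function(k, mask_grid) {
  d <- dim(k)
  dim(k) <- c(d[1], prod(d[-1]))
  k[, rep(as.vector(mask_grid) == 0, length.out = ncol(k))] <- 0i
  dim(k) <- d
  k
}

# Coil-weight an image and carry it to hybrid (kx, y, z) space, including the
# PSF modulation.  Returns (nkx, ny, nz, n_coil); all steps act on the full
# coil stack at once.
#' @keywords internal
image_to_hybrid <- function(img, op) {
  w <- array(img + 0i, c(op$nx, op$ny, op$nz, op$n_coil)) * op$coils$maps
  w <- pad_axis1(w, op$nkx)
  w <- fft_axis(w, 1)
  if (!is.null(op$psf)) w <- w * as.vector(op$psf$psf)
  w
}

#' @keywords internal
hybrid_to_kspace <- function(h, op) {
  k <- fft_axis(fft_axis(h, 2), 3)
  apply_mask(k, op$mask$grid)
}

#' Forward wave encoding
#'
#' Applies the full encoding chain to a complex image on the nominal grid:
#' coil weighting, zero-padding into the oversampled readout grid, readout
#' FFT, PSF modulation in hybrid space, phase/partition FFTs and sampling
#' mask.
#'
#' @param img Complex (or numeric) array (nx, ny, nz).
#' @param op An [encoding_operator()].
#' @return Complex k-space array (nkx, ny, nz, n_coil); masked-out (ky, kz)
#'   columns are exactly zero.
#' @export
encode_forward <- function(img, op) {
  stopifnot(inherits(op, "encoding_operator"))
  if (!all(dim(img) == c(op$nx, op$ny, op$nz)))
    stop("image dimensions do not match the operator grid")
  hybrid_to_kspace(image_to_hybrid(img, op), op)
}

#' Adjoint wave encoding
#'
#' Exact conjugate-transpose of [encode_forward()] (mask, inverse
#' phase/partition FFTs, conjugate PSF, inverse readout FFT, center crop,
#' conjugate coil combination).
#'
#' @param kspace Complex array (nkx, ny, nz, n_coil).
#' @param op The matching [encoding_operator()].
#' @return Complex image array (nx, ny, nz).
#' @export
encode_adjoint <- function(kspace, op) {
  stopifnot(inherits(op, "encoding_operator"))
  if (!all(dim(kspace) == c(op$nkx, op$ny, op$nz, op$n_coil)))
    stop("k-space dimensions do not match the operator")
  k <- apply_mask(kspace, op$mask$grid)
  h <- fft_axis(fft_axis(k, 3, inverse = TRUE), 2, inverse = TRUE)
  if (!is.null(op$psf)) h <- h * Conj(as.vector(op$psf$psf))
  x <- crop_axis1(fft_axis(h, 1, inverse = TRUE), op$nx)
  x <- Conj(op$coils$maps) * x
  array(rowSums(matrix(x, ncol = op$n_coil)), c(op$nx, op$ny, op$nz))
}

#' Synthesize Cartesian k-space from fully sampled wave data
#'
#' Deconvolves fully sampled wave-encoded k-space by the (unit-modulus) PSF:
#' transform to hybrid (kx, y, z) space, multiply by the conjugate PSF,
#' transform back, and crop the readout oversampling to the nominal FOV.
#' The result is the Cartesian reference dataset used for retrospective
#' comparisons.
#'
#' @param kspace Fully sampled wave k-space (nkx, ny, nz, n_coil).
#' @param op The wave [encoding_operator()] that produced it (its mask must
#'   be full).
#' @return Cartesian k-space array (nx, ny, nz, n_coil).
#' @export
deconvolve_to_cartesian <- function(kspace, op) {
  stopifnot(inherits(op, "encoding_operator"))
  if (any(op$mask$grid == 0))
    stop("deconvolution is only defined for fully sampled wave data")
  if (!all(dim(kspace) == c(op$nkx, op$ny, op$nz, op$n_coil)))
    stop("k-space dimensions do not match the operator")
  h <- fft_axis(fft_axis(kspace, 3, inverse = TRUE), 2, inverse = TRUE)
  if (!is.null(op$psf)) h <- h * Conj(as.vector(op$psf$psf))
  x <- crop_axis1(fft_axis(h, 1, inverse = TRUE), op$nx)
  fft_axis(fft_axis(fft_axis(x, 1), 2), 3)
}

#' Cartesian counterpart of a wave encoding operator
#'
#' Drops the PSF and the readout oversampling, optionally replacing the
#' sampling mask; used for reconstructing the synthesized Cartesian
#' reference and conventional (non-wave) acquisitions.
#'
#' @param op A wave [encoding_operator()].
#' @param mask Optional replacement `sampling_mask`.
#' @return A Cartesian `encoding_operator`.
#' @export
cartesian_operator <- function(op, mask = NULL) {
  encoding_operator(op$coils, mask = if (is.null(mask)) op$mask else mask,
                    psf = NULL, os_factor = 1, fov = op$fov)
}

#' Replace the sampling mask of an encoding operator
#'
#' @param op An [encoding_operator()].
#' @param mask The new `sampling_mask`.
#' @return The operator with the new mask.
#' @export
with_mask <- function(op, mask) {
  stopifnot(inherits(op, "encoding_operator"), inherits(mask, "sampling_mask"))
  op$mask <- mask
  op
}
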