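#' @keywords internal
new_sampling_mask <- function(grid, R_nominal, kind, calib_size = 0, seed = NA) {
  grid <- (grid != 0) * 1L
  structure(list(grid = grid, R_nominal = R_nominal,
                 R_achieved = length(grid) / sum(grid),
                 kind = kind, calib_size = calib_size, seed = seed),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("%s sampling mask %d x %d: R nominal %.3g, achieved %.3g (%d samples)\n",
              x$kind, nrow(x$grid), ncol(x$grid), x$R_nominal, x$R_achieved,
              sum(x$grid)))
  invisible(x)
}

#' 2D-CAIPIRINHA undersampling mask
#'
#' Staggered-lattice undersampling of the (ky, kz) plane: a point (ky, kz)
#' (0-based indices) is sampled iff `ky mod R_y == 0` and
#' `kz mod R_z == ((ky / R_y) * caipi_shift) mod R_z`.  The row-dependent
#' shift spreads aliasing along both phase directions (controlled aliasing);
#' the shifted lattices used by default for R = 4, 6, 8 are (R_y, R_z,
#' shift) = (2, 2, 1), (2, 3, 1), (2, 4, 1), the patterns with the lowest
#' mean g-factor among lattices of equal acceleration.
#'
#' @param n_ky,n_kz Grid dimensions.
#' @param R_y,R_z Acceleration factors along ky and kz (total R = R_y R_z).
#' @param caipi_shift Integer stagger in kz per sampled ky line
#'   (0 <= shift < R_z).
#' @return A `sampling_mask` of kind `"caipi"`.
#' @examples
#' caipi_mask(8, 8, 2, 2, 1)
#' @export
caipi_mask <- function(n_ky, n_kz, R_y, R_z, caipi_shift = 1) {
  if (R_y < 1 || R_z < 1 || R_y != round(R_y) || R_z != round(R_z))
    stop("R_y and R_z must be positive integers")
  if (caipi_shift < 0 || caipi_shift >= max(R_z, 1) ||
      caipi_shift != round(caipi_shift))
    stop("caipi_shift must be an integer in [0, R_z)")
  ky <- 0:(n_ky - 1); kz <- 0:(n_kz - 1)
  on_ky <- (ky %% R_y) == 0
  grid <- matrix(0L, n_ky, n_kz)
  for (i in which(on_ky)) {
    off <- ((ky[i] %/% R_y) * caipi_shift) %% R_z
    grid[i, (kz %% R_z) == off] <- 1L
  }
  new_sampling_mask(grid, R_y * R_z, "caipi")
}

#' Default CAIPI lattice factorization for a total acceleration factor
#'
#' @param R Total acceleration (1, 2, 4, 6 or 8).
#' @return List with `R_y`, `R_z`, `shift`.
#' @export
caipi_default_lattice <- function(R) {
  tab <- list(`1` = c(1, 1, 0), `2` = c(2, 1, 0), `4` = c(2, 2, 1),
              `6` = c(2, 3, 1), `8` = c(2, 4, 1))
  v <- tab[[as.character(R)]]
  if (is.null(v)) stop("no default lattice for R = ", R)
  list(R_y = v[1], R_z = v[2], shift = v[3])
}

#' Variable-density Poisson-disc undersampling mask
#'
#' Pseudorandom dart-throwing with an exclusion radius that grows linearly
#' with k-space radius, `r(k) = r0 (1 + alpha |k| / |k|_max)`, giving the
#' denser sampling of the k-space center needed for compressed sensing.
#' `r0` is solved by bisection so the achieved acceleration lands within 5%
#' of the target.  An optional fully sampled calibration block is kept at
#' the center.  Reproducible for a fixed seed.
#'
#' @param n_ky,n_kz Grid dimensions.
#' @param R Target acceleration factor (>= 1).
#' @param calib_size Edge length of the fully sampled central block (0 = none).
#' @param seed RNG seed.
#' @param alpha Density-gradient parameter of the radius law.
#' @return A `sampling_mask` of kind `"poisson"`.
#' @export
poisson_disc_mask <- function(n_ky, n_kz, R, calib_size = 0, seed = 1,
                              alpha = 2) {
  if (R < 1) stop("R must be >= 1")
  if (R == 1) return(new_sampling_mask(matrix(1L, n_ky, n_kz), 1, "poisson",
                                       calib_size, seed))
  cy <- floor(n_ky / 2); cz <- floor(n_kz / 2)
  kyg <- matrix(0:(n_ky - 1), n_ky, n_kz) - cy
  kzg <- matrix(0:(n_kz - 1), n_ky, n_kz, byrow = TRUE) - cz
  krad <- sqrt(kyg^2 + kzg^2)
  krad <- krad / max(krad)
  calib <- matrix(FALSE, n_ky, n_kz)
  if (calib_size > 0) {
    iy <- which(kyg[, 1] >= -floor(calib_size / 2) &
                  kyg[, 1] < ceiling(calib_size / 2))
    iz <- which(kzg[1, ] >= -floor(calib_size / 2) &
                  kzg[1, ] < ceiling(calib_size / 2))
    calib[iy, iz] <- TRUE
  }
  gen <- function(r0) {
    with_seed(seed, {
      rloc <- r0 * (1 + alpha * krad)
      acc <- calib
      pts_y <- integer(0); pts_z <- integer(0); pts_r <- numeric(0)
      if (any(calib)) {
        w <- which(calib, arr.ind = TRUE)
        pts_y <- w[, 1]; pts_z <- w[, 2]
        pts_r <- rloc[calib]
      }
      order_idx <- sample.int(n_ky * n_kz)
      for (idx in order_idx) {
        if (acc[idx]) next
        iy <- (idx - 1) %% n_ky + 1
        iz <- (idx - 1) %/% n_ky + 1
        rc <- rloc[idx]
        if (length(pts_y)) {
          d2 <- (pts_y - iy)^2 + (pts_z - iz)^2
          rmin <- pmin(rc, pts_r)
          if (any(d2 < rmin^2)) next
        }
        acc[idx] <- TRUE
        pts_y <- c(pts_y, iy); pts_z <- c(pts_z, iz); pts_r <- c(pts_r, rc)
      }
      acc
    })
  }
  target <- n_ky * n_kz / R
  lo <- 0.5; hi <- 2 * sqrt(R)          # r0 bracket in grid units
  best <- NULL
  for (it in 1:14) {
    mid <- (lo + hi) / 2
    acc <- gen(mid)
    n <- sum(acc)
    if (is.null(best) || abs(n - target) < abs(best$n - target))
      best <- list(acc = acc, n = n, r0 = mid)
    if (abs(n / target - 1) <= 0.02) break
    if (n > target) lo <- mid else hi <- mid
  }
  if (abs(best$n / target - 1) > 0.05)
    stop(sprintf("poisson_disc_mask: could not reach R = %g within 5%% (achieved %.2f)",
                 R, n_ky * n_kz / best$n))
  out <- new_sampling_mask(best$acc, R, "poisson", calib_size, seed)
  out$r0 <- best$r0
  out$alpha <- alpha
  out
}

#' Achieved acceleration factor of a mask
#'
#' @param mask A `sampling_mask` or binary matrix.
#' @return `n_total / n_sampled`.
#' @export
achieved_acceleration <- function(mask) {
  grid <- if (inherits(mask, "sampling_mask")) mask$grid else mask
  if (length(grid) == 0) stop("empty mask")
  n <- sum(grid != 0)
  if (n == 0) stop("mask samples no k-space positions")
  length(grid) / n
}
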