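#' Nominal corkscrew k-space trajectory
#'
#' Integrates the wave waveforms into k-space deflections
#' `ky_wave(t) = gamma int gy dt'`, `kz_wave(t) = gamma int gz dt'`
#' (cycles/m), and pairs them with the readout axis samples
#' `kx(t) = gamma G_read (t - T_read/2)`, symmetric about the echo.
#'
#' @param params A [wave_params()] object.
#' @param fov_x Readout field of view in mm (sets the readout gradient and
#'   hence the physical kx scale).
#' @return Object of class `wave_trajectory` with `t` (ms) and `kx`,
#'   `ky_wave`, `kz_wave` in cycles/m.
#' @export
nominal_trajectory <- function(params, fov_x = 200) {
  stopifnot(inherits(params, "wave_params"))
  wf <- synthesize_waveforms(params)
  trajectory_from_waveform(wf, fov_x)
}

#' Integrate an arbitrary wave waveform into a trajectory
#'
#' Same integration as [nominal_trajectory()] but starting from a waveform
#' that may include gradient-chain imperfections.
#'
#' @param wave A `gradient_waveform`.
#' @param fov_x Readout field of view in mm.
#' @return A `wave_trajectory`.
#' @export
trajectory_from_waveform <- function(wave, fov_x = 200) {
  stopifnot(inherits(wave, "gradient_waveform"))
  p <- wave$params
  t_s <- wave$t * 1e-3
  # gamma [Hz/T] * g [T/m] integrated over s -> cycles/m.  The deflections
  # are demeaned so the corkscrew is centered on the nominal Cartesian
  # readout line (equivalent to starting the wave gradient ahead of the ADC
  # window); a DC deflection would only add a linear image phase.
  ky <- p$gamma * pracma::cumtrapz(t_s, wave$gy * 1e-3)[, 1]
  kz <- p$gamma * pracma::cumtrapz(t_s, wave$gz * 1e-3)[, 1]
  ky <- ky - mean(ky)
  kz <- kz - mean(kz)
  g_read <- readout_gradient(p, fov_x) * 1e-3            # T/m
  kx <- p$gamma * g_read * (t_s - max(t_s) / 2)
  structure(list(t = wave$t, kx = kx, ky_wave = ky, kz_wave = kz,
                 fov_x = fov_x, params = p),
            class = "wave_trajectory")
}

#' @export
print.wave_trajectory <- function(x, ...) {
  cat(sprintf("Corkscrew trajectory: %d samples, peak deflection |ky| = %.2f, |kz| = %.2f cycles/m\n",
              length(x$t), max(abs(x$ky_wave)), max(abs(x$kz_wave))))
  invisible(x)
}

#' Gradient-chain imperfection description
#'
#' @param delay_us Timing delay per axis in microseconds (scalar or length-2
#'   for (y, z)).
#' @param eddy_amps Amplitudes of exponential eddy-current lag terms
#'   (fractions of the waveform, >= 0).
#' @param eddy_taus Matching time constants in ms (> 0).
#' @return Object of class `gradient_imperfection`.
#' @export
gradient_imperfection <- function(delay_us = 0, eddy_amps = numeric(0),
                                  eddy_taus = numeric(0)) {
  if (!all(is.finite(delay_us))) stop("delay must be finite")
  if (length(eddy_amps) != length(eddy_taus))
    stop("eddy_amps and eddy_taus must have equal length")
  if (any(eddy_taus <= 0)) stop("eddy time constants must be > 0")
  d <- if (length(delay_us) == 1) rep(delay_us, 2) else delay_us[1:2]
  structure(list(delay_us = d, eddy_amps = eddy_amps, eddy_taus = eddy_taus),
            class = "gradient_imperfection")
}

# Shift a sampled waveform by delay (ms) and blend in exponentially lagged
# copies: out = (1 - sum a_j) g(t - tau) + sum_j a_j (g(t - tau) * k_j)(t)
# with k_j a unit-area causal exponential kernel of time constant tau_j.
#' @keywords internal
distort_axis <- function(t, g, delay_ms, amps, taus) {
  xo <- t - delay_ms
  gs <- stats::spline(t, g, xout = xo)$y
  gs[xo < t[1] | xo > t[length(t)]] <- 0
  if (length(amps) == 0) return(gs)
  dt <- t[2] - t[1]
  out <- (1 - sum(amps)) * gs
  n <- length(t)
  for (j in seq_along(amps)) {
    m <- min(n, ceiling(taus[j] * 20 / dt))
    kern <- exp(-(0:(m - 1)) * dt / taus[j])
    kern <- kern / sum(kern)
    conv <- stats::convolve(gs, rev(kern), type = "open")[seq_len(n)]
    out <- out + amps[j] * conv
  }
  out
}

#' Apply gradient-chain imperfections to a waveform
#'
#' Time-shifts each axis by its delay and passes it through a sum of
#' decaying-exponential eddy-current kernels, producing the "actual"
#' waveform on the same ADC grid.  The waveform is assumed zero outside
#' the readout window.
#'
#' @param wave A `gradient_waveform`.
#' @param imp A [gradient_imperfection()].
#' @return A distorted `gradient_waveform`.
#' @export
apply_imperfection <- function(wave, imp) {
  stopifnot(inherits(wave, "gradient_waveform"),
            inherits(imp, "gradient_imperfection"))
  t_read <- max(wave$t)
  if (any(abs(imp$delay_us) * 1e-3 > t_read))
    stop("delay larger than the readout duration")
  wave$gy <- distort_axis(wave$t, wave$gy, imp$delay_us[1] * 1e-3,
                          imp$eddy_amps, imp$eddy_taus)
  wave$gz <- distort_axis(wave$t, wave$gz, imp$delay_us[2] * 1e-3,
                          imp$eddy_amps, imp$eddy_taus)
  wave
}

#' Simulate the projection-based trajectory calibration scans
#'
#' Emulates the calibration acquisition: for each wave axis (y and z), thin
#' slices at known offsets are excited and their readout signal is recorded
#' with and without the wave gradient.  With the wave on, the signal of a
#' slice at offset r is `rho exp(-i 2 pi k_wave(t) r)`; without it the wave
#' phase is absent.  Four scan sets result (y/z, with/without).
#'
#' @param profile Numeric vector of slice magnitudes (same offsets used for
#'   both axes); must be non-empty.
#' @param positions_mm Offsets of the slices from isocenter, in mm.
#' @param traj The true `wave_trajectory` being played out.
#' @param noise_sigma SD of additive complex Gaussian noise (0 = noiseless).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @return Object of class `calibration_scans`: per axis, `with` and
#'   `without` complex matrices of size (n_time x n_positions).
#' @export
simulate_calibration_scans <- function(profile, positions_mm, traj,
                                       noise_sigma = 0, seed = 1) {
  if (length(profile) == 0) stop("empty calibration profile")
  stopifnot(length(profile) == length(positions_mm),
            inherits(traj, "wave_trajectory"))
  r_m <- positions_mm * 1e-3
  sig <- function(k_wave) {
    ph <- outer(k_wave, r_m)                       # cycles
    sweep(exp(-2i * pi * ph), 2, profile, "*")
  }
  out <- list(
    y = list(with = sig(traj$ky_wave), without = sig(0 * traj$ky_wave)),
    z = list(with = sig(traj$kz_wave), without = sig(0 * traj$kz_wave)))
  if (noise_sigma > 0) {
    out <- with_seed(seed, {
      for (ax in c("y", "z")) for (w in c("with", "without")) {
        m <- out[[ax]][[w]]
        out[[ax]][[w]] <- m + complex(
          real = stats::rnorm(length(m), sd = noise_sigma / sqrt(2)),
          imaginary = stats::rnorm(length(m), sd = noise_sigma / sqrt(2)))
        dim(out[[ax]][[w]]) <- dim(m)
      }
      out
    })
  }
  structure(list(scans = out, positions_mm = positions_mm, t = traj$t,
                 kx = traj$kx, fov_x = traj$fov_x, params = traj$params),
            class = "calibration_scans")
}

# 1D phase unwrapping along a vector.
#' @keywords internal
unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(phi[1], phi[1] + cumsum(d))
}

#' Estimate the actual wave trajectory from calibration scans
#'
#' Recovers `k_wave(t)` per axis from the phase difference between the
#' with-wave and without-wave projection signals.  Phases are unwrapped
#' along time relative to the first sample, which yields
#' `k_wave(t) - k_wave(0)` free of wrapping ambiguity; the absolute level
#' is then fixed by the package's zero-mean deflection convention (the
#' corkscrew is centered on the Cartesian readout line).  The default
#' estimator fits the relative phase against slice offset by least squares
#' through the origin at every time point (slope fit); the `"single"`
#' method uses only one reference offset.
#'
#' @param scans A `calibration_scans` object (simulated or equivalently
#'   structured measurements).
#' @param method `"slope"` (default) or `"single"`.
#' @param ref Index of the reference position for `method = "single"`.
#' @return A `wave_trajectory` with the estimated deflections.
#' @export
estimate_trajectory <- function(scans, method = c("slope", "single"), ref = NULL) {
  stopifnot(inherits(scans, "calibration_scans"))
  method <- match.arg(method)
  r_m <- scans$positions_mm * 1e-3
  est_axis <- function(ax) {
    w <- scans$scans[[ax]]$with
    wo <- scans$scans[[ax]]$without
    if (any(Mod(wo) < 1e-12 * max(Mod(wo))))
      stop("ill-conditioned calibration: vanishing signal magnitude at a reference position")
    ratio <- w / wo
    ph <- apply(Arg(ratio), 2, unwrap_phase)       # n_t x n_pos
    ph <- sweep(ph, 2, ph[1, ])                    # relative to t = 0
    k_rel <- if (method == "single") {
      i <- if (is.null(ref)) which.max(abs(r_m)) else ref
      if (abs(r_m[i]) < 1e-12) stop("reference position must be off-center")
      -ph[, i] / (2 * pi * r_m[i])
    } else {
      # weighted LS slope through origin across positions
      wgt <- Mod(wo[1, ])^2
      den <- sum(wgt * r_m^2)
      if (den < 1e-24) stop("ill-conditioned calibration: positions all at isocenter")
      -(ph %*% (wgt * r_m)) / (2 * pi * den)
    }
    k_rel - mean(k_rel)
  }
  structure(list(t = scans$t, kx = scans$kx,
                 ky_wave = as.numeric(est_axis("y")),
                 kz_wave = as.numeric(est_axis("z")),
                 fov_x = scans$fov_x, params = scans$params),
            class = "wave_trajectory")
}
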