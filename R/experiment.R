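# Retrospective comparison driver: simulate one fully sampled wave
# acquisition, synthesize the Cartesian reference from it, retrospectively
# undersample both, reconstruct with the matched method, and score every
# (method, R) cell.

#' Configuration of the retrospective comparison experiment
#'
#' @param phantom A [phantom_spec()] describing the object and coils.
#' @param wave A [wave_params()] for the wave acquisition (its `n_read`
#'   must match the phantom readout dimension).
#' @param methods Subset of `"wave-caipi"`, `"2d-caipi"`, `"cs-wave"`,
#'   `"cs"`.  CAIPI methods use staggered-lattice masks with least-squares
#'   reconstruction; CS methods use Poisson-disc masks with the sparsity-
#'   regularized reconstruction.
#' @param R_list Acceleration factors (the protocol compares 4, 6 and 8).
#' @param recon A [recon_params()] object.
#' @param seed Master seed (noise and Poisson masks).
#' @param flow_on Include the flow-phase mechanism in the simulation.
#' @param gfactor Also compute pseudo-replica g-factor maps for the CAIPI
#'   methods (expensive; off by default).
#' @param gfactor_replicas Replicas when `gfactor = TRUE`.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              wave = NULL,
                              methods = c("wave-caipi", "2d-caipi",
                                          "cs-wave", "cs"),
                              R_list = c(4, 6, 8),
                              recon = recon_params(),
                              seed = 1, flow_on = FALSE,
                              gfactor = FALSE, gfactor_replicas = 50) {
  methods <- match.arg(methods, c("wave-caipi", "2d-caipi", "cs-wave", "cs"),
                       several.ok = TRUE)
  if (length(R_list) == 0) stop("R_list must be non-empty")
  if (is.null(wave)) wave <- desk_wave_params(phantom)
  if (wave$n_read != phantom$dims[1])
    stop("wave n_read must match the phantom readout dimension")
  structure(list(phantom = phantom, wave = wave, methods = methods,
                 R_list = R_list, recon = recon, seed = seed,
                 flow_on = flow_on, gfactor = gfactor,
                 gfactor_replicas = gfactor_replicas),
            class = "experiment_config")
}

#' Desk-scale wave parameters matched to a phantom grid
#'
#' A wave protocol that preserves the spread-to-FOV ratio of the
#' full-scale protocol (PSF spread about 1.5 readout FOVs) on a coarse
#' desk grid: the wave amplitude is scaled to the desk readout gradient
#' and the oversampling factor is chosen to cover the spread without
#' wrap-around.
#'
#' @param phantom A [phantom_spec()].
#' @param n_cyc Number of wave cycles.
#' @param bw_per_pixel Readout bandwidth (Hz/pixel).
#' @param spread_frac Target one-sided PSF spread as a fraction of the
#'   readout FOV (the full-scale protocol has ~1.5).
#' @return A [wave_params()] object.
#' @export
desk_wave_params <- function(phantom, n_cyc = 8, bw_per_pixel = 121,
                             spread_frac = 1.5) {
  os <- max(2, ceiling(1 + 2 * spread_frac))
  probe <- wave_params(g_max = 1, n_cyc = n_cyc, bw_per_pixel = bw_per_pixel,
                       n_read = phantom$dims[1], os_factor = os)
  s1 <- psf_spread_extent(probe, phantom$fov[1], phantom$fov[2],
                          phantom$fov[3])
  g <- spread_frac * phantom$fov[1] / s1
  wave_params(g_max = g, n_cyc = n_cyc, bw_per_pixel = bw_per_pixel,
              n_read = phantom$dims[1], os_factor = os)
}

#' Run the retrospective undersampling comparison
#'
#' Simulates one fully sampled wave acquisition of the phantom, synthesizes
#' the fully sampled Cartesian reference by PSF deconvolution, then for
#' every requested acceleration factor applies the matched mask (CAIPI
#' lattice for the least-squares methods, Poisson disc for the CS methods)
#' to the wave data (wave methods) or the Cartesian reference data
#' (conventional methods), reconstructs, and scores CBR, SSIM and
#' vessel-masked SSIM against the fully sampled reference MIP.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-stage progress.
#' @return Object of class `wave_experiment`: a list with `metrics` (one
#'   `data.frame` row per (method, R)), `reference` (reference image, MIP
#'   and masks), `images` (reconstructed volumes) and, if requested,
#'   `gfactor` maps.
#' @export
run_retrospective_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  ph <- make_vessel_phantom(config$phantom)
  coils <- make_coil_maps(config$phantom$n_coils, config$phantom$dims,
                          ph$support, config$phantom$fov)
  say("simulating fully sampled wave acquisition")
  sim <- simulate_acquisition(ph, coils, wave = config$wave, mask = NULL,
                              flow_on = config$flow_on, seed = config$seed)
  op_wave_full <- sim$op
  say("synthesizing Cartesian reference by PSF deconvolution")
  k_cart_full <- deconvolve_to_cartesian(sim$data, op_wave_full)
  op_cart_full <- cartesian_operator(op_wave_full)
  ref <- recon_least_squares(k_cart_full, op_cart_full, config$recon)
  ref_mip <- mip(ref$image)
  vmask2 <- make_vessel_mask(ref_mip)
  results <- list()
  images <- list()
  gmaps <- list()
  ny <- config$phantom$dims[2]; nz <- config$phantom$dims[3]
  for (R in config$R_list) {
    masks <- list()
    if (any(config$methods %in% c("wave-caipi", "2d-caipi"))) {
      lat <- caipi_default_lattice(R)
      masks$caipi <- caipi_mask(ny, nz, lat$R_y, lat$R_z, lat$shift)
    }
    if (any(config$methods %in% c("cs-wave", "cs")))
      masks$poisson <- poisson_disc_mask(ny, nz, R, calib_size = 0,
                                         seed = config$seed + R)
    for (method in config$methods) {
      say("method %s at R = %g", method, R)
      rec <- switch(
        method,
        "wave-caipi" = recon_least_squares(
          sim$data, with_mask(op_wave_full, masks$caipi), config$recon),
        "2d-caipi" = recon_least_squares(
          k_cart_full, cartesian_operator(op_wave_full, masks$caipi),
          config$recon),
        "cs-wave" = recon_cs(
          sim$data, with_mask(op_wave_full, masks$poisson), config$recon),
        "cs" = recon_cs(
          k_cart_full, cartesian_operator(op_wave_full, masks$poisson),
          config$recon))
      row <- quality_report(rec$image, ref_mip, ph$vessel_labels,
                            ph$support, method = method, R = R)
      results[[length(results) + 1]] <- row
      images[[sprintf("%s_R%g", method, R)]] <- rec$image
      if (config$gfactor && method %in% c("wave-caipi", "2d-caipi")) {
        o <- if (method == "wave-caipi") with_mask(op_wave_full, masks$caipi)
        else cartesian_operator(op_wave_full, masks$caipi)
        gmaps[[sprintf("%s_R%g", method, R)]] <- gfactor_pseudo_replica(
          o, function(k, oo) recon_least_squares(k, oo, config$recon)$image,
          n_replicas = config$gfactor_replicas,
          noise_sigma = config$phantom$noise_sigma,
          seed = config$seed, image = ph$magnitude)
      }
    }
  }
  structure(list(metrics = do.call(rbind, results),
                 reference = list(image = ref$image, mip = ref_mip,
                                  vessel_mask = vmask2, phantom = ph),
                 images = images, gfactor = gmaps, config = config),
            class = "wave_experiment")
}

#' @export
print.wave_experiment <- function(x, ...) {
  cat("Retrospective undersampling comparison\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.wave_experiment <- function(x, ...) {
  m <- x$metrics
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (metric in c("cbr", "ssim", "vessel_ssim")) {
    graphics::plot(NULL, xlim = range(m$R), ylim = range(m[[metric]]),
                   xlab = "acceleration R", ylab = metric, main = metric)
    for (meth in unique(m$method)) {
      sub <- m[m$method == meth, ]
      graphics::lines(sub$R, sub[[metric]], type = "b",
                      pch = which(unique(m$method) == meth))
    }
    graphics::legend("bottomleft", legend = unique(m$method),
                     pch = seq_along(unique(m$method)), cex = 0.7)
  }
  invisible(x)
}
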