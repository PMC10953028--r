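# Evaluation battery: Monte-Carlo pseudo-replica g-factor maps,
# contrast-to-background ratio, standard and vessel-masked SSIM,
# reference-based vessel segmentation, and maximum intensity projections.

#' Maximum intensity projection
#'
#' @param volume 3D magnitude (or complex; modulus taken) volume.
#' @param axis Projection axis (1, 2 or 3; default 3, the partition axis).
#' @return 2D image of per-pixel maxima.
#' @export
mip <- function(volume, axis = 3) {
  stopifnot(length(dim(volume)) == 3, axis %in% 1:3)
  apply(Mod(volume), setdiff(1:3, axis), max)
}

# Separable Gaussian filtering with reflected boundaries (2D).
#' @keywords internal
gauss_filter2 <- function(img, sigma = 1.5, radius = 5) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  reflect_pad <- function(m, r, axis) {
    n <- dim(m)[axis]
    idx <- c(rev(seq_len(r) + 1), seq_len(n), n - seq_len(r))
    if (axis == 1) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  }
  p <- reflect_pad(img, radius, 1)
  out <- matrix(0, nrow(img), ncol(p))
  for (j in seq_along(k))
    out <- out + k[j] * p[(seq_len(nrow(img)) + j - 1), , drop = FALSE]
  p <- reflect_pad(out, radius, 2)
  res <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(k))
    res <- res + k[j] * p[, (seq_len(ncol(img)) + j - 1), drop = FALSE]
  res
}

# Local SSIM map between two images sharing a dynamic range.
#' @keywords internal
ssim_map <- function(a, b, data_range = NULL, sigma = 1.5, K1 = 0.01,
                     K2 = 0.03) {
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(data_range)) data_range <- max(a, b) - min(a, b)
  if (data_range <= 0) data_range <- 1
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_a <- gauss_filter2(a, sigma); mu_b <- gauss_filter2(b, sigma)
  va <- gauss_filter2(a * a, sigma) - mu_a^2
  vb <- gauss_filter2(b * b, sigma) - mu_b^2
  cab <- gauss_filter2(a * b, sigma) - mu_a * mu_b
  ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
}

#' Structural similarity index between two MIP images
#'
#' Mean local SSIM with an 11 x 11 Gaussian window (sigma = 1.5,
#' K1 = 0.01, K2 = 0.03) over the shared dynamic range of the two images;
#' a border of the window radius is excluded from the average.  Symmetric
#' in its arguments.
#'
#' @param mip_a,mip_b Equal-shape 2D images.
#' @param data_range Shared dynamic range; defaults to the range of the two
#'   images combined.
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(mip_a, mip_b, data_range = NULL) {
  if (!all(dim(mip_a) == dim(mip_b))) stop("images must have equal shape")
  s <- ssim_map(mip_a, mip_b, data_range)
  r <- 5
  mean(s[(r + 1):(nrow(s) - r), (r + 1):(ncol(s) - r)])
}

#' Vessel-masked structural similarity
#'
#' The local SSIM map aggregated only over the vessel-mask pixels, the
#' metric that tracks radiologists' vessel-focused reading of accelerated
#' TOF MIPs better than whole-image SSIM.
#'
#' @param mip_a,mip_b Equal-shape 2D images.
#' @param vessel_mask Logical mask of vessel pixels (non-empty).
#' @param data_range Shared dynamic range (see [ssim()]).
#' @return Masked SSIM in \[-1, 1\].
#' @export
vessel_masked_ssim <- function(mip_a, mip_b, vessel_mask, data_range = NULL) {
  if (!all(dim(mip_a) == dim(mip_b))) stop("images must have equal shape")
  if (!any(vessel_mask)) stop("empty vessel mask")
  s <- ssim_map(mip_a, mip_b, data_range)
  mean(s[vessel_mask])
}

#' Contrast-to-background ratio
#'
#' `CBR = (Mean_vessel - Mean_background) / SD_background` computed on
#' magnitude source images: the vessel-background signal difference in
#' units of the background variation.  Invariant to global additive
#' offsets.
#'
#' @param volume Magnitude (or complex) source volume or MIP.
#' @param vessel_mask,background_mask Disjoint non-empty logical masks.
#' @return The CBR (dimensionless).
#' @export
cbr <- function(volume, vessel_mask, background_mask) {
  if (!any(vessel_mask) || !any(background_mask))
    stop("vessel and background masks must be non-empty")
  if (any(vessel_mask & background_mask))
    stop("vessel and background masks must be disjoint")
  m <- Mod(volume)
  sd_bg <- stats::sd(m[background_mask])
  if (is.na(sd_bg) || sd_bg == 0)
    stop("undefined CBR: background SD is zero")
  (mean(m[vessel_mask]) - mean(m[background_mask])) / sd_bg
}

# Connected-component labelling (8-connectivity) of a logical image.
#' @keywords internal
label_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (p - 1) %% d[1] + 1; j <- (p - 1) %/% d[1] + 1
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ni <- i + di; nj <- j + dj
        if (ni < 1 || ni > d[1] || nj < 1 || nj > d[2]) next
        q <- (nj - 1) * d[1] + ni
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

#' Segment vessels from a reference MIP
#'
#' Threshold-based vessel segmentation of the fully sampled reference MIP:
#' pixels brighter than `mean + n_sd * SD` of the image, with connected
#' components smaller than `min_size` pixels removed.  The relative
#' threshold makes the mask invariant to global intensity scaling.
#'
#' @param reference_mip The fully sampled reference MIP.
#' @param n_sd Threshold in SDs above the mean (default 2).
#' @param min_size Minimum component size in pixels (default 5).
#' @return Logical vessel mask.
#' @export
make_vessel_mask <- function(reference_mip, n_sd = 2, min_size = 5) {
  thr <- mean(reference_mip) + n_sd * stats::sd(reference_mip)
  mask <- reference_mip > thr
  if (!any(mask)) stop("vessel segmentation produced an empty mask")
  lab <- label_components(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  out <- matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
  if (!any(out)) stop("vessel segmentation produced an empty mask")
  out
}

#' Background mask for CBR evaluation
#'
#' The static-tissue region: object support (projected for MIPs) minus the
#' vessel mask dilated by a safety margin.
#'
#' @param support Logical support (2D or 3D, matching the source).
#' @param vessel_mask Logical vessel mask of the same shape.
#' @param margin Dilation radius in voxels (default 2).
#' @return Logical background mask.
#' @export
background_mask <- function(support, vessel_mask, margin = 2) {
  dil <- if (length(dim(vessel_mask)) == 3) {
    dilate_mask(vessel_mask, margin)
  } else {
    m3 <- array(vessel_mask, c(dim(vessel_mask), 1))
    dilate_mask(m3, margin)[, , 1]
  }
  support & !dil
}

#' Monte-Carlo pseudo-replica g-factor map
#'
#' Estimates the spatial noise-amplification map of an accelerated
#' reconstruction with the pseudo multiple replica method: many replicas of
#' the k-space data with fresh complex Gaussian noise are reconstructed
#' through the accelerated and through the fully sampled pipeline, and
#'
#' `g(voxel) = SD_accel(voxel) / (SD_full(voxel) * sqrt(R_achieved))`
#'
#' where the SDs are across replicas.  Voxels with vanishing fully sampled
#' SD are marked invalid and excluded from the summary statistics, which
#' are computed inside the region of interest (the object support by
#' default).
#'
#' @param op Accelerated [encoding_operator()].
#' @param recon_fn Deterministic function `(kspace, op) -> complex image`.
#' @param n_replicas Number of pseudo replicas (the protocol uses 100).
#' @param noise_sigma Complex noise SD per k-space sample.
#' @param seed RNG seed (reproducible).
#' @param image Noise-free object; its forward encoding seeds every replica
#'   (`NULL` for pure-noise replicas).
#' @param roi Logical region of interest for `g_mean` / `g_max`.
#' @return Object of class `gfactor_map` with the map `g` (NA where
#'   invalid), `g_mean`, `g_max`, `n_replicas`, `seed`.
#' @export
gfactor_pseudo_replica <- function(op, recon_fn, n_replicas = 100,
                                   noise_sigma = 1, seed = 1, image = NULL,
                                   roi = NULL) {
  stopifnot(inherits(op, "encoding_operator"))
  op_full <- with_mask(op, new_sampling_mask(
    matrix(1L, op$ny, op$nz), 1, "full"))
  R <- op$mask$R_achieved
  if (is.null(roi)) roi <- op$coils$support
  k0_acc <- if (is.null(image)) array(0i, c(op$nkx, op$ny, op$nz, op$n_coil)) else
    encode_forward(image + 0i, op)
  k0_full <- if (is.null(image)) k0_acc else encode_forward(image + 0i, op_full)
  run <- function(k0, o, seed_off) {
    for (r in seq_len(n_replicas)) {
      k <- with_seed(seed + seed_off + r, {
        n <- array(complex(real = stats::rnorm(length(k0), sd = noise_sigma / sqrt(2)),
                           imaginary = stats::rnorm(length(k0), sd = noise_sigma / sqrt(2))),
                   dim(k0))
        k0 + apply_mask_4d(n, o)
      })
      img <- recon_fn(k, o)
      if (r == 1) { s_re <- Re(img); s_im <- Im(img); s2 <- Mod(img)^2 }
      else { s_re <- s_re + Re(img); s_im <- s_im + Im(img); s2 <- s2 + Mod(img)^2 }
    }
    mu2 <- (s_re / n_replicas)^2 + (s_im / n_replicas)^2
    v <- (s2 / n_replicas - mu2) * n_replicas / (n_replicas - 1)
    v[v < 0] <- 0
    sqrt(v)
  }
  sd_acc <- run(k0_acc, op, 0)
  sd_full <- run(k0_full, op_full, 10^6)
  g <- sd_acc / (sd_full * sqrt(R))
  invalid <- sd_full <= .Machine$double.eps * max(sd_full)
  g[invalid] <- NA_real_
  sel <- roi & !invalid
  structure(list(g = g, g_mean = mean(g[sel]), g_max = max(g[sel]),
                 n_replicas = n_replicas, seed = seed, R = R, roi = roi),
            class = "gfactor_map")
}

#' @export
print.gfactor_map <- function(x, ...) {
  cat(sprintf("Pseudo-replica g-factor map (R = %.3g, %d replicas): g_mean = %.3f, g_max = %.3f\n",
              x$R, x$n_replicas, x$g_mean, x$g_max))
  invisible(x)
}

#' Quality report for one reconstruction
#'
#' @param source_volume Reconstructed source volume (complex or magnitude).
#' @param reference_mip Fully sampled reference MIP.
#' @param vessel_mask_3d Logical vessel mask on the volume grid.
#' @param support Logical object support.
#' @param method,R Labels recorded in the report.
#' @param axis MIP projection axis.
#' @return A one-row `data.frame` with `method`, `R`, `cbr`, `ssim`,
#'   `vessel_ssim`.
#' @export
quality_report <- function(source_volume, reference_mip, vessel_mask_3d,
                           support, method = "recon", R = NA, axis = 3) {
  m <- mip(source_volume, axis)
  vmask2 <- make_vessel_mask(reference_mip)
  bg3 <- background_mask(support, vessel_mask_3d)
  rng <- max(reference_mip) - min(reference_mip)
  data.frame(method = method, R = R,
             cbr = cbr(Mod(source_volume), vessel_mask_3d, bg3),
             ssim = ssim(m, reference_mip, data_range = rng),
             vessel_ssim = vessel_masked_ssim(m, reference_mip, vmask2,
                                              data_range = rng))
}
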