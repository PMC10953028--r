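#' Reconstruction parameters
#'
#' Defaults follow the protocol settings of the method: LSQR stopping
#' tolerance 1e-3 with at most 200 iterations for the least-squares
#' (wave-CAIPI / 2D-CAIPI) problem, and for the compressed-sensing problem
#' regularization weights `gamma_G = gamma_W = 3e-4` (gradient- and
#' wavelet-domain L1), NLCG tolerance 3e-3 with at most 100 iterations.
#'
#' @param ls_tol Relative-residual stopping tolerance of the LSQR solver.
#' @param ls_maxiter Maximum LSQR iterations.
#' @param gamma_G Gradient-domain L1 weight (relative to unit-normalized data).
#' @param gamma_W Wavelet-domain L1 weight.
#' @param cs_tol NLCG stopping tolerance (relative gradient norm).
#' @param cs_maxiter Maximum NLCG iterations.
#' @param l1_smooth_eps Smoothing constant in `|x| ~ sqrt(|x|^2 + eps)`.
#' @param wavelet_levels Haar decomposition depth.
#' @return Object of class `recon_params`.
#' @export
recon_params <- function(ls_tol = 1e-3, ls_maxiter = 200,
                         gamma_G = 3e-4, gamma_W = 3e-4,
                         cs_tol = 3e-3, cs_maxiter = 100,
                         l1_smooth_eps = 1e-15, wavelet_levels = 3) {
  stopifnot(ls_tol > 0, cs_tol > 0, l1_smooth_eps > 0,
            gamma_G >= 0, gamma_W >= 0, ls_maxiter >= 1, cs_maxiter >= 1)
  structure(list(ls_tol = ls_tol, ls_maxiter = as.integer(ls_maxiter),
                 gamma_G = gamma_G, gamma_W = gamma_W,
                 cs_tol = cs_tol, cs_maxiter = as.integer(cs_maxiter),
                 l1_smooth_eps = l1_smooth_eps,
                 wavelet_levels = as.integer(wavelet_levels)),
            class = "recon_params")
}

#' @keywords internal
new_wave_recon <- function(image, residual_history, converged, iterations,
                           method, op) {
  structure(list(image = image, residual_history = residual_history,
                 converged = converged, iterations_used = iterations,
                 method = method,
                 R = op$mask$R_achieved,
                 wave = !is.null(op$psf),
                 dims = c(op$nx, op$ny, op$nz)),
            class = "wave_recon")
}

#' @export
print.wave_recon <- function(x, ...) {
  cat(sprintf("%s reconstruction (%s encoding), R = %.3g\n", x$method,
              if (x$wave) "wave" else "Cartesian", x$R))
  cat(sprintf("  grid %d x %d x %d, %d iterations, %s (final residual %.3g)\n",
              x$dims[1], x$dims[2], x$dims[3], x$iterations_used,
              if (x$converged) "converged" else "iteration limit reached",
              utils::tail(x$residual_history, 1)))
  invisible(x)
}

#' @export
summary.wave_recon <- function(object, ...) {
  m <- Mod(object$image)
  cat(sprintf("%s reconstruction, R = %.3g, %d iterations\n",
              object$method, object$R, object$iterations_used))
  cat(sprintf("  magnitude range [%.4g, %.4g], mean %.4g\n",
              min(m), max(m), mean(m)))
  invisible(object)
}

#' @export
residuals.wave_recon <- function(object, ...) object$residual_history

#' @export
plot.wave_recon <- function(x, slice = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (is.null(slice)) slice <- ceiling(x$dims[3] / 2)
  m <- Mod(x$image[, , slice])
  graphics::image(m, col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  main = sprintf("|image|, slice %d", slice), useRaster = TRUE)
  graphics::plot(seq_along(x$residual_history), x$residual_history,
                 type = "l", log = "y", xlab = "iteration",
                 ylab = "residual / objective", main = x$method)
  invisible(x)
}

# LSQR (Paige & Saunders bidiagonalization) for a complex linear operator.
#' @keywords internal
lsqr_solve <- function(Afun, Atfun, b, tol, maxiter) {
  beta0 <- cnorm(b)
  if (beta0 == 0) {
    x <- Atfun(b)
    return(list(x = 0 * x, relres = 0, iters = 0, hist = numeric(0),
                converged = TRUE))
  }
  u <- b / beta0
  v <- Atfun(u); alpha <- cnorm(v); v <- v / alpha
  w <- v
  x <- 0 * v
  phibar <- beta0; rhobar <- alpha
  hist <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < maxiter) {
    it <- it + 1
    u <- Afun(v) - alpha * u
    beta <- cnorm(u)
    if (!is.finite(beta)) stop("LSQR diverged (non-finite) at iteration ", it)
    if (beta > 0) u <- u / beta
    v <- Atfun(u) - beta * v
    alpha <- cnorm(v)
    if (alpha > 0) v <- v / alpha
    rho <- sqrt(rhobar^2 + beta^2)
    cc <- rhobar / rho; ss <- beta / rho
    theta <- ss * alpha
    rhobar <- -cc * alpha
    phi <- cc * phibar; phibar <- ss * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    relres <- abs(phibar) / beta0
    hist <- c(hist, relres)
    if (!is.finite(relres)) stop("LSQR diverged at iteration ", it)
    if (relres < tol) { converged <- TRUE; break }
  }
  list(x = x, relres = utils::tail(hist, 1), iters = it, hist = hist,
       converged = converged)
}

#' Iterative least-squares (SENSE) reconstruction
#'
#' Solves `min_s || M F_z F_y PSF F_x C s - k ||_2^2` with LSQR.  With a
#' wave PSF in the operator this is the wave-CAIPI reconstruction; with
#' `psf = NULL` it is the conventional 2D-CAIPI (Cartesian SENSE)
#' reconstruction.
#'
#' @param kspace Complex k-space array matching the operator.
#' @param op An [encoding_operator()]; its mask must match the zeros of
#'   `kspace`.
#' @param params A [recon_params()] object.
#' @return A `wave_recon` object.
#' @export
recon_least_squares <- function(kspace, op, params = recon_params()) {
  stopifnot(inherits(op, "encoding_operator"))
  b <- apply_mask_4d(kspace, op)
  res <- lsqr_solve(function(x) encode_forward(x, op),
                    function(k) encode_adjoint(k, op),
                    b, params$ls_tol, params$ls_maxiter)
  new_wave_recon(res$x, res$hist, res$converged, res$iters,
                 "least-squares", op)
}

#' @keywords internal
apply_mask_4d <- function(kspace, op) {
  if (!all(dim(kspace) == c(op$nkx, op$ny, op$nz, op$n_coil)))
    stop("k-space dimensions do not match the operator")
  apply_mask(kspace, op$mask$grid)
}

#' Zero-filled (adjoint) reconstruction
#'
#' Adjoint of the encoding applied to the measured data with
#' sensitivity-combined normalization (division by the coil
#' sum-of-squares, which is 1 on the object support).
#'
#' @inheritParams recon_least_squares
#' @return Complex image array (nx, ny, nz).
#' @export
zero_filled_recon <- function(kspace, op) {
  img <- encode_adjoint(apply_mask_4d(kspace, op), op)
  ss <- apply(Mod(op$coils$maps)^2, 1:3, sum)
  nz <- ss > 1e-8
  img[nz] <- img[nz] / ss[nz]
  img
}

#' Compressed-sensing (NLCG) reconstruction
#'
#' Solves
#' `min_s ||A s - k||_2^2 + gamma_G ||G s||_1 + gamma_W ||W s||_1`
#' with a smoothed-L1 nonlinear conjugate gradient method
#' (Fletcher-Reeves with periodic restart, Armijo backtracking line
#' search), where `G` is the finite-difference gradient and `W` the
#' orthonormal Haar wavelet.  With a wave PSF in the operator this is the
#' CS-wave reconstruction; without it, conventional CS.  The k-space data
#' are normalized so the zero-filled image has unit peak magnitude before
#' solving (the regularization weights are expressed on that scale) and the
#' output is scaled back.
#'
#' @inheritParams recon_least_squares
#' @return A `wave_recon` object; `residual_history` holds the objective
#'   value per accepted iteration (monotone non-increasing).
#' @export
recon_cs <- function(kspace, op, params = recon_params()) {
  stopifnot(inherits(op, "encoding_operator"))
  if (!is.null(op$mask$kind) && op$mask$kind == "caipi")
    warning("compressed-sensing reconstruction expects a Poisson-disc mask")
  b <- apply_mask_4d(kspace, op)
  x0 <- zero_filled_recon(b, op)
  scale <- max(Mod(x0))
  if (scale == 0) return(new_wave_recon(x0, 0, TRUE, 0, "compressed-sensing", op))
  b <- b / scale
  x <- x0 / scale
  gG <- params$gamma_G; gW <- params$gamma_W
  eps <- params$l1_smooth_eps
  lev <- params$wavelet_levels
  sl1 <- function(z) sum(sqrt(Mod(z)^2 + eps))
  objective <- function(x, Ax) {
    val <- sum(Mod(Ax - b)^2)
    if (gG > 0) val <- val + gG * sl1(fd_gradient(x))
    if (gW > 0) val <- val + gW * sl1(haar3d(x, lev))
    val
  }
  gradient <- function(x, Ax) {
    g <- 2 * encode_adjoint(Ax - b, op)
    if (gG > 0) {
      gx <- fd_gradient(x)
      g <- g + gG * fd_gradient_adj(gx / sqrt(Mod(gx)^2 + eps))
    }
    if (gW > 0) {
      wx <- haar3d(x, lev)
      g <- g + gW * ihaar3d(wx / sqrt(Mod(wx)^2 + eps), attr(wx, "levels"))
    }
    g
  }
  alpha_ls <- 0.01; beta_ls <- 0.6; max_ls <- 20
  Ax <- encode_forward(x, op)
  f <- objective(x, Ax)
  g <- gradient(x, Ax)
  g0n <- cnorm(g)
  d <- -g
  hist <- f
  converged <- FALSE
  it <- 0
  t0 <- 1
  while (it < params$cs_maxiter) {
    it <- it + 1
    Ad <- encode_forward(d, op)
    slope <- Re(cdot(g, d))
    if (slope >= 0) { d <- -g; Ad <- encode_forward(d, op); slope <- Re(cdot(g, d)) }
    t <- t0; ls <- 0
    repeat {
      fnew <- objective(x + t * d, Ax + t * Ad)
      if (fnew <= f + alpha_ls * t * slope || ls >= max_ls) break
      t <- t * beta_ls; ls <- ls + 1
    }
    # one quadratic-interpolation refinement (exact for the pure
    # least-squares objective, a better step otherwise)
    denom <- fnew - f - slope * t
    if (is.finite(denom) && denom > 0) {
      t2 <- -slope * t^2 / (2 * denom)
      if (is.finite(t2) && t2 > 0 && t2 < 4 * t) {
        f2 <- objective(x + t2 * d, Ax + t2 * Ad)
        if (f2 < fnew) { t <- t2; fnew <- f2 }
      }
    }
    if (ls >= max_ls && fnew > f) {
      # line-search failure: fall back to a tiny steepest-descent step once
      d <- -g; Ad <- encode_forward(d, op); slope <- Re(cdot(g, d))
      t <- 1e-6; fnew <- objective(x + t * d, Ax + t * Ad)
      if (fnew > f) break
    }
    # adapt the initial step like the classic sparse-MRI implementation
    if (ls > 2) t0 <- t0 * beta_ls
    if (ls < 1) t0 <- t0 / beta_ls
    x <- x + t * d
    Ax <- Ax + t * Ad
    f <- fnew
    gnew <- gradient(x, Ax)
    beta_fr <- if (it %% 50 == 0) 0 else sum(Mod(gnew)^2) / sum(Mod(g)^2)
    d <- -gnew + beta_fr * d
    g <- gnew
    hist <- c(hist, f)
    if (cnorm(g) / g0n < params$cs_tol) { converged <- TRUE; break }
  }
  new_wave_recon(x * scale, hist, converged, it, "compressed-sensing", op)
}
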