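# Sparsifying transforms for the compressed-sensing objective: anisotropic
# first-order finite differences and an orthonormal 3D Haar wavelet.

# Forward difference along one axis with zero boundary (x[n+1] = 0).
#' @keywords internal
fdiff_axis <- function(x, axis) {
  n <- dim(x)[axis]
  args <- rep(list(quote(expr = )), length(dim(x)))
  a2 <- args; a2[[axis]] <- c(2:n)
  shifted <- array(0i, dim(x))
  a1 <- args; a1[[axis]] <- c(1:(n - 1))
  shifted <- do.call(`[<-`, c(list(shifted), a1,
                              list(value = do.call(`[`, c(list(x), a2, list(drop = FALSE))))))
  shifted - x
}

# Adjoint of fdiff_axis: (D^H y)[i] = y[i-1] - y[i] with y[0] = 0.
#' @keywords internal
fdiff_axis_adj <- function(y, axis) {
  n <- dim(y)[axis]
  args <- rep(list(quote(expr = )), length(dim(y)))
  a1 <- args; a1[[axis]] <- c(1:(n - 1))
  a2 <- args; a2[[axis]] <- c(2:n)
  shifted <- array(0i, dim(y))
  shifted <- do.call(`[<-`, c(list(shifted), a2,
                              list(value = do.call(`[`, c(list(y), a1, list(drop = FALSE))))))
  shifted - y
}

#' Finite-difference gradient transform
#'
#' Anisotropic first-order forward differences along the three spatial axes
#' (zero boundary), stacked into a 4D array; the sparsity penalty of the
#' compressed-sensing objective is applied to these coefficients.
#'
#' @param x Complex array (nx, ny, nz).
#' @return Complex array (nx, ny, nz, 3).
#' @export
fd_gradient <- function(x) {
  d <- dim(x)
  out <- array(0i, c(d, 3))
  for (a in 1:3) out[, , , a] <- fdiff_axis(x + 0i, a)
  out
}

#' Adjoint of the finite-difference gradient transform
#'
#' @param g Complex array (nx, ny, nz, 3).
#' @return Complex array (nx, ny, nz).
#' @export
fd_gradient_adj <- function(g) {
  d <- dim(g)[1:3]
  out <- array(0i, d)
  for (a in 1:3)
    out <- out + fdiff_axis_adj(array(g[, , , a], d), a)
  out
}

# One orthonormal Haar analysis step along an axis: pairwise
# (a+b)/sqrt2 (low, first half) and (a-b)/sqrt2 (high, second half).
#' @keywords internal
haar_step <- function(x, axis, inverse = FALSE) {
  d <- dim(x); n <- d[axis]
  perm <- c(axis, setdiff(seq_along(d), axis))
  xm <- aperm(x, perm); dim(xm) <- c(n, prod(d) / n)
  if (!inverse) {
    a <- xm[seq(1, n, 2), , drop = FALSE]
    b <- xm[seq(2, n, 2), , drop = FALSE]
    ym <- rbind((a + b) / sqrt(2), (a - b) / sqrt(2))
  } else {
    lo <- xm[1:(n / 2), , drop = FALSE]
    hi <- xm[(n / 2 + 1):n, , drop = FALSE]
    ym <- matrix(0i, n, ncol(xm))
    ym[seq(1, n, 2), ] <- (lo + hi) / sqrt(2)
    ym[seq(2, n, 2), ] <- (lo - hi) / sqrt(2)
  }
  dim(ym) <- d[perm]
  aperm(ym, order(perm))
}

#' @keywords internal
haar_levels_for <- function(d, levels) {
  max_lev <- 0
  while (max_lev < levels && all(d %% 2^(max_lev + 1) == 0)) max_lev <- max_lev + 1
  max_lev
}

#' Orthonormal 3D Haar wavelet transform
#'
#' Multi-level separable Haar decomposition (periodization-free: grid
#' dimensions must be divisible by `2^levels`; the level count is reduced
#' automatically when they are not).  The transform is orthonormal, so its
#' adjoint equals its inverse.
#'
#' @param x Complex array (nx, ny, nz).
#' @param levels Requested decomposition depth (default 3).
#' @return Complex array of coefficients, same shape, with the low-pass
#'   block in the leading corner; attribute `levels` records the depth used.
#' @export
haar3d <- function(x, levels = 3) {
  d <- dim(x)
  lev <- haar_levels_for(d, levels)
  y <- x + 0i
  dd <- d
  for (l in seq_len(lev)) {
    idx <- lapply(dd, seq_len)
    blk <- y[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    for (a in 1:3) blk <- haar_step(blk, a)
    y[idx[[1]], idx[[2]], idx[[3]]] <- blk
    dd <- dd / 2
  }
  attr(y, "levels") <- lev
  y
}

#' Inverse (adjoint) 3D Haar wavelet transform
#'
#' @param y Coefficient array from [haar3d()].
#' @param levels Decomposition depth; defaults to the `levels` attribute.
#' @return Complex array (nx, ny, nz).
#' @export
ihaar3d <- function(y, levels = NULL) {
  if (is.null(levels)) levels <- attr(y, "levels")
  if (is.null(levels)) stop("levels not given and not recorded on y")
  d <- dim(y)
  x <- y + 0i
  for (l in rev(seq_len(levels))) {
    dd <- d / 2^(l - 1)
    idx <- lapply(dd, seq_len)
    blk <- x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    for (a in 3:1) blk <- haar_step(blk, a, inverse = TRUE)
    x[idx[[1]], idx[[2]], idx[[3]]] <- blk
  }
  attr(x, "levels") <- NULL
  x
}
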