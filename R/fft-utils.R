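# Centered orthonormal FFTs along single array axes.
#
# Convention used throughout the package: the DC sample of every k-space axis
# sits at index floor(N/2) (0-based), voxel centers at (i - N/2) * delta with
# 0-based i.  Orthonormal scaling (1/sqrt(N) both ways) makes the adjoint of
# the forward transform equal to its inverse, which keeps the encoding
# operator's adjoint exact.

#' @keywords internal
circshift1 <- function(x, axis, shift) {
  d <- dim(x)
  if (is.null(d)) {
    n <- length(x)
    return(x[((seq_len(n) - 1 - shift) %% n) + 1])
  }
  n <- d[axis]
  idx <- ((seq_len(n) - 1 - shift) %% n) + 1
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

#' @keywords internal
fftshift_axis <- function(x, axis) circshift1(x, axis, floor(dimlen(x, axis) / 2))

#' @keywords internal
ifftshift_axis <- function(x, axis) circshift1(x, axis, -floor(dimlen(x, axis) / 2))

#' @keywords internal
dimlen <- function(x, axis) if (is.null(dim(x))) length(x) else dim(x)[axis]

# Orthonormal centered FFT along one axis of an n-d complex array.
# For even axis lengths the index rolls of fftshift/ifftshift are folded
# into alternating-sign multiplications:
#   fftshift(F(ifftshift(x))) = (-1)^{n/2} alt_k * F(alt_n * x)
# which avoids two full array copies per transform.
#' @keywords internal
fft_axis <- function(x, axis, inverse = FALSE) {
  d <- dim(x)
  if (is.null(d)) { d <- length(x); dim(x) <- d }
  n <- d[axis]
  if (n %% 2 == 0) {
    alt <- rep_len(c(1, -1), n)
    sgn <- if ((n / 2) %% 2 == 0) 1 else -1
    if (axis != 1L) {
      perm <- c(axis, setdiff(seq_along(d), axis))
      x <- aperm(x, perm)
    } else perm <- seq_along(d)
    dim(x) <- c(n, prod(d) / n)
    x <- mvfft(x * alt, inverse = inverse) * (alt * (sgn / sqrt(n)))
    dim(x) <- d[perm]
    if (axis != 1L) x <- aperm(x, order(perm))
    return(x)
  }
  x <- ifftshift_axis(x, axis)
  if (axis != 1L) {
    perm <- c(axis, setdiff(seq_along(d), axis))
    x <- aperm(x, perm)
  } else perm <- seq_along(d)
  dim(x) <- c(n, prod(d) / n)
  x <- mvfft(x, inverse = inverse) / sqrt(n)
  dim(x) <- d[perm]
  if (axis != 1L) x <- aperm(x, order(perm))
  fftshift_axis(x, axis)
}

# Zero-pad / crop the first (readout) axis symmetrically about the center,
# matching the voxel-center convention above.  pad_axis1 and crop_axis1 are
# exact adjoints of one another.
#' @keywords internal
pad_axis1 <- function(x, n_out) {
  d <- dim(x)
  if (n_out == d[1]) return(x)
  stopifnot(n_out > d[1])
  out <- array(0i, c(n_out, d[-1]))
  off <- (n_out - d[1]) %/% 2
  idx <- seq_len(d[1]) + off
  args <- rep(list(quote(expr = )), length(d))
  args[[1]] <- idx
  do.call(`[<-`, c(list(out), args, list(value = x)))
}

#' @keywords internal
crop_axis1 <- function(x, n_out) {
  d <- dim(x)
  if (n_out == d[1]) return(x)
  stopifnot(n_out < d[1])
  off <- (d[1] - n_out) %/% 2
  idx <- seq_len(n_out) + off
  args <- rep(list(quote(expr = )), length(d))
  args[[1]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

# Complex inner product <x, y> = sum(conj(x) * y) over arrays.
#' @keywords internal
cdot <- function(x, y) sum(Conj(x) * y)

#' @keywords internal
cnorm <- function(x) sqrt(sum(Mod(x)^2))

# Evaluate a block with a temporary RNG state so that seeded generators do not
# disturb (and are not disturbed by) the caller's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
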