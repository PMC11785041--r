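# Internal numerical helpers shared across modules.

# Cyclic shift of a matrix with even dimensions so that the DFT zero-frequency
# term ends up at the central pixel (row ny/2+1, column nx/2+1).
fftshift2 <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  stopifnot(ny %% 2L == 0L, nx %% 2L == 0L)
  m[c((ny / 2L + 1L):ny, 1L:(ny / 2L)), c((nx / 2L + 1L):nx, 1L:(nx / 2L)),
    drop = FALSE]
}

# Inverse of fftshift2 (identical for even dimensions).
ifftshift2 <- fftshift2

# Physical frequency axis for an even-length DFT after centering: n values
# spaced 1/(n*d), running from -1/(2d) up to (n/2-1)/(n*d).
freq_axis <- function(n, d) {
  stopifnot(n %% 2L == 0L, d > 0)
  ((0:(n - 1L)) - n / 2L) / (n * d)
}

# Frequency axis in native (unshifted) DFT order, zero first.
freq_axis_unshifted <- function(n, d) {
  stopifnot(n %% 2L == 0L, d > 0)
  (((0:(n - 1L)) + n / 2L) %% n - n / 2L) / (n * d)
}

# Radial frequency magnitude grid for a (ny, nx) spectrum.
radial_freq_grid <- function(ny, nx, dy, dx, shifted = TRUE) {
  ax <- if (shifted) freq_axis else freq_axis_unshifted
  uy <- ax(ny, dy)
  ux <- ax(nx, dx)
  sqrt(outer(uy^2, rep(1, nx)) + outer(rep(1, ny), ux^2))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}
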