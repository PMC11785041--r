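#' Build the exit wave from an elemental map
#'
#' For incoherent fluorescence the analysis treats the square root of the
#' per-element intensity image as a real-space exit wave. Maps containing
#' negative pixels (which spectrum-fitting software can produce) are first
#' offset by the magnitude of the most negative pixel, so that the minimum of
#' the offset image is exactly zero; a constant offset affects only the zero
#' spatial frequency of the spectrum.
#'
#' @param map An [elemental_map()].
#' @return An object of class `ExitWave`: list with `psi` (matrix of
#'   square-root amplitudes), `offset` (the constant added before the square
#'   root), `dx`, `dy`, `element`.
#' @examples
#' m <- elemental_map(matrix(4, 8, 8), 1, 1)
#' w <- to_exit_wave(m)
#' w$psi[1, 1]  # 2
#' @export
to_exit_wave <- function(map) {
  stopifnot(inherits(map, "ElementalMap"))
  mn <- min(map$values)
  offset <- if (mn < 0) -mn else 0
  psi <- sqrt(map$values + offset)
  structure(list(psi = psi, offset = offset, dx = map$dx, dy = map$dy,
                 element = map$element),
            class = "ExitWave")
}

#' Pad an exit wave to even dimensions
#'
#' Any odd dimension is extended by one row/column filled with the mean of the
#' exit-wave amplitude (computed before padding), so the discrete transform
#' has a well-defined central pixel and even-length FFTs can be used. Even
#' dimensions pass through unchanged.
#'
#' @param wave An `ExitWave` from [to_exit_wave()].
#' @return An `ExitWave` with both dimensions even.
#' @export
pad_to_even <- function(wave) {
  stopifnot(inherits(wave, "ExitWave"))
  psi <- wave$psi
  fill <- mean(psi)
  if (nrow(psi) %% 2L == 1L) psi <- rbind(psi, rep(fill, ncol(psi)))
  if (ncol(psi) %% 2L == 1L) psi <- cbind(psi, rep(fill, nrow(psi)))
  wave$psi <- psi
  wave
}

#' Compute the 2D power spectral density of an exit wave
#'
#' The PSD is the squared modulus of the unnormalized forward discrete
#' Fourier transform of the exit wave, cyclically shifted so that the zero
#' spatial frequency sits at the central pixel. The frequency axes are
#' physical, in inverse micrometers: along x the frequency runs from
#' `-1/(2*dx)` up to `b/(2*dx)` with `b = (nx/2 - 1)/(nx/2)`, in steps of
#' `1/(nx*dx)` (and likewise along y).
#'
#' The DFT normalization is immaterial for resolution estimates: the
#' resolution frequency depends only on the ratio of noise floor to power-law
#' amplitude, which is invariant under a common rescaling of the spectrum.
#'
#' @param wave An `ExitWave` with even dimensions (see [pad_to_even()]).
#' @return An object of class `Spectrum2D`: list with `S` (non-negative
#'   matrix, zero frequency at row `ny/2+1`, column `nx/2+1`), `ux_axis`,
#'   `uy_axis` (1/um), `nx`, `ny`, `dx`, `dy`, `element`.
#' @export
compute_psd <- function(wave) {
  stopifnot(inherits(wave, "ExitWave"))
  ny <- nrow(wave$psi)
  nx <- ncol(wave$psi)
  if (ny %% 2L == 1L || nx %% 2L == 1L) {
    stop("exit wave has odd dimensions; apply pad_to_even() first", call. = FALSE)
  }
  S <- fftshift2(Mod(stats::fft(wave$psi))^2)
  structure(list(S = S,
                 ux_axis = freq_axis(nx, wave$dx),
                 uy_axis = freq_axis(ny, wave$dy),
                 nx = nx, ny = ny, dx = wave$dx, dy = wave$dy,
                 element = wave$element),
            class = "Spectrum2D")
}

#' Azimuthal sector specification
#'
#' Restricts radial averaging of the 2D PSD to wedges about the x or y
#' frequency axis, for direction-dependent resolution estimates. Sectors are
#' point-symmetric (both half-axes included). Membership about the x axis
#' uses a half-open test (acute angle from the x axis strictly less than
#' `half_angle`); about the y axis the boundary is closed, so that 45-degree
#' x and y sectors tile all frequencies exactly once.
#'
#' @param mode `"isotropic"` (all azimuths), `"x_sector"`, or `"y_sector"`.
#' @param half_angle Sector half-angle in degrees, in (0, 45]; default 30.
#' @return An object of class `SectorSpec`.
#' @export
sector_spec <- function(mode = c("isotropic", "x_sector", "y_sector"),
                        half_angle = 30) {
  mode <- match.arg(mode)
  if (mode != "isotropic") {
    if (!is.numeric(half_angle) || length(half_angle) != 1L ||
        !(half_angle > 0 && half_angle <= 45)) {
      stop("'half_angle' must be in (0, 45] degrees", call. = FALSE)
    }
  }
  structure(list(mode = mode, half_angle = half_angle), class = "SectorSpec")
}

# Logical mask of spectrum pixels belonging to a sector. `theta` is the acute
# angle from the x frequency axis in degrees. Pixels at u_r = 0 are excluded.
sector_mask <- function(spec, sector) {
  UX <- outer(rep(1, spec$ny), spec$ux_axis)
  UY <- outer(spec$uy_axis, rep(1, spec$nx))
  ur <- sqrt(UX^2 + UY^2)
  keep <- ur > 0
  if (sector$mode == "isotropic") return(keep)
  theta <- atan2(abs(UY), abs(UX)) * 180 / pi
  if (sector$mode == "x_sector") {
    keep & (theta < sector$half_angle)
  } else {
    keep & ((90 - theta) <= sector$half_angle)
  }
}

#' Reduce a 2D PSD to a radial profile
#'
#' Each non-central pixel is assigned its radial frequency
#' `u_r = sqrt(ux^2 + uy^2)` and, in sector modes, kept only when it lies
#' within the requested wedge about the x or y axis. Kept pixels are binned
#' uniformly in `u_r` from 0 up to the maximum `u_r` present in the kept set
#' (corner frequencies included), and each bin's value is the arithmetic mean
#' of the PSD over its pixels. Using fewer bins than frequency samples
#' smooths the profile. The zero-frequency pixel is always excluded. Bins
#' that receive no pixels are retained in the output with `counts == 0` and
#' `S_values == NA`; fitting functions skip them.
#'
#' @param spec A `Spectrum2D` from [compute_psd()].
#' @param n_bins Number of radial bins (>= 2). Default
#'   `floor(min(nx, ny)/2)`: one bin per resolvable frequency step of the
#'   smaller axis.
#' @param sector A [sector_spec()]; default isotropic.
#' @return An object of class `RadialProfile`: list with `ur_centers` (1/um,
#'   strictly increasing), `S_values`, `counts`, `sector`, `n_bins`.
#' @export
radial_profile <- function(spec, n_bins = NULL, sector = sector_spec()) {
  stopifnot(inherits(spec, "Spectrum2D"), inherits(sector, "SectorSpec"))
  if (is.null(n_bins)) n_bins <- max(2L, floor(min(spec$nx, spec$ny) / 2))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be at least 2", call. = FALSE)
  ur <- radial_freq_grid(spec$ny, spec$nx, spec$dy, spec$dx, shifted = TRUE)
  keep <- sector_mask(spec, sector)
  if (!any(keep)) stop("sector contains no spectrum pixels", call. = FALSE)
  ur_kept <- ur[keep]
  s_kept <- spec$S[keep]
  ur_max <- max(ur_kept)
  idx <- pmin(pmax(ceiling(ur_kept / ur_max * n_bins), 1L), n_bins)
  sums <- vapply(split(s_kept, factor(idx, levels = seq_len(n_bins))),
                 sum, numeric(1))
  counts <- tabulate(idx, nbins = n_bins)
  S_values <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  structure(list(ur_centers = (seq_len(n_bins) - 0.5) * ur_max / n_bins,
                 S_values = unname(S_values),
                 counts = counts,
                 sector = sector,
                 n_bins = n_bins,
                 ur_max = ur_max,
                 element = spec$element),
            class = "RadialProfile")
}

#' @export
print.RadialProfile <- function(x, ...) {
  cat(sprintf("RadialProfile (%s%s): %d bins, u_r up to %.4g 1/um, %d empty\n",
              x$sector$mode,
              if (x$sector$mode == "isotropic") ""
              else sprintf(", +/-%g deg", x$sector$half_angle),
              x$n_bins, x$ur_max, sum(x$counts == 0)))
  invisible(x)
}

#' @export
print.Spectrum2D <- function(x, ...) {
  cat(sprintf("Spectrum2D: %d x %d, ux in [%.4g, %.4g], uy in [%.4g, %.4g] 1/um\n",
              x$ny, x$nx, min(x$ux_axis), max(x$ux_axis),
              min(x$uy_axis), max(x$uy_axis)))
  invisible(x)
}

#' @export
print.ExitWave <- function(x, ...) {
  cat(sprintf("ExitWave '%s': %d x %d, offset %g\n",
              x$element, nrow(x$psi), ncol(x$psi), x$offset))
  invisible(x)
}
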