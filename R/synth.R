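#' Specification of a synthetic elemental map
#'
#' Synthetic maps give every analysis stage a ground truth: a noiseless
#' intensity field of known spectral structure, plus independent Poisson
#' counting noise per pixel emulating photon-limited acquisition. Three
#' kinds are available:
#'
#' * `power_law_field` — a random field whose power spectrum falls as
#'   `u_r^a_true`, emulating the signal trend of real fluorescence images;
#' * `flat_field` — a constant field, isolating the flat Poisson noise floor;
#' * `spot_pair` — two Gaussian spots on a low uniform background, a
#'   real-space sanity target for resolution estimates.
#'
#' @param nx,ny Even grid dimensions, >= 16.
#' @param dx,dy Pixel sizes, um.
#' @param a_true Spectral exponent (< 0) for `power_law_field`.
#' @param amplitude Spectral scale of the raw field (the field is rescaled to
#'   `mean_counts` afterwards, so this only matters if you use the raw truth).
#' @param mean_counts Target mean photons per pixel (lambda, > 0).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param kind One of `"power_law_field"`, `"flat_field"`, `"spot_pair"`.
#' @param spot_separation Center-to-center spot distance, um
#'   (`spot_pair` only; must be positive and fit inside the field).
#' @return An object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(nx = 512L, ny = 512L, dx = 1, dy = 1,
                           a_true = -3.5, amplitude = 1, mean_counts = 200,
                           seed = 1L,
                           kind = c("power_law_field", "flat_field",
                                    "spot_pair"),
                           spot_separation = NULL) {
  kind <- match.arg(kind)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 16L || ny < 16L || nx %% 2L != 0L || ny %% 2L != 0L) {
    stop("'nx' and 'ny' must be even and >= 16", call. = FALSE)
  }
  stop_if_not_scalar_pos(dx, "dx"); stop_if_not_scalar_pos(dy, "dy")
  stop_if_not_scalar_pos(mean_counts, "mean_counts")
  if (kind == "power_law_field" && (!is.finite(a_true) || a_true >= 0)) {
    stop("'a_true' must be negative for a power-law field", call. = FALSE)
  }
  if (kind == "spot_pair") {
    if (is.null(spot_separation) || !is.finite(spot_separation) ||
        spot_separation <= 0) {
      stop("'spot_separation' must be a positive distance in um", call. = FALSE)
    }
    if (spot_separation >= min(nx * dx, ny * dy) / 2) {
      stop("'spot_separation' is too large for the field", call. = FALSE)
    }
  }
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy, a_true = a_true,
                 amplitude = amplitude, mean_counts = mean_counts,
                 seed = as.integer(seed), kind = kind,
                 spot_separation = spot_separation),
            class = "SyntheticSpec")
}

# Two independent substreams per seed: one for the random field, one for the
# Poisson draws, so changing lambda never changes the underlying field.
synth_seed_field <- function(seed) seed
synth_seed_noise <- function(seed) (seed %% 1000000000L) + 1000003L

# Poisson-sample a non-negative truth field reproducibly.
poisson_sample <- function(truth, seed) {
  set.seed(synth_seed_noise(seed))
  matrix(stats::rpois(length(truth), as.vector(truth)),
         nrow(truth), ncol(truth))
}

#' Generate a synthetic elemental map
#'
#' Dispatches on `spec$kind`. For `power_law_field`, Fourier amplitudes
#' proportional to `u_r^(a_true/2)` are applied to the transform of a white
#' Gaussian field (which supplies random phases with the conjugate symmetry
#' of a real field); the zero-frequency amplitude is excluded (the `u^a`
#' singularity) and instead fixed by rescaling the real-space field: after
#' the inverse transform the field is shifted by its minimum and rescaled to
#' mean `mean_counts`, avoiding any hard clipping that would distort the
#' spectrum. Poisson counts are then drawn independently per pixel from a
#' separate random substream.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `SyntheticResult`: list with `map` (an
#'   [elemental_map()] of integer counts), `truth` (the noiseless intensity
#'   field), and `spec`.
#' @examples
#' r <- synth_map(synthetic_spec(nx = 64, ny = 64, mean_counts = 50, seed = 7))
#' mean(r$map$values)
#' @export
synth_map <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  truth <- switch(spec$kind,
    power_law_field = synth_truth_power_law(spec),
    flat_field = matrix(spec$mean_counts, spec$ny, spec$nx),
    spot_pair = synth_truth_spot_pair(spec)
  )
  counts <- poisson_sample(truth, spec$seed)
  map <- elemental_map(counts, dx = spec$dx, dy = spec$dy,
                       element = paste0("synthetic-", spec$kind),
                       source = "synthetic")
  structure(list(map = map, truth = truth, spec = spec),
            class = "SyntheticResult")
}

synth_truth_power_law <- function(spec) {
  set.seed(synth_seed_field(spec$seed))
  g <- matrix(stats::rnorm(spec$nx * spec$ny), spec$ny, spec$nx)
  ur <- radial_freq_grid(spec$ny, spec$nx, spec$dy, spec$dx, shifted = FALSE)
  amp <- matrix(0, spec$ny, spec$nx)
  pos <- ur > 0
  amp[pos] <- spec$amplitude * ur[pos]^(spec$a_true / 2)
  f <- Re(stats::fft(stats::fft(g) * amp, inverse = TRUE)) /
    (spec$nx * spec$ny)
  f <- f - min(f)
  f * spec$mean_counts / mean(f)
}

synth_truth_spot_pair <- function(spec) {
  sep <- spec$spot_separation
  fwhm <- sep / 2
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  x <- (seq_len(spec$nx) - (spec$nx + 1) / 2) * spec$dx
  y <- (seq_len(spec$ny) - (spec$ny + 1) / 2) * spec$dy
  g <- function(cx) {
    outer(exp(-y^2 / (2 * sigma^2)), exp(-(x - cx)^2 / (2 * sigma^2)))
  }
  spots <- g(-sep / 2) + g(sep / 2)           # equal-integral spots
  field <- spots + 0.02 * max(spots)          # low uniform background
  field * spec$mean_counts / mean(field)
}

#' @export
print.SyntheticResult <- function(x, ...) {
  cat(sprintf("SyntheticResult (%s): %d x %d, lambda = %g, seed = %d\n",
              x$spec$kind, x$spec$ny, x$spec$nx, x$spec$mean_counts,
              x$spec$seed))
  invisible(x)
}
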