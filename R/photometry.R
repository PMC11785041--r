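#' Absolute photon flux from a calibrated photodiode reading
#'
#' A calibrated Si PIN photodiode placed at the optic's focus, read through a
#' current preamplifier, gives the absolute incident flux as
#' `Phi = K_E * g_s * V_out`, with the gain sensitivity converted from the
#' instrument's uA/V to the pA/V in which the diode calibration is stated.
#' Dark current is assumed negligible.
#'
#' @param K_E Photon-flux-to-photocurrent conversion factor,
#'   photons/(pA s) (e.g. 2382 for a Hamamatsu S3590-06 at 10 keV).
#' @param g_s Preamplifier gain sensitivity, uA/V.
#' @param V_out Photodiode voltage, V (>= 0).
#' @return Photon flux in photons/s.
#' @examples
#' photon_flux(K_E = 2382, g_s = 2, V_out = 4.4)
#' @export
photon_flux <- function(K_E, g_s, V_out) {
  stop_if_not_scalar_pos(K_E, "K_E")
  stop_if_not_scalar_pos(g_s, "g_s")
  if (!is.numeric(V_out) || length(V_out) != 1L || !is.finite(V_out) ||
      V_out < 0) {
    stop("'V_out' must be a single non-negative number", call. = FALSE)
  }
  K_E * (g_s * 1e6) * V_out  # uA/V -> pA/V
}

#' Effective beam width on a tilted sample
#'
#' A planar sample mounted at angle `theta` from normal incidence sees the
#' beam broadened along the tilt direction: `W' = W / cos(theta)`.
#'
#' @param W_beam Beam width at normal incidence, um.
#' @param theta Sample tilt from normal incidence, degrees, in [0, 90).
#' @return Effective beam width, um.
#' @export
effective_beam_width <- function(W_beam, theta) {
  stop_if_not_scalar_pos(W_beam, "W_beam")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta < 0 || theta >= 90) {
    stop("'theta' must be in [0, 90) degrees", call. = FALSE)
  }
  W_beam / cospi(theta / 180)
}

#' Fit the sample-to-detector distance from inverse-square intensities
#'
#' Pulling the fluorescence detector back by known displacements `Delta_d`
#' changes a stationary fluorescence signal by the inverse-square law
#' `I(Delta_d) = alpha / (d_sd + Delta_d)^2`. A bounded Levenberg-Marquardt
#' least-squares fit over `(alpha, d_sd)` recovers the unknown working
#' distance `d_sd`. Intensities must already be normalized for incident-flux
#' variation (e.g. by an ion chamber). Initialization is deterministic: the
#' two extreme displacements admit a closed-form solution
#' (`sqrt(I_near/I_far) = (d_sd + dd_far)/(d_sd + dd_near)`), which is exact
#' on noiseless data and a good starting point otherwise; a fixed fallback of
#' 10 mm is used if the endpoint intensities are non-decreasing.
#'
#' @param displacements Detector displacements `Delta_d`, mm; at least two
#'   distinct values.
#' @param intensities Normalized intensities at each displacement (> 0).
#' @return An object of class `DistanceFitResult`: list with `alpha`
#'   (intensity mm^2), `d_sd` (mm), `residual` (sum of squared residuals).
#' @examples
#' I <- 100 / (31.2 + c(0, 3, 6))^2
#' fit_detector_distance(c(0, 3, 6), I)$d_sd
#' @export
fit_detector_distance <- function(displacements, intensities) {
  dd <- as.numeric(displacements)
  I <- as.numeric(intensities)
  if (length(dd) < 2L || length(I) != length(dd)) {
    stop("need >= 2 displacement/intensity pairs of equal length", call. = FALSE)
  }
  if (length(unique(dd)) < 2L) {
    stop("displacements are degenerate (all identical)", call. = FALSE)
  }
  if (any(!is.finite(I)) || any(I <= 0) || any(!is.finite(dd))) {
    stop("intensities must be positive and all values finite", call. = FALSE)
  }
  i_near <- which.min(dd)
  i_far <- which.max(dd)
  ratio <- sqrt(I[i_near] / I[i_far])
  d0 <- if (ratio > 1) (dd[i_far] - ratio * dd[i_near]) / (ratio - 1) else 10
  if (!is.finite(d0) || d0 <= 0) d0 <- 10
  alpha0 <- I[i_near] * (d0 + dd[i_near])^2
  df <- data.frame(dd = dd, I = I)
  fit <- minpack.lm::nlsLM(
    I ~ alpha / (d_sd + dd)^2,
    data = df,
    start = list(alpha = alpha0, d_sd = d0),
    lower = c(alpha = .Machine$double.xmin, d_sd = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  co <- stats::coef(fit)
  structure(list(alpha = unname(co["alpha"]), d_sd = unname(co["d_sd"]),
                 residual = sum(stats::resid(fit)^2)),
            class = "DistanceFitResult")
}

#' Detector solid angle of collection
#'
#' Small-angle approximation `Omega = A_active / d_sd^2` for a detector of
#' active area `A_active` at distance `d_sd` from the probe spot.
#'
#' @param A_active Detector active area, mm^2.
#' @param d_sd Sample-to-detector distance, mm.
#' @return Solid angle in steradians.
#' @examples
#' solid_angle(127.5, 31.2)  # ~0.13 sr
#' @export
solid_angle <- function(A_active, d_sd) {
  stop_if_not_scalar_pos(A_active, "A_active")
  stop_if_not_scalar_pos(d_sd, "d_sd")
  A_active / d_sd^2
}

#' Fluence per unit time at the probe spot
#'
#' Approximating the probe as an ellipse with the directional resolutions as
#' axes, the probe area is `A_beam = pi * delta_x * delta_y` and the fluence
#' rate is `dF/dt = Phi / A_beam` in photons/(um^2 s). Multiplying by the
#' per-pixel dwell time gives the fluence delivered per pixel.
#'
#' @param Phi Photon flux, photons/s.
#' @param delta_x,delta_y Directional spatial resolutions, um.
#' @return Fluence per time, photons/(um^2 s).
#' @examples
#' fluence_rate(2.1e10, 9.4, 12.2)  # ~5.8e7
#' @export
fluence_rate <- function(Phi, delta_x, delta_y) {
  stop_if_not_scalar_pos(Phi, "Phi")
  stop_if_not_scalar_pos(delta_x, "delta_x")
  stop_if_not_scalar_pos(delta_y, "delta_y")
  Phi / (pi * delta_x * delta_y)
}

#' Evaluate a photometry configuration
#'
#' Computes every photometry quantity derivable from the supplied settings:
#' flux from the photodiode reading, effective beam width under tilt, solid
#' angle, and fluence per time. Full precision values are returned; the
#' `display` element holds values rounded the way they are conventionally
#' reported (solid angle to 2 decimals, fluence to 2 significant figures).
#'
#' @param settings Named list with any of: `K_E`, `g_s`, `V_out` (flux);
#'   `W_beam`, `theta` (beam width); `A_active`, `d_sd` (solid angle);
#'   `Phi` (photons/s; computed from the diode reading when absent),
#'   `delta_x`, `delta_y` (fluence).
#' @return Named list of computed quantities plus a `display` sub-list.
#' @export
photometry_summary <- function(settings) {
  s <- settings
  out <- list()
  if (!is.null(s$K_E) && !is.null(s$g_s) && !is.null(s$V_out)) {
    out$Phi_photons_per_s <- photon_flux(s$K_E, s$g_s, s$V_out)
  }
  if (is.null(out$Phi_photons_per_s) && !is.null(s$Phi)) {
    out$Phi_photons_per_s <- s$Phi
  }
  if (!is.null(s$W_beam) && !is.null(s$theta)) {
    out$W_eff_um <- effective_beam_width(s$W_beam, s$theta)
  }
  if (!is.null(s$A_active) && !is.null(s$d_sd)) {
    out$Omega_sr <- solid_angle(s$A_active, s$d_sd)
  }
  if (!is.null(out$Phi_photons_per_s) && !is.null(s$delta_x) &&
      !is.null(s$delta_y)) {
    out$probe_area_um2 <- pi * s$delta_x * s$delta_y
    out$fluence_rate_photons_per_um2_s <-
      fluence_rate(out$Phi_photons_per_s, s$delta_x, s$delta_y)
  }
  if (length(out) == 0L) {
    stop("no computable photometry quantity; supply (K_E, g_s, V_out) or Phi, ",
         "(W_beam, theta), (A_active, d_sd), and/or (delta_x, delta_y)",
         call. = FALSE)
  }
  disp <- list()
  if (!is.null(out$Omega_sr)) disp$Omega_sr <- round(out$Omega_sr, 2)
  if (!is.null(out$fluence_rate_photons_per_um2_s)) {
    disp$fluence_rate_photons_per_um2_s <-
      signif(out$fluence_rate_photons_per_um2_s, 2)
  }
  out$display <- disp
  out
}

#' @export
print.DistanceFitResult <- function(x, ...) {
  cat(sprintf("DistanceFitResult: d_sd = %.6g mm, alpha = %.6g, SSR = %.3g\n",
              x$d_sd, x$alpha, x$residual))
  invisible(x)
}
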