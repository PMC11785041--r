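# Independent brute-force oracles used to cross-check the FFT-based
# implementation on tiny inputs. These deliberately use naive double loops
# and no code from the package's computational path.

# Unnormalized forward 2D DFT by direct summation.
bf_dft2 <- function(x) {
  ny <- nrow(x); nx <- ncol(x)
  out <- matrix(0 + 0i, ny, nx)
  for (ky in seq_len(ny)) {
    for (kx in seq_len(nx)) {
      acc <- 0 + 0i
      for (j in seq_len(ny)) {
        for (l in seq_len(nx)) {
          ph <- -2i * pi * ((ky - 1) * (j - 1) / ny + (kx - 1) * (l - 1) / nx)
          acc <- acc + x[j, l] * exp(ph)
        }
      }
      out[ky, kx] <- acc
    }
  }
  out
}

# Centered PSD from the brute-force DFT, zero frequency at (ny/2+1, nx/2+1).
bf_psd <- function(psi) {
  ny <- nrow(psi); nx <- ncol(psi)
  S <- Mod(bf_dft2(psi))^2
  S[c((ny / 2 + 1):ny, 1:(ny / 2)), c((nx / 2 + 1):nx, 1:(nx / 2))]
}

# Brute-force radial/sector binning by an explicit pixel loop, applying the
# package's documented membership and binning rules independently.
bf_radial_profile <- function(S, dx, dy, n_bins, mode = "isotropic",
                              half_angle = 30) {
  ny <- nrow(S); nx <- ncol(S)
  uy <- ((0:(ny - 1)) - ny / 2) / (ny * dy)
  ux <- ((0:(nx - 1)) - nx / 2) / (nx * dx)
  urs <- c(); svals <- c()
  for (j in seq_len(ny)) {
    for (l in seq_len(nx)) {
      ur <- sqrt(uy[j]^2 + ux[l]^2)
      if (ur == 0) next
      theta <- atan2(abs(uy[j]), abs(ux[l])) * 180 / pi
      keep <- switch(mode,
        isotropic = TRUE,
        x_sector = theta < half_angle,
        y_sector = (90 - theta) <= half_angle)
      if (!keep) next
      urs <- c(urs, ur); svals <- c(svals, S[j, l])
    }
  }
  ur_max <- max(urs)
  sums <- numeric(n_bins); cnt <- integer(n_bins)
  for (i in seq_along(urs)) {
    b <- min(max(ceiling(urs[i] / ur_max * n_bins), 1), n_bins)
    sums[b] <- sums[b] + svals[i]
    cnt[b] <- cnt[b] + 1L
  }
  list(ur_centers = (seq_len(n_bins) - 0.5) * ur_max / n_bins,
       S_values = ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_),
       counts = cnt)
}

# Root of P * u^a = target by bisection, independent of the closed form.
bf_power_law_root <- function(P, a, target, lo = 1e-9, hi = 1e9) {
  f <- function(u) P * u^a - target
  stopifnot(f(lo) * f(hi) < 0)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)  # bisect in log space
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

# Build a RadialProfile from explicit (u_r, S) pairs for fit-stage tests.
profile_from_points <- function(ur, S, counts = rep(1L, length(ur))) {
  structure(list(ur_centers = ur, S_values = S, counts = counts,
                 sector = sector_spec("isotropic"),
                 n_bins = length(ur), ur_max = max(ur), element = "test"),
            class = "RadialProfile")
}

# Isotropic resolution of a synthetic count map with the labeled heuristic
# range selection; used by several property tests.
delta_res_of <- function(map, snr_res = 5) {
  resolve_map(map, snr_res = snr_res)$isotropic$delta_res
}
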