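test_that("fit ranges enforce their ordering and bin-count preconditions", {
  expect_error(fit_ranges(0.2, 0.1, 0.3, 0.4), "signal_lo < signal_hi")
  expect_error(fit_ranges(0.1, 0.2, 0.15, 0.4), "signal_lo < signal_hi")
  expect_s3_class(fit_ranges(0.1, 0.2, 0.2, 0.4), "FitRanges")
  prof <- profile_from_points(c(0.1, 0.2, 0.3), c(1, 1, 1))
  expect_error(fit_signal(prof, fit_ranges(0.05, 0.12, 0.25, 0.35)),
               "at least 2")
})

test_that("log-log line fit recovers exact power-law data to machine precision", {
  u <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  prof <- profile_from_points(u, 10 * u^-4)
  fit <- fit_signal(prof, fit_ranges(0.01, 0.5, 0.5, 1))
  expect_equal(fit$a, -4, tolerance = 1e-12)
  expect_equal(fit$P, 10, tolerance = 1e-12)

  # two points define the line exactly
  prof2 <- profile_from_points(c(0.1, 1), c(1e4, 1))
  fit2 <- fit_signal(prof2, fit_ranges(0.05, 1, 1, 2))
  expect_equal(fit2$a, -4, tolerance = 1e-12)
  expect_equal(fit2$P, 1, tolerance = 1e-12)

  prof3 <- profile_from_points(c(0.1, 0.2, 0.3), c(1, 0, 2))
  expect_error(fit_signal(prof3, fit_ranges(0.05, 0.35, 0.4, 0.5)),
               "positive")
})

test_that("noise floor is the arithmetic mean over the noise range", {
  prof <- profile_from_points(c(0.1, 0.5, 0.6, 0.7), c(100, 2, 2, 2))
  expect_equal(estimate_noise_floor(prof, fit_ranges(0.05, 0.3, 0.4, 0.8)), 2)
  prof2 <- profile_from_points(c(0.1, 0.5, 0.7), c(100, 1, 3))
  expect_equal(estimate_noise_floor(prof2, fit_ranges(0.05, 0.3, 0.4, 0.8)), 2)
  expect_error(estimate_noise_floor(prof2, fit_ranges(0.05, 0.3, 0.85, 0.9)),
               "no non-empty bins")
})

test_that("knee and Rose frequencies match closed forms and bisection roots", {
  expect_equal(knee_frequency(7, -2.3, 7), 1)
  expect_equal(knee_frequency(16, -4, 1), 2)
  expect_error(knee_frequency(16, 0, 1), "negative")
  expect_error(knee_frequency(-1, -2, 1), "P")

  r <- rose_resolution(1, -4, 1, snr_res = 5)
  expect_equal(r$u_res, 5^(-1 / 4), tolerance = 1e-12)
  expect_equal(r$delta_res, 1 / (2 * 5^(-1 / 4)), tolerance = 1e-12)
  expect_error(rose_resolution(1, -4, 1, snr_res = 0.5), ">= 1")

  # SNR 1 reduces the Rose frequency to the knee
  expect_equal(rose_resolution(3, -3.2, 0.7, 1)$u_res,
               knee_frequency(3, -3.2, 0.7), tolerance = 1e-14)

  # closed form vs independent bisection over a parameter grid
  grid <- expand.grid(P = c(0.5, 10, 1e4), a = c(-2, -3.5, -6),
                      S_nf = c(0.1, 1, 50), snr = c(1, 5, 10))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    uk <- knee_frequency(g$P, g$a, g$S_nf)
    ur <- rose_resolution(g$P, g$a, g$S_nf, g$snr)$u_res
    expect_equal(uk, bf_power_law_root(g$P, g$a, g$S_nf), tolerance = 1e-10)
    expect_equal(ur, bf_power_law_root(g$P, g$a, g$snr * g$S_nf),
                 tolerance = 1e-10)
    expect_lte(ur, uk * (1 + 1e-12))
  }
})

test_that("u_res decreases (delta_res increases) strictly with SNR_res", {
  snrs <- c(1, 2, 5, 10, 20)
  res <- vapply(snrs, function(s) rose_resolution(40, -3.1, 2, s)$u_res,
                numeric(1))
  expect_true(all(diff(res) < 0))
  del <- vapply(snrs, function(s) rose_resolution(40, -3.1, 2, s)$delta_res,
                numeric(1))
  expect_true(all(diff(del) > 0))
})

test_that("delta_res is the half-period of u_res and flags out-of-band results", {
  u <- c(0.05, 0.1, 0.2, 0.4, 0.45)
  prof <- profile_from_points(u, c(0.01 * u[1:3]^-4, 2, 2))
  fit <- fit_resolution(prof, fit_ranges(0.04, 0.25, 0.35, 0.5))
  expect_equal(fit$u_res, (5 * 2 / 0.01)^(-1 / 4), tolerance = 1e-12)
  expect_equal(fit$delta_res, 1 / (2 * fit$u_res))
  expect_false(fit$out_of_band)
  expect_true(fit$valid)

  # a very low floor puts the SNR-5 crossing beyond the measured band
  prof2 <- profile_from_points(u, c(0.01 * u[1:3]^-4, 1e-4, 1e-4))
  expect_warning(fit2 <- fit_resolution(prof2, fit_ranges(0.04, 0.25, 0.35, 0.5)),
                 "exceeds the measured band")
  expect_true(fit2$out_of_band)

  # rising fitted slope marks the fit invalid instead of raising
  prof3 <- profile_from_points(u, c(1, 2, 4, 2, 2))
  expect_warning(fit3 <- fit_resolution(prof3, fit_ranges(0.04, 0.25, 0.35, 0.5)),
                 "invalid")
  expect_false(fit3$valid)
  expect_true(is.na(fit3$delta_res))
})

test_that("parameter recovery: fitted slope tracks the generator's truth", {
  fits <- vapply(1:3, function(s) {
    r <- synth_map(synthetic_spec(nx = 256, ny = 256, a_true = -3.5,
                                  mean_counts = 200, seed = s))
    resolve_map(r$map)$isotropic$a
  }, numeric(1))
  expect_true(all(abs(fits - (-3.5)) < 0.5))
  expect_lt(abs(mean(fits) - (-3.5)), 0.3)
})

test_that("Wiener weights obey their closed-form contracts", {
  # equal signal and noise gives exactly 1/2
  ustar <- knee_frequency(4, -3, 0.5)
  expect_equal(wiener_weights(4, -3, 0.5, ustar), 0.5, tolerance = 1e-12)
  expect_equal(wiener_weights(1, -4, 1, 0.5), 16 / 17, tolerance = 1e-12)

  ug <- seq(0.01, 2, length.out = 100)
  w <- wiener_weights(3, -3.5, 0.2, ug)
  expect_true(all(w >= 0 & w <= 1))
  expect_true(all(diff(w) <= 0))              # non-increasing in u_r
  expect_equal(wiener_weights(3, -3.5, 0, ug), rep(1, 100))  # no-noise limit
  expect_equal(wiener_weights(3, -3.5, 0.2, 0), 1)           # DC passes
  expect_error(wiener_weights(3, -3.5, -1, ug), "non-negative")
})

test_that("Wiener filtering is the identity at zero noise floor", {
  r <- synth_map(synthetic_spec(nx = 32, ny = 32, mean_counts = 150, seed = 8))
  fit <- list(P = 10, a = -3, S_nf = 0, valid = TRUE)
  out <- apply_wiener(r$map, fit)
  expect_equal(out$values, r$map$values, tolerance = 1e-9)
})

test_that("Wiener filtering matches a brute-force DFT filter oracle", {
  r <- synth_map(synthetic_spec(nx = 16, ny = 16, mean_counts = 300, seed = 12))
  fit <- list(P = 50, a = -3, S_nf = 30, valid = TRUE)
  out <- apply_wiener(r$map, fit)

  psi <- sqrt(r$map$values)
  F <- bf_dft2(psi)
  ny <- 16; nx <- 16
  uy <- (((0:(ny - 1)) + ny / 2) %% ny - ny / 2) / ny
  ux <- (((0:(nx - 1)) + nx / 2) %% nx - nx / 2) / nx
  for (j in 1:ny) for (l in 1:nx) {
    ur <- sqrt(uy[j]^2 + ux[l]^2)
    w <- if (ur == 0) 1 else (50 * ur^-3) / (50 * ur^-3 + 30)
    F[j, l] <- F[j, l] * w
  }
  # inverse brute-force DFT
  inv <- matrix(0 + 0i, ny, nx)
  for (j in 1:ny) for (l in 1:nx) {
    acc <- 0 + 0i
    for (ky in 1:ny) for (kx in 1:nx) {
      acc <- acc + F[ky, kx] *
        exp(2i * pi * ((ky - 1) * (j - 1) / ny + (kx - 1) * (l - 1) / nx))
    }
    inv[j, l] <- acc / (nx * ny)
  }
  expect_lt(max(abs(Im(inv))) / max(abs(Re(inv))), 1e-9)  # real before squaring
  expect_equal(out$values, Re(inv)^2, tolerance = 1e-8)

  bad <- list(P = 1, a = 2, S_nf = 1, valid = FALSE)
  expect_error(apply_wiener(r$map, bad), "invalid")
})

test_that("resolution estimates are invariant under intensity rescaling", {
  r <- synth_map(synthetic_spec(nx = 128, ny = 128, mean_counts = 400, seed = 21))
  f1 <- resolve_map(r$map)$isotropic
  scaled <- elemental_map(r$map$values * 5.3, r$map$dx, r$map$dy)
  f2 <- resolve_map(scaled, ranges = f1$ranges)$isotropic
  expect_equal(f2$P / f1$P, 5.3, tolerance = 1e-8)
  expect_equal(f2$S_nf / f1$S_nf, 5.3, tolerance = 1e-8)
  expect_equal(f2$u_knee, f1$u_knee, tolerance = 1e-10)
  expect_equal(f2$u_res, f1$u_res, tolerance = 1e-10)
  expect_equal(f2$delta_res, f1$delta_res, tolerance = 1e-10)
})

test_that("resolution worsens at lower counts for the same ground-truth field", {
  deltas <- function(lam) {
    vapply(1:10, function(s) {
      r <- synth_map(synthetic_spec(nx = 128, ny = 128, mean_counts = lam,
                                    seed = s))
      delta_res_of(r$map)
    }, numeric(1))
  }
  d_lo <- deltas(200)
  d_hi <- deltas(800)
  expect_gt(mean(d_lo), mean(d_hi))
})

test_that("delta_res is robust to signal-range selection on a clean profile", {
  r <- synth_map(synthetic_spec(nx = 256, ny = 256, mean_counts = 5000,
                                seed = 42))
  base <- resolve_map(r$map)$isotropic
  u_hi <- base$ranges$signal_hi / 0.8   # the detected crossing frequency
  noise <- c(base$ranges$noise_lo, base$ranges$noise_hi)
  picks <- list(c(0.1, 1), c(0.08, 0.8), c(0.25, 1))
  prof <- radial_profile(compute_psd(pad_to_even(to_exit_wave(r$map))))
  ds <- vapply(picks, function(p) {
    rg <- fit_ranges(p[1] * u_hi, min(p[2] * u_hi, noise[1]),
                     noise[1], noise[2])
    fit_resolution(prof, rg)$delta_res
  }, numeric(1))
  expect_lt((max(ds) - min(ds)) / min(ds), 0.05)
})
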