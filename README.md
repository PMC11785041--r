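# xrfres

Single-image spatial-resolution estimation for scanning fluorescence X-ray
microscopy (SFXM) elemental maps, plus the beamline photometry that goes
with it.

## The problem

SFXM raster-scans a focused X-ray spot across a specimen (a tissue section,
a cell) and records characteristic fluorescence per pixel, giving
quantitative per-element images of metals such as Ca, Fe, Cu and Zn. The
resolution *achieved* in such an image is set not only by the optic's focal
spot but by photon statistics: weak fluorescence means the finest spatial
frequencies drown in Poisson noise. Two-image methods (Fourier ring
correlation) need a repeat scan, doubling dose and time. `xrfres`
estimates the achieved resolution from a single map.

## The method

For an elemental image `I(x, y)` with pixel steps `Δx, Δy` (μm), the
analysis works on the exit wave `ψ = sqrt(I + offset)` (square root of
intensity, as appropriate for an incoherent signal; `offset` neutralizes
negative pixels some spectrum-fitting programs produce). Its power
spectral density

```
S(u_x, u_y) = |F[ψ]|²,     u_r = sqrt(u_x² + u_y²)
```

is radially averaged to `S(u_r)`, which splits into two regimes:

* a **signal trend** `S(u_r) ≈ P·u_r^a` (power law, `a < 0`) at low
  frequency, fitted by least squares in log–log space over a user-chosen
  range below the knee;
* a flat **noise floor** `S_nf` at high frequency, produced by
  pixel-uncorrelated Poisson counting noise, estimated as the mean of the
  profile above the knee.

The trend crosses the floor at the knee `u_knee = (S_nf/P)^(1/a)`. Requiring
the signal to exceed the floor by the Rose criterion `SNR_res = 5` gives the
resolution-defining frequency and the resolution estimate

```
u_res = (SNR_res · S_nf / P)^(1/a),     δ_res = 1/(2·u_res)   [μm]
```

Restricting the radial average to azimuthal wedges (±30° by default) about
the x or y frequency axis gives directional estimates `δ_res,x`, `δ_res,y`.
The same `(P, a, S_nf)` fit drives a Wiener filter
`W(u_r) = P·u_r^a / (P·u_r^a + S_nf)` for noise suppression.

Photometry helpers cover the closed forms used to characterize a
microprobe station: absolute flux from a calibrated photodiode
(`Φ = K_E·g_s·V_out`), effective beam width under sample tilt
(`W/cosθ`), detector distance from inverse-square intensity measurements,
solid angle (`Ω = A/d²`), and fluence per time
(`dF/dt = Φ/(π·δ_x·δ_y)`).

A synthetic-map generator (power-law spectral field, flat field, Gaussian
spot pair — each Poisson-sampled with a reproducible seed) provides ground
truth for every stage.

## Worked example

```r
library(xrfres)

# synthetic 256x256 map: spectral slope -3.5, mean 200 counts/pixel
r <- synth_map(synthetic_spec(nx = 256, ny = 256, a_true = -3.5,
                              mean_counts = 200, seed = 7))
fits <- resolve_map(r$map, sector = "both")
fits$isotropic
#> PowerLawFit 'synthetic-power_law_field' (isotropic):
#>   S(u_r) ~= 71.3839 * u_r^-3.2789, noise floor 16147.4
#>   u_knee = 0.19139 1/um, u_res(SNR=5) = 0.11715 1/um
#>   delta_res = 4.268 um
```

The fitted exponent (−3.28) tracks the generator's truth (−3.5); the Rose
frequency 0.117 μm⁻¹ means structure with half-period below ≈ 4.3 μm is
too noisy to trust at SNR 5, even though the pixel grid would nominally
support 0.5 μm. Directional fits here give `δ_res,x = 4.14` μm and
`δ_res,y = 4.28` μm. With four times the counts (four times the dwell
time) the estimate sharpens — see the exposure study in the acceptance
script below.

```r
photometry_summary(list(K_E = 2382, g_s = 2, V_out = 4.41,
                        A_active = 127.5, d_sd = 31.2,
                        delta_x = 9.4, delta_y = 12.2))$display
#> $Omega_sr
#> [1] 0.13
#> $fluence_rate_photons_per_um2_s
#> [1] 5.8e+07
```

That is: a 127.5 mm² detector at 31.2 mm collects 0.13 sr, and a
2.1×10¹⁰ photons/s beam focused to a 9.4 μm × 12.2 μm probe delivers
5.8×10⁷ photons/(μm²·s).

Real maps enter through `read_map()` (HDF5 with a configurable dataset
path, single-plane TIFF, or delimited text) and results leave through
`write_report()` (JSON). A command-line wrapper is installed at
`system.file("scripts", "xrfres", package = "xrfres")` with subcommands
`resolve`, `synth`, `photometry`, `wiener`.

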