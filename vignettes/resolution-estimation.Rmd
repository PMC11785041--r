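---
title: "Power-spectral-density resolution estimation for photon-limited elemental maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-spectral-density resolution estimation for photon-limited elemental maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrfres)
```

## The model

A scanning fluorescence X-ray microscope records, per pixel, photon counts
at an element's emission line. Natural images of tissue have power spectra
that fall off roughly as a power law in spatial frequency, while Poisson
counting noise is uncorrelated between pixels and therefore spectrally
flat. On the radially averaged power spectral density of the exit wave
$\psi = \sqrt{I + \text{offset}}$ these two contributions separate
cleanly:

$$S(u_r) \;\approx\; P\,u_r^{\,a} \;+\; S_{nf},
  \qquad a < 0 ,$$

with the power-law term dominating at low $u_r$ and the constant floor
$S_{nf}$ at high $u_r$. The analysis estimates $(P, a)$ by an unweighted
least-squares line through $(\log u_r, \log S)$ over a user-selected
range below the knee, and $S_{nf}$ as the arithmetic mean of the profile
above the knee. The frequency at which the *fitted* signal still exceeds
the floor by a factor $\mathrm{SNR}_{res}$ defines the resolution:

$$u_{res} = \left(\frac{\mathrm{SNR}_{res}\, S_{nf}}{P}\right)^{1/a},
  \qquad \delta_{res} = \frac{1}{2\,u_{res}} .$$

Assumptions worth keeping in mind:

* the square root is the right amplitude transform for an incoherent
  signal; it also variance-stabilizes Poisson counts, which is what makes
  the noise floor flat and, for mean counts $\lambda \gtrsim 20$ or so,
  equal to $N_{pix}\,\mathrm{Var}(\sqrt{X}) \approx N_{pix}/4$ under this
  package's unnormalized DFT convention;
* a single power law describes the signal over the fitted range — real
  spectra bend, which is exactly why the fitted range is explicit,
  recorded, and the sensitivity to it is measured (below);
* the offset applied to maps with negative pixels (from spectrum-fitting
  residuals) only affects the zero-frequency term, which is excluded from
  every profile.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `snr_res` | 5 | — | Rose criterion for a high-quality detection; `snr_res = 1` reduces `u_res` to the knee frequency. |
| `half_angle` | 30 | degrees | wedge half-width for directional profiles; wide enough to average speckle, narrow enough to stay directional. |
| `n_bins` | `floor(min(nx, ny)/2)` | — | one bin per resolvable frequency step of the smaller axis; fewer bins smooth the profile. |
| `dx`, `dy` | — | μm | physical pixel steps; they set the frequency axes, so directional profiles terminate at each axis's own Nyquist frequency `1/(2Δ)`. |
| fit ranges | none (explicit) | μm⁻¹ | $\delta_{res}$ is weakly sensitive to the selection, so it must be explicit and is recorded in every report. |

`suggest_fit_ranges()` provides a clearly-labeled heuristic for scripted
runs: noise range = top 20% of the measured band; the crossing is the
highest-frequency bin still a factor 2 above a provisional floor; signal
range = `[0.08, 0.8]` of the crossing. The upper stop at 0.8 exists
because bins near the knee already contain an appreciable floor
contribution and bias the fitted slope shallow; fitting the decade *below*
the knee recovers generator truth measurably better in the package's own
tests. The heuristic is never a substitute for deliberate selection on
real data.

## Numerical conventions

* **DFT**: unnormalized forward transform (`stats::fft`), PSD shifted so
  $u_r = 0$ is the central pixel of an even-dimensioned grid; odd
  dimensions are padded with the mean of the exit wave (the image actually
  transformed, not the raw map). Along x the frequency axis runs from
  $-1/(2\Delta x)$ to $b_x/(2\Delta x)$ with $b_x = (N_x/2-1)/(N_x/2)$,
  the standard even-length asymmetry. The normalization choice cannot
  change $\delta_{res}$, which depends only on the ratio $S_{nf}/P$.
* **Binning**: uniform in $u_r$ up to the maximum frequency present in the
  kept pixel set; bin statistic is the arithmetic mean (matching the
  expectation argument behind the noise floor); empty bins are kept but
  flagged and excluded from fits; the $u_r = 0$ pixel is excluded always.
* **Sector boundaries**: membership about the x axis is strict
  (`angle < half_angle`), about the y axis closed
  (`90 - angle <= half_angle`), so ties are deterministic and
  45° x- and y-sectors tile every non-zero frequency exactly once.
* **Degenerate fits**: a non-negative fitted slope marks the result
  invalid (with a warning) instead of raising, so batch runs over many
  elements complete. A resolution frequency beyond the measured band is
  reported with an `out_of_band` flag, never clamped — clamping would hide
  optic-limited cases where photon statistics are not the bottleneck.
* **Wiener filtering**: weights $W = Pu_r^a/(Pu_r^a + S_{nf})$ applied in
  the Fourier plane of the exit wave, DC passed unchanged, then inverse
  transform, squaring, and offset subtraction. Small negative outputs are
  preserved, not clipped.
* **Detector-distance fit**: bounded Levenberg–Marquardt on
  $I = \alpha/(d_{sd} + \Delta d)^2$. Initialization is the closed-form
  solution of the two extreme displacement points (exact on noiseless
  data); a naive fixed start such as $d_0 = 10$ mm can stall on the
  $\alpha$ bound for short working distances, which is why the
  deterministic closed-form start was chosen.
* **Photometry units**: detector geometry in mm/mm², resolutions in μm,
  preamplifier gain at the interface in μA/V converted internally to pA/V
  (the diode calibration's unit). Display rounding (2 decimals for sr,
  2 significant figures for fluence) is separated from full-precision
  values.

## What the synthetic generator emulates — and what it does not

`synth_map()` builds ground truth for three regimes:

* `power_law_field`: Fourier amplitudes $\propto u_r^{a_{true}/2}$ with
  random phases from the transform of a white Gaussian field (conjugate
  symmetry for free), inverse-transformed, shifted by the minimum and
  rescaled to a mean of $\lambda$ counts — no hard clipping, which would
  distort the spectrum; the $u_r = 0$ amplitude is set by the rescaling,
  not the (singular) power law. Poisson counts are drawn from a separate
  random substream, so the same seed gives the *same underlying field* at
  every $\lambda$: exposure comparisons isolate counting statistics.
* `flat_field`: constant $\lambda$, isolating the noise floor.
* `spot_pair`: two equal-integral Gaussian spots (FWHM = separation/2) on
  a 2% uniform background, a real-space resolvability sanity target.

Defaults (512×512, $a_{true} = -3.5$, $\lambda = 200$) reflect a
photon-limited elemental map with a typical natural-image slope. What the
generator does **not** emulate: the optic's point-spread function and tilt
broadening, fly-scan motion blur, detector spectral response and pile-up,
spectrum-fitting artifacts (other than the sign of the offset rule), and
spatially varying background. Passing tests therefore validate the
*estimator's statistical machinery* — that it recovers known slopes, floor
levels, and exposure trends — not the full physics of any particular
beamline.

## Problem sizes and tolerances

The validation suite runs slope recovery on five 512×512 maps
($\lambda = 200$), noise-floor checks on 256×256 flat fields
($\lambda = 100$, predicted floor $N_{pix}/4$ within 5%), exposure
monotonicity on ten paired 128×128 maps at $\lambda$ = 200 vs 800, and
selection-sensitivity on a high-count ($\lambda = 5000$) 256×256 map with
three decade-spanning range choices required to agree within 5%.
Brute-force double-loop DFT and pixel-loop binning oracles cross-check the
FFT path on 8×8–16×16 grids at 10⁻⁸ relative tolerance; closed-form knee
and Rose frequencies are checked against log-space bisection at 10⁻¹⁰.

## Known limitations

* One power law, one floor: maps whose spectra show two slopes (e.g.
  mixed cellular and organ-scale structure) need a deliberately chosen
  fitting range; nothing detects the bend automatically.
* The estimate is per element and per image; it degrades gracefully but
  uninformatively when no signal trend rises above the floor (the
  heuristic then refuses and asks for explicit ranges).
* Sector profiles shorten along axes with coarser pixel steps (lower
  Nyquist), so x/y estimates on anisotropic scans cover different bands.
* $\delta_{res}$ is a statistical statement at a chosen SNR, not an
  optical PSF width; comparing values across instruments requires the same
  `snr_res` and comparable range-selection practice.
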