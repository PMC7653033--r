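---
title: "cardioSAXS: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardioSAXS: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the measurement model for scanning micro-focus X-ray diffraction of
striated cardiac muscle, the estimators applied to it, the
power-spectral-density (PSD) undulation indicator for second-harmonic
generation (SHG) micrographs, and the design decisions taken where the
underlying methodology leaves choices open.

# The diffraction measurement model

A focused X-ray beam (13 keV, `λ = hc/E ≈ 0.0954` nm) is raster-scanned
over a thin tissue section; each scan point yields a 2D detector frame.
Per pixel, the scattering angle is `θ = atan(r/L)` for in-plane distance
`r` from the beam center and sample–detector distance `L`, the wavevector
transfer is `q = (4π/λ) sin(θ/2)`, and the azimuth `φ` is measured
counter-clockwise from the +column axis in [0°, 360°). Orientation-valued
results are reported modulo 180°.

After subtraction of the per-line empty-frame background (instrument and
air scattering), the azimuthally averaged intensity of muscle tissue is
modeled as

```
I(q) = S q^(−d) + I_p exp(−(q − q0)² / σ²) + I_bgr
```

a power-law matrix-scattering decay plus the Gaussian (1,1) equatorial
reflection of the hexagonal acto-myosin filament lattice plus a flat
offset. The Gaussian width is **fixed at σ = 0.034 nm⁻¹**; its exponent
uses `σ²` without the conventional factor 2, exactly as the model is
stated (`fitConfig(gaussianTwoSigmaSq = TRUE)` switches to the
`2σ²` convention for comparison). The peak position converts to the
filament spacing `a = 4π/q₀`; a healthy murine myocardium sits near
39 nm.

## Peak fitting

`fitProfile()` minimizes unweighted least squares over
`(S, d, I_p, q₀, I_bgr)` with bounded Levenberg–Marquardt (minpack.lm):

* bounds: `S, I_p, I_bgr ≥ 0`, `d ∈ [0, 6]`,
  `q₀ ∈ [4π/a_max, 4π/a_min]` with defaults `a_max = 45` nm (the
  reference fit boundary) and `a_min = 30` nm (a package choice — the
  methodology states only the upper bound);
* fit window 0.15–0.60 nm⁻¹ by default: it covers the (1,1) ring and
  excludes the beamstop edge;
* initialization: `q₀` at the maximum of the profile minus a
  running-median baseline, `d = 3`, `I_bgr = min I`, `S` from the
  lowest-q point. This is robust on the forward model; the methodology is
  silent on initialization;
* optimizer non-convergence is reported as `converged = FALSE` with the
  last iterate, never as an exception; `atBound` is set when the spacing
  is within 10⁻⁶ nm of a bound (the projected LM step lands on bounds
  exactly);
* Poisson weighting (`weighted = TRUE`) is available but off by default —
  unweighted is the stated procedure.

The radial abscissa of each q bin is the mean q of its contributing
pixels rather than the nominal bin center; with 200 linear bins this
removes most of the discretization bias of the fitted `q₀` (the residual
bias on the default synthetic geometry is below 0.05 nm in spacing).

## Orientation and anisotropy

The azimuthal profile `I(φ)` is the mean background-subtracted intensity
within the annulus 0.2–0.5 nm⁻¹, on 2° bins, normalized as

```
I_norm(φ) = (I(φ) − min I(φ)) / Σ_φ I(φ)
```

with min and sum over valid bins. Two conventions here deserve emphasis:

1. **The denominator is the raw profile sum**, so `Σ I_norm ≤ 1` (equal
   to 1 only when `min I = 0`). The anisotropy defined below therefore
   measures the oriented signal *relative to total scattering in the
   annulus*: an isotropic baseline (matrix scattering, residual
   background) dilutes it. That is a feature, not a bug — a fibrotic
   region without an acto-myosin reflection scores low anisotropy even if
   the little remaining signal is aligned.
2. **Axial statistics with angle doubling.** Diffraction is
   centrosymmetric: `I(φ) ≈ I(φ + 180°)`, so the ordinary circular
   resultant vanishes identically. Doubling the angle is the standard
   treatment of axial data and is adopted here:
   `z = Σ I_norm(φ) e^{2iφ}`, `φ₀ = ½ arg z (mod 180°)`,
   anisotropy `= |z| = 1 − Var`. This is the single most consequential
   convention in the orientation module. The fiber (cardiomyocyte chain)
   orientation is `φ₀ + 90°`, since the equatorial reflection is rotated
   90° with respect to the chains.

Orientations with resultant `|z| < 10⁻³` are flagged undefined and
reported as NA, never interpolated.

**Beamstop handling.** The beamstop wire shadow empties some azimuthal
bins entirely and — more insidiously — depletes the *inner radii* of
others, which would bias their mean toward the outer-annulus intensity
and imprint a spurious 2φ ripple. The azimuthal profile is therefore
computed on a (φ × q) cake-cell grid (12 radial cells by default): a φ
bin is valid only when all of its radial cells contain pixels, and its
intensity is the unweighted mean of cell means. Partially occluded bins
become invalid instead of biased. Fully excluded arcs still bias
orientations whose scattering azimuth falls inside them (up to a few
degrees on the default geometry); the median orientation error over a
tangential phantom stays below 2°.

**Noise floor.** Because `I_norm` subtracts the minimum bin, the
estimator has a Poisson noise floor of roughly
`0.9 σ_bin / (μ_bin √N_bins)` per scan point. The isotropic-limit check
(anisotropy ≤ 0.02 everywhere) is meaningful only on noise-free frames;
at the study's ~1 count/exposure peak intensities the floor is several
times larger. The generator's `poisson = FALSE` mode exists for exactly
such endpoint checks.

## Maps, clustering, lesions

Per-point results are joined into `ParameterMaps` with a shared validity
mask (failed fits propagate as NA). Segmentation choices:

* **k-means on z-scored features.** The five fit parameters span four
  orders of magnitude; clustering the raw values would degenerate to the
  largest-scale feature, so features are standardized first. k = 3, at
  least 10 restarts under a fixed seed, `iter.max = 100`. Clusters are
  relabeled so cluster 1 has the lowest mean spacing, ascending — a
  deterministic labeling contract.
* **KDE mode** of spacing distributions: Gaussian kernel, Silverman's
  rule-of-thumb bandwidth (overridable), 512-point grid over the data
  range ± 3 bandwidths. Constant samples return the constant.
* **Pseudo-Voigt histogram model**: amplitude × (η Lorentzian +
  (1 − η) Gaussian) with a shared half width and η ∈ [0, 1].
* **Lesion thresholding** at 46.0 nm OR `atBound`: at severe lesions the
  fit diverges and pins the spacing at the 45 nm boundary — *below* the
  46 nm threshold — so both criteria are honored. Connected components
  smaller than 4 points (8-connectivity, EBImage) are removed as
  speckle.

## Dosimetry

`D = I₀ τ E (μ/ρ) / (Δx Δy)` with E in joules, μ/ρ in m²/kg and the
**focal FWHM product** as the beam area — not a Gaussian-integral area —
reproducing the reference worked example (2.54 MGy at 13 keV,
1.57 × 10¹² ph/s, 10 ms, 3.1582 cm²/g, 2.9 × 1.4 µm).

# The synthetic scan generator

`simulateScan()` renders, per scan point and pixel,

```
λ(q, φ) = bg_instr(q) + S q^(−d) + I_bgr + I_p exp(−(q − q₀)²/σ²) A(φ)
```

and draws Poisson counts under a fixed seed. Design notes:

* **Instrument vs sample background.** Empty frames physically cannot
  contain the sample's matrix scattering, and the fitted power law must
  survive background subtraction. Empty frames therefore carry an
  instrument background (its own power law + flat term, stored as
  truth), and sample frames add the per-point `(S, d, I_bgr)` model on
  top. Per-line subtraction removes the instrument part exactly in
  expectation.
* **Azimuthal modulation** is a von Mises density on the doubled angle
  (period 180°, centrosymmetric), centered at orientation + 90°, scaled
  to mean 1 over φ so the radial model is exact after angular averaging.
  The measured anisotropy of such a ring is
  `R = I_p g r₁(κ) / (I_p g + M)` where `r₁(κ) = I₁(κ)/I₀(κ)`, `g` is
  the radial average of the Gaussian over the annulus and `M` the
  isotropic (matrix + flat) level there. The generator computes `g` and
  `M` numerically from the pixel q-map and inverts `κ` per point so the
  *pipeline's* measured anisotropy matches the requested ground truth
  (within ±0.05 away from the beamstop arc; `r₁` is capped at 0.99).
* **Beamstop**: a vertical 1 mm wide rectangular shadow through the beam
  center (the wire diameter over the pixel pitch), applied as a mask.
* **Phantoms** (`makeDefaultPhantom`): a tangential fiber-orientation
  field with three scenarios. *sham* — three concentric layers (thin
  38.3 nm rim, 40.8 nm outer layer, 39.5 nm bulk) that differ in all
  five fit parameters, as layered myocardium does; *ring* — uniform bulk
  with an inner annulus lowered by 2.0 nm by default (bracketing
  reported 1.7–2.4 nm differences); *tac_lesion* — a compact lesion with
  a zero-peak-intensity, low-anisotropy core and a 47 nm
  elevated-spacing surround (above both the 45 nm fit bound and the
  46 nm threshold). Defaults: peak intensity 2 counts/exposure (the
  "more than 1 count per 10 ms" regime), anisotropy 0.5.
* **Detector**: 256 × 256 px at 75 µm pitch with the sample–detector
  distance chosen to put the 0.32 nm⁻¹ ring at mid-detector radius
  (`syntheticGeometry()`). At this size the beamstop subtends the same
  angular fraction of the annulus as in a realistic megapixel geometry;
  on much smaller grids the shadow becomes disproportionately wide and
  orientation biases grow.

What the generator does **not** emulate: meridional reflections and the
(1,0) equatorial peak (absorbed by the beamstop in the reference setup),
detector flat-field/polarization/solid-angle corrections, beam drift,
and radiation damage. Passing tests therefore validate the estimators
against the stated forward model, not against every artifact of real
beamline data.

# The SHG undulation indicator

`simulateShg()` renders
`B + A cos²(π (x′ + U sin(2π y′/Λ)) / p)` in coordinates rotated to the
striation orientation, with period `p = 2` µm at 0.109 µm pixel pitch
(the sarcomeric A-band spacing at a typical two-photon ROI resolution),
plus Gaussian noise. `U = 0` gives straight striation.

The indicator pipeline (`shgIndicator`): center square crop (512 px
default, for comparability), mean subtraction, Hann window (default on —
edge leakage would otherwise bias the axes; `window = FALSE` reproduces
a raw-FFT variant), PSD = |FFT|²/N with the DC bin zeroed, principal
axes, cake integration, ratio, RMS. Choices that the methodology leaves
open, and how they were resolved:

* **Axis estimation.** The PCA second-moment tensor weights pixels by
  `P r²`, which lets broadband noise at high frequency tilt the
  eigenvector by a degree or two — enough to de-center a 5° sector. The
  axis *direction* is therefore refined by the axial (doubled-angle)
  spectral mean `½ arg Σ P e^{2iφ}`, which is unbiased for a
  centrosymmetric PSD; the eigenvalue ratio still provides the
  instability flag (< 1.05 → unstable, e.g. isotropic noise).
* **Sector layout.** Sectors are centered on *both* principal axes and
  both directions — a four-armed cross — because the integration is
  specified to cover the two principal axes. The stated opening angle is
  interpreted as the full sector width (half-angle = angle/2);
  `narrowAngle`/`wideAngle` are configurable (defaults 5° and 20°, the
  stated range endpoints).
* **RMS band.** No frequency band is stated. A fixed band from 2 bins
  above DC to 0.8 × Nyquist is dominated by the sampling scatter of
  near-empty sector bins: off-signal bins hold the ratio of two
  few-sample averages of exponentially distributed periodogram values,
  with relative scatter of order `1/√n` per bin, independent of signal
  strength. The default band is therefore *signal-adaptive*: bins whose
  narrow-cake value exceeds both 10× the median narrow-cake value and
  2 × 10⁻³ of its maximum. An image with no directional signal has an
  empty band and scores exactly 0. A fixed band can be forced via the
  `band` argument.
* **Mean, not sum,** within cake bins — so the isotropic ratio is 1
  regardless of the pixel-count difference between the 5° and 20°
  sectors.
* **Undulation wavelength.** The generator's default `Λ = 40` µm keeps
  the azimuthal spread of the undulation sidebands inside the 20° wide
  sector across `U ∈ [0, 0.3 p]`, which is the regime the indicator is
  designed for (slowly wavy fibers). Short-wavelength coherent
  undulation scatters discrete satellites *outside* both sectors and is
  not monotonically resolved by the cake ratio; real myofibril
  undulation is spatially incoherent and behaves like the long-Λ limit.

With these conventions the scalar is strictly decreasing in `U` over
`{0, 0.1, 0.2, 0.3} p` under fixed seeds, exactly scale invariant, and
stable to within 2% under 90° rotation — all asserted in the test suite.

Group comparison: per-image scalars are averaged within each heart, the
per-heart means are paired across groups by heart rank, and a two-tailed
paired Student t-test (`t = mean(d)/(sd(d)/√n)`, `dof = n − 1`) is
applied; n and dof are always reported. Zero-variance differences are
flagged degenerate rather than assigned a p-value.

# Numerical and I/O choices

* Scan stacks serialize to a directory: multi-page 32-bit float TIFF
  frames (value-scaled, scale in the sidecar; integer counts round-trip
  exactly), an 8-bit mask TIFF, and JSON sidecars holding geometry,
  flags and the full-precision ground truth.
* Parameter maps export as per-layer TIFFs, a combined CSV, and a
  full-precision JSON used by `readParameterMaps()`.
* Every pipeline artifact carries a provenance sidecar (stage, package
  version, MD5 of the canonical YAML configuration dump).
* The YAML run configuration rejects unknown keys outright; unspecified
  fields take the documented defaults (`defaultRunConfig()`).
* Negative post-subtraction intensities are retained; clipping would
  bias `I_bgr` upward.
* Radial bins with no pixels and azimuthal bins without full radial
  coverage are flagged invalid and excluded — never interpolated.

# Problem sizes

The test suite and the acceptance script use 16 × 16 scan grids on the
256 × 256 px synthetic detector (20 empty frames per line for the
Poisson runs), 512 × 512 px SHG micrographs, and 3 + 3 synthetic hearts
with 20 micrographs each. These sizes resolve every estimator property
the package asserts — peak-fit bias well below the 0.05 nm contract,
orientation to ~1°, cluster separability, indicator monotonicity — while
a full test run completes in a few minutes on one CPU.

# Known limitations

* Anisotropy is SNR-dependent by construction (see the normalization
  discussion); absolute values are comparable only at comparable
  counting statistics.
* Orientations whose scattering azimuth falls inside the beamstop arc
  carry a bias of up to a few degrees; the affected bins are flagged
  invalid but the truncation of the azimuthal distribution cannot be
  fully undone.
* The spacing lower bound (30 nm) and the fit window are package
  defaults, not measured constants; configurations exploring unusually
  compressed lattices should widen them.
* The PSD indicator's absolute scale depends on the crop size, window
  and band rule; only values computed under one configuration are
  comparable, which is why the pipeline fixes a 512 px crop by default.
* k-means with k = 3 reflects the three-layer anatomy of the reference
  application; it is a descriptive segmentation, not a model selection.
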