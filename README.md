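# cardioSAXS

Quantitative mapping of cardiac-muscle microstructure from **scanning
micro-focus small-angle X-ray diffraction** (µSAXS) and **second-harmonic
generation (SHG) microscopy**, in R.

In pressure-overloaded (hypertrophic, fibrotic) hearts, the acto-myosin
filament lattice and the myofibril architecture change in ways that are
invisible to conventional histology at the micrometer scale. A focused X-ray
beam raster-scanned over a tissue section yields one 2D diffraction pattern
per scan point; the equatorial (1,1) reflection of the acto-myosin lattice
encodes the filament spacing, and the azimuthal distribution of the
scattered intensity encodes the cardiomyocyte chain orientation and its
degree of alignment. SHG micrographs of the same tissue resolve the
sarcomeric striation of individual myofibrils, whose undulation is a
morphological marker of pathological remodeling.

## Models and statistics at the core

* **Reciprocal space.** Per-pixel wavevector transfer
  `q = (4π/λ) sin(θ/2)` with `λ = hc/E`; azimuth φ in [0°, 360°).
* **Background subtraction.** The empty frames recorded in each scan line
  are averaged and subtracted from that line's sample frames.
* **Peak model.** Each azimuthally averaged profile is fitted with
  `I(q) = S q⁻ᵈ + Iₚ exp(−(q − q₀)²/σ²) + I_bgr`, with σ fixed at
  0.034 nm⁻¹, by bounded Levenberg–Marquardt least squares; the filament
  spacing is `a = 4π/q₀`, constrained to [30, 45] nm with an at-bound flag.
* **Orientation and anisotropy.** The azimuthal profile within
  0.2–0.5 nm⁻¹ is normalized as
  `I_norm(φ) = (I(φ) − min I(φ)) / Σ_φ I(φ)` and treated as axial
  (period-180°) circular data: with `z = Σ I_norm(φ) e^{2iφ}`, the
  scattering azimuth is `φ₀ = ½ arg z` (fiber orientation = φ₀ + 90°) and
  the anisotropy is `R = |z| = 1 − Var`, between 0 (disordered) and 1
  (perfectly aligned).
* **Maps and segmentation.** Per-point parameters are assembled into 2D
  maps; k-means (k = 3) on the z-scored five-parameter set (S, d, Iₚ, q₀,
  I_bgr) segments tissue layers; spacing histograms are summarized by a
  KDE mode and pseudo-Voigt fits; lesions are masked by thresholding the
  spacing map at 46.0 nm OR-combined with the at-bound flag.
* **Dosimetry.** `D = I₀ τ E (μ/ρ) / (Δx Δy)` over the focal FWHM area.
* **SHG undulation indicator.** 2D PSD of the micrograph → principal
  symmetry axes → cake integration at a narrow (5°) and wide (20°) opening
  angle about both axes → ratio curve wide/narrow → RMS of (ratio − 1)
  over the signal band. Straight striation scores high; undulated
  myofibrils drive the ratio toward 1 and the scalar toward 0. Groups are
  compared by a two-tailed paired Student t-test on per-heart means.

A synthetic-data module (`makeDefaultPhantom`, `simulateScan`,
`simulateShg`) renders detector stacks and micrographs from known ground
truth — power-law matrix scattering plus a von Mises-modulated Gaussian
ring with Poisson noise, a beamstop-wire shadow, per-line empty frames,
and cos²-striation images with controllable undulation — so that every
stage is testable without beamline data.

## Worked example

```r
library(cardioSAXS)

g <- BeamGeometry()           # 13 keV, 1.57e12 ph/s, 10 ms, 2.9 x 1.4 um
xrayDose(g) / 1e6             # 2.54 MGy deposited per exposure

truth <- makeDefaultPhantom(c(16L, 16L), "tac_lesion")
stack <- simulateScan(truth, syntheticGeometry(), noiseSeed = 3)
red   <- reduceScan(stack)
maps  <- assembleMaps(fitScan(red), orientationMap(red), red@total)
maps
#> ParameterMaps: 16 x 16 scan points (256 valid, 50 at fit bound)
#>   spacing 30.00-45.00 nm, median anisotropy 0.515

les <- thresholdLesion(maps, threshold = 46.0)
diceCoefficient(les$mask, truth@lesionMask)          # 0.980
c(les$inside@meanAnisotropy, les$outside@meanAnisotropy)  # 0.26 vs 0.50

im  <- simulateShg(orientation = 30, undulationAmp = 0.6, seed = 1)
shgIndicator(im)
#> PSDIndicatorResult: scalar = 0.3695 (angles 5/20 deg, axes 29.9/119.9 deg)
```

The lesion mask recovers the generated fibrotic region (Dice 0.98): inside
it the fits hit the 45 nm spacing boundary and the anisotropy drops to
0.26 against 0.50 in the surrounding tissue. The SHG scalar for this
undulated image (0.37) is roughly half the value the same image scores
with straight striation (0.73).

`runPipeline()` (or `inst/scripts/cardiosaxs.R` from a shell) chains the
stages `simulate | reduce | fit | orient | maps | cluster | lesion | dose |
shg-indicator | all` under a YAML configuration with strict key checking,
and writes CSV/TIFF/JSON artifacts with provenance sidecars.

## Vignette

`vignettes/cardioSAXS-methods.Rmd` documents the measurement model, the
estimator conventions (axial statistics, the printed normalization and its
consequences), the synthetic generator's calibration, numerical choices and
known limitations.
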