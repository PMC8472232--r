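---
title: "Models and methods behind beadband"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind beadband}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

beadband models a multiplexed bead-based sandwich immunoassay read out in a
variable-height microfluidic channel. Antibody-coated superparamagnetic
beads of different diameters carry analyte-specific quantum-dot labels; when
the bead mixture flows through a channel whose ceiling height decreases
monotonically from inlet to outlet, each population traps where its diameter
matches the local height and forms a spatially distinct detection band. One
fluorescence image per quantum-dot channel plus one epi-illuminated image
are acquired per field of view (FOV), and the band's signal is the masked
statistic *RFU/Bead-Area*. This vignette records the models, the defaults
and why they were chosen, and what the synthetic validation does and does
not demonstrate.

## The channel model

A channel is described by its length $L$, width $w$, and inlet/outlet
heights $h_i > h_o > 0$ (micrometres). The default height profile is linear,

$$h(x) = h_i + (h_o - h_i)\,x/L,$$

the minimal monotone model consistent with a profilometer trace that falls
from inlet to outlet; measured profiles can be supplied as
(position, height) samples and are interpolated piecewise-linearly. Linear
profiles make every downstream quantity analytic and therefore testable: a
bead of diameter $d$ traps at the unique $x$ with $h(x) = d$ when
$h_o < d < h_i$. The tie rule is inclusive toward *not* trapping: $d \ge
h_i$ is excluded at the inlet (it cannot enter), $d \le h_o$ passes through
(it is never pinched).

Multiplexing capacity uses the band-packing rule
$\lfloor L / (W_\mathrm{band} + S) \rfloor$ with a nominal band width
$W_\mathrm{band} = 500\ \mu m$ and minimum separation $S = 500\ \mu m$ —
centre-to-centre packing, which reproduces the designed 20-band capacity of
a 20 mm channel. Edge-to-edge packing would differ by one band at most for
realistic geometries.

### Flow model

Pressure-driven flow is modelled in the lubrication (wide-slit) limit,
valid because $w$ (millimetres) vastly exceeds $h$ (micrometres):

$$Q = \frac{\Delta P}{R}, \qquad
  R = 12\,\mu \int_0^L \frac{dx}{w\,h(x)^3},$$

which for a linear profile integrates to

$$R = \frac{6\,\mu L}{w}\cdot\frac{1/h_o^2 - 1/h_i^2}{h_i - h_o},$$

reducing to the plane-Poiseuille slit resistance $12\,\mu L / (w h^3)$ as
$h_i \to h_o$. The closed form is verified against adaptive quadrature of
the integral to $10^{-9}$ relative tolerance. Because the integrand weights
the channel by $h^{-3}$, resistance concentrates at the narrow outlet: on
the grid $h_o \in [1, 2.5]\ \mu m \times h_i \in [3, 8]\ \mu m$ the
log-sensitivity of $Q$ to $h_o$ exceeds its sensitivity to $h_i$ at every
point. This is the physical basis for the design rule enforced by
`design_check()`: outlet heights below $1.5\ \mu m$ throttle the flow,
slowing band formation and risking bead aggregation and wall adsorption.
No particle tracking or CFD is attempted; band-formation *times* are out of
scope.

## The synthetic imaging model

Every downstream stage is validated against images with exact ground
truth. The generator's defaults describe one fixed set of study conditions
and are not tuned per experiment:

* **Geometry.** 1344 × 1100 pixel frames (stored as 1100 × 1344 matrices)
  at 0.325 µm/pixel, the scale of a cooled CCD behind a mid-magnification
  objective. Default bead populations: ~4.5 µm (reporting IL-6, channel
  q525), ~2.8 µm (GFAP, q585), optionally ~1 µm (IL-8, q655); diameters are
  truncated-normal with a 3% CV, consistent with monodisperse commercial
  beads.
* **Packing.** Detection bands are densely packed, so beads are placed on a
  randomized, jittered grid sized to the largest bead — a few percent
  areal coverage at the default counts (1500 beads of 2.8 µm per FOV). The
  grid guarantees non-overlap in O(n) time; a FOV that cannot hold the
  requested count is a generation error, not a silent truncation.
* **Binding response.** Mean on-bead signal at analyte concentration $c$
  (pg/mL) follows a Hill/Langmuir form
  $r(c) = r_0 + r_{\max} c^{n}/(K^{n} + c^{n})$ with defaults
  $r_0 = 50$ RFU, $r_{\max} = 2000$ RFU, $K = 2000$ pg/mL, $n = 1$ — the
  simplest monotone saturating response, with $K$ placed mid-range of the
  default calibrator series (0–10,000 pg/mL).
* **Optics.** A row-stochastic-up-to-gain crossover matrix (diagonal 1,
  off-diagonal 0.05) maps each fluorophore into every detection channel;
  additive per-bead autofluorescence defaults to 5 RFU, raised to 150 RFU
  for ~2.8 µm beads in q525, emulating the strong 525 nm polymer
  autofluorescence of that bead class. The epi image renders beads darker
  than a bright background (attenuation 400 on background 1000) under a
  smooth multiplicative illumination field (±15% linear gradient by
  default); polarity is configurable since reflected-light contrast depends
  on the instrument.
* **Nuisances.** Per-pixel noise is Gaussian with
  $\sigma = \sqrt{\sigma_r^2 + g\,I}$ ($\sigma_r = 10$, $g = 0.5$), a
  Gaussian approximation to read-plus-shot noise. Each FOV receives a
  log-normal excitation jitter (5% log-sd), which is what gives replicate
  FOVs realistic dispersion. Five bright debris spots per channel per FOV
  emulate untethered quantum-dot aggregates: present in fluorescence,
  absent from the epi image, hence excluded by the mask. Smaller bead
  types lodge in an upstream band with probability 0.02 each (carryover);
  larger beads can never appear downstream.
* **Reproducibility.** Every FOV draws from a private sub-seed
  `(master * 69069 + counter * 1013904223) mod (2^31 - 1)`, so any subset
  of a run can be regenerated bit-identically.

What the generator does **not** emulate: diffraction/PSF blur, spectral
emission curves (the crossover matrix abstracts them), bead stacking or
partial focus, matrix effects of serum or whole blood, and the flow
dynamics of band formation. Passing the synthetic suite therefore shows the
*pipeline* is correct and robust to the modelled artifacts; it does not
certify performance on any particular instrument's raw images.

## Quantification

Per FOV: (1) pseudo-flat-field correct the epi image by dividing by a
large-sigma Gaussian blur of itself and rescaling to preserve the global
mean; (2) binarize the corrected epi image to the bead mask $B'$; (3)
background-correct each fluorescence channel by subtracting the median of
off-mask pixels (lowest-decile median when no mask is available), clamping
at zero; (4) form $F' = B' \odot$ fluorescence, $b = \sum B'$,
$f = \sum F'$, and report $f/b$ per channel. Band-level results average
FOVs, report SEM across FOVs, and subtract the matched control band after
averaging; negative control-subtracted values are preserved.

Numerical choices that matter:

* The blur uses separable FFT convolution with **odd-reflection (linear
  extrapolating) padding**, `pad(-t) = 2 img(1) - img(1 + t)`. Odd
  reflection continues a linear trend exactly, so a full-image linear
  illumination ramp is estimated — and hence divided out — essentially
  exactly; plain mirror padding rounds the ramp near the borders by
  ~$0.8\,\sigma \times$ slope, leaving a multi-percent residual. With this
  padding the default sigma, one quarter of the smaller image dimension,
  removes a 0.5→1.5 ramp to under 1% while leaving beads (two orders of
  magnitude smaller) untouched.
* Otsu thresholding is the default binarization and assumes beads occupy a
  non-negligible fraction of the frame, true of packed detection bands.
  The local-mean alternative (window radius 15 px, offset 0) is preferable
  for sparse fields but needs a positive offset on images whose background
  retains smooth structure after correction.
* Local-mean comparisons carry a $10^{-9}\times$range guard because the
  underlying FFT filtering leaves ~$10^{-13}$ ripple on exactly flat
  regions, which a strict inequality would binarize into noise.
* An empty mask is an explicit error (`b = 0` never yields a silent NaN).

The masked statistic is exactly invariant to off-mask signal of any
intensity, scales linearly with fluorescence gain, and — because the mask
comes from the flat-fielded epi image — moves by well under 3% when a
smooth illumination gradient is imposed.

## Bead sizing

Bead populations are characterized from confocal stacks: pixelwise
maximum-intensity projection, local-mean thresholding (bright particles),
connected-component labelling, optional border and minimum-area filters,
then equivalent-circle diameters $d = 2\sqrt{A/\pi}$ summarized with the
sample ($n-1$) standard deviation and CV. The "default" local-threshold
heuristic of common image-analysis GUIs is not reproduced bit-for-bit;
local-mean thresholding is equivalent in effect on high-contrast bead
images and is fully parameterized. Labelling is 8-connected by default
(4-connected labels are merged across diagonal contacts by union-find);
4-connectivity is available. Touching beads are not watershed-split, which
is why the simulated sizing acquisitions space beads on a grid, as mounted
beads under a coverslip are approximately dispersed.

## Assay statistics

* **Standard curve:** four-parameter logistic
  $r(c) = d + (a - d)/(1 + (c/c_0)^b)$ fitted by Levenberg–Marquardt, with
  a linear-in-$\log_{10}c$ fallback; both refuse non-monotone fits. The
  4PL is standard immunoassay practice; the package does not attempt to
  guess which model any particular laboratory used.
* **LOD:** blank mean + 3 × sample SD (conventionally $n = 10$ blanks),
  converted to concentration through the fitted curve. The blanks are
  included in the curve fit as zero-concentration replicates: they anchor
  the zero asymptote $a$, without which the LOD signal of a clean assay
  can fall below a 3-replicate estimate of $a$ and become uninvertible.
  Sample ($n-1$) SD is used throughout; at these $n$ the choice is not
  innocuous and is stated rather than hidden.
* **CVs:** intra-assay = SD/mean of same-day replicates ($n = 3$
  conventionally); inter-assay = arithmetic mean of per-day CVs across
  (conventionally three) days.
* **Crossover test:** two-tailed two-sample t-test, pooled-variance
  Student's by default (the classic reading of "two-tailed t-test"), Welch
  optional. Used to ask whether a band whose own analyte is absent responds
  to a co-analyte's presence; non-significance means carryover does not
  create false positives at the modelled rates.
* **Method comparison:** OLS trend of test vs. reference concentrations
  plus mean bias against the identity line — slope < 1 with negative bias
  is the signature of a test assay detecting only a subset of the analyte
  forms the reference detects.

## Reagent stoichiometry

Adding an analyte to the panel uses one fixed molar-ratio chain relative to
the maximum analyte amount the assay must resolve: capture antibody 5×,
detection antibody 10×, quantum dots 2× the detection antibody (20× the
analyte). Amounts convert to volumes through stock concentrations;
antibody molar mass defaults to 150 kDa (intact IgG) and the recipe flags
when that default was used.

## Problem sizes and validation design

The validation suite runs the system-level checks at the full default frame
size and study design — the 6-point calibrator series with 3 replicates and
10 blanks, 6 FOVs per multiplex condition, 100 randomized flow geometries,
a 7 × 7 design grid for outlet dominance, and 300-bead sizing populations —
while unit tests exercise the same code paths on reduced frames (roughly
200 × 260 pixels, tens of beads) where a property does not depend on scale.
All expected values in the tests were computed from independent oracles
(hand arithmetic, brute-force loops, quadrature, closed forms) before being
frozen.

## Known limitations

* The flow model is quasi-1-D lubrication theory; it ignores bead-induced
  blockage, which in a forming band feeds back on the flow.
* Trap positions ignore band *width*: a band is represented by its centre,
  and the 500 µm nominal width enters only through the packing rule.
* The quantification assumes epi and fluorescence frames are pixel-aligned
  (shared field of view); no registration is performed.
* Estimated concentrations for all bands of a multiplex are inverted
  through a single fitted curve in `run_end_to_end()`, which presumes the
  panel's assays share a response calibration — true of the generator,
  not necessarily of a bench panel.
* Simulated LOD/CV values characterize the synthetic noise model, not any
  laboratory's reagents; they are not comparable to bench values.
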