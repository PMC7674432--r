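---
title: "SPOT reconstruction: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SPOT reconstruction: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotr)
```

## What the method measures

Spectrum and polarization optical tomography (SPOT) extracts three
co-registered views of lipid membranes from six structured-illumination raw
images — three stripe-pattern directions, each acquired at two pattern
phases shifted by $\pi$:

* **Intensity** — an optically sectioned morphology image, obtained by HiLo
  fusion per pattern direction and averaging the three sectioned images.
* **Polarity** — the emission ratio of two spectral channels of a
  solvatochromic dye (longer / shorter wavelength). The emission of such
  dyes red-shifts in polar lipid environments, so a higher ratio means a
  more polar membrane.
* **Phase (lipid order)** — the polarization modulation depth $m$ of the
  fluorescence response to the rotating excitation polarization, together
  with the ensemble dipole orientation $\varphi$. Dipoles wobble less in
  ordered membranes, giving a deeper modulation.

Because s-polarized interference stripes carry a polarization perpendicular
to their wavevector, rotating the pattern direction rotates the excitation
polarization for free: the same six frames provide both the sectioning
phases and the three polarization states.

## Forward model

The simulator renders point dipole emitters with per-emitter brightness
$B$, emission ratio $\rho$, orientation $\varphi$ and wobble modulation
depth $m \in [0,1]$. The expected image for direction $k$, phase $p$,
channel $c$ is

$$I_{kpc}(x) = b + \sum_e B_e\, w(x - x_e)\,
  \bigl[1 + M(z_e)\cos(\vec k_k \cdot \vec x + p)\bigr]\,
  \bigl[1 + m_e \cos 2(\theta_k - \varphi_e)\bigr]\, g_c\, s_c(\rho_e),$$

with a separable Gaussian detection weight
$w = \exp[-4\ln 2\,(dx^2{+}dy^2)/\mathrm{FWHM_{lat}}^2]
     \exp[-4\ln 2\, dz^2/\mathrm{FWHM_{ax}}^2]$ and excitation polarization
$\theta_k = \theta_k^{pattern} + \pi/2$. Three modelling choices deserve
emphasis; all are this package's own decisions, made because analytic
testability was the priority:

* **Gaussian PSF.** Only the resolution (FWHM) is physically specified;
  a separable Gaussian makes every oracle in the test-suite closed-form.
  The two-fluorophore accuracy numbers below inherit a mild sensitivity to
  this choice.
* **Axial pattern-contrast envelope.** The illumination stripes are
  projected at the focal plane, so their contrast washes out with defocus.
  We model the contrast envelope $M(z)$ with the same Gaussian as the axial
  PSF. This is the mechanism that gives HiLo its sectioning: a defocused
  layer appears in the uniform image but not in the phase-difference image.
* **Pattern phase sampled at the detection pixel.** The modulation factor
  uses $\vec k \cdot \vec x$ at the pixel, not at the emitter — the
  smooth-sample approximation under which blur and modulation commute.
  Phase-averaged (uniform) images are identical under either convention,
  but this one keeps the rectified-cosine demodulation of HiLo exact for
  sparse scenes: with the pattern point-sampled at each emitter, the
  low-frequency band of an isolated emitter would be multiplied by
  $|\cos\delta_e|$ of its private pattern phase, an error no two-phase
  algorithm could undo (the recovered modulation depth would be off by up
  to $\sim$0.5).

For an extended defocused layer, the axial envelope on a *point* emitter's
peak does not describe energy conservation — defocus spreads light, it does
not destroy it. Plane scenes used by the sectioning tests therefore scale
the per-emitter brightness by $1/w(0,0,z)$ so that the wide-field mean of
an out-of-focus plane matches the in-focus one, as in a real thick sample.

Channel splitting is not physically pinned down by a ratiometric
measurement, so both conventions are implemented and selectable:
`equal_total` ($B\rho/(1{+}\rho)$ vs $B/(1{+}\rho)$) and
`equal_denominator` ($B\rho$ vs $B$). Either way the noiseless channel
quotient is $\rho$.

Noise is Poisson shot noise on expected photons plus Gaussian read noise
(default SD 1 photon-equivalent, an sCMOS-like figure); a seed is mandatory
so every noisy dataset is reproducible.

## HiLo sectioning

For each direction, with $I_0$ and $I_\pi$ the two phase images:
$U = (I_0 + I_\pi)/2$ is pattern-free; $D = (I_0 - I_\pi)/2$ retains the
pattern and therefore only in-focus signal. The sectioned image is

$$\mathrm{Hi} + \alpha\,\eta\,\mathrm{Lo}, \qquad
  \mathrm{Hi} = U - \mathrm{LP}[U], \qquad
  \mathrm{Lo} = \tfrac{\pi}{2}\,\mathrm{LP}[|D|],$$

clipped at zero last. The Gaussian low-pass has half-amplitude at the
cutoff (default: half the pattern frequency), so Hi and Lo partition the
spectrum exactly; $\pi/2$ corrects the mean of the rectified cosine, and
$\alpha = 1$ throughout. Numerical details that matter:

* **Rectification on a 2$\times$ Fourier-interpolated grid.** $|D|$
  computed pixel-wise generates harmonics of the stripe carrier; at the
  default period (3.54 px) the 4th harmonic aliases *into* the low-pass
  band for the axis-aligned direction, producing a position-dependent
  $\sim$8% gain error in that direction only. $D$ is band-limited, so
  Fourier upsampling is exact; rectifying and low-passing on the fine grid
  then decimating removes the alias entirely.
* **The merge factor $\eta$** equalizes the radially averaged spectral
  amplitudes of Hi and Lo in a $\pm 10\%$ band around the cutoff, computed
  per image pair. Both bands have half-amplitude transfer at the cutoff,
  so a sound $\eta$ is $O(1)$; ratios outside $[0.1, 10]$ indicate an
  empty band (for example a featureless defocused plane, where the Hi band
  holds only border artefacts) and fall back to $\eta = 1$, flagged in the
  result attributes. Without this guard the automatic scaling silently
  re-amplifies the rejected background.
* **Five-phase SIM input** is adapted by taking the mean of the five
  phases as the uniform image and synthesizing the complementary phase as
  $2U - I_1$, so one HiLo code path serves both acquisition modes.

## Harmonic polarimetry

With three equally spaced excitation polarizations the per-pixel cosine
response is solved exactly by its discrete Fourier coefficients:
$a_0 = \tfrac13\sum_k I_k$, $a_1 = \tfrac23\sum_k I_k e^{-2i\theta_k}$,
$m = |a_1|/a_0$, $\varphi = -\arg(a_1)/2 \bmod \pi$. The $2/3$
normalization is fixed by requiring $m$ to equal the true cosine
modulation depth, and the sign convention makes $\varphi$ the excitation
angle of maximal response measured from the image $+x$ axis. Unequally
spaced angle sets are rejected rather than least-squares-solved: the
exactness contract is the module's core invariant (machine-precision
recovery for any single-cosine input, verified for $10^4$ random triples).
Pixels with $a_0 \le$ an intensity threshold, or with raw $|a_1|/a_0$
beyond $1 + $ tolerance (noise, not physics), are masked.

## The two-fluorophore accuracy experiment

Resolution limits mapping accuracy because the PSF mixes neighbouring
molecules' signals. The canonical scene: two equal-brightness ideal
dipoles, 300 nm apart axially and 50 nm laterally; the in-focus one has
$\rho = 1$, $\varphi = 0^\circ$; the defocused one $\rho = 0.5$,
$\varphi = 60^\circ$. Errors are $|V_O - V_A|/V_R$ with ranges 1.2 (ratio),
1 (depth), $\pi$ (orientation, wrapped into $[0, \pi/2]$ so 50% is the
worst case). Maps are rendered noiselessly at wide-field FWHM
(230/670 nm) and at doubled resolution, then read at each fluorophore's
nearest pixel; per-fluorophore errors, both channel-split conventions and
their mean are all reported, with the headline being the in-focus
fluorophore under the equal-denominator split.

One caveat is intrinsic to this planar model: the orientation recovered at
either fluorophore is a phasor mixture of $0^\circ$ and $60^\circ$ and so
lies between them — the wide-field orientation error cannot exceed
$30^\circ/180^\circ \approx 16.7\%$. The accuracy report carries this
bound in its `note` attribute, and the CLI prints it. Reported values
above the bound would require 3D dipole tilt, polarized detection or
region-averaged evaluation, none of which this simulation includes.

## Measurement utilities

Polyline profiles are sampled at 1-px arc-length steps across a
perpendicular band with nearest-pixel lookup (measurements live on
discrete maps; interpolation would blur masked edges). Repeated
acquisitions are accepted when the fluctuation $(\max - \min)/\mathrm{mean}
\le 0.15$, inclusive — the strictest common reading of a
"fluctuation within 15%" rule, applied against motion drift. Groups on the
polarity–phase plane are summarized by their centroid and sample
covariance; the $\sigma$ contour is the Mahalanobis distance-1 ellipse, and
a point is classified into a compartment group only when it lies inside
exactly one $\sigma$ contour (otherwise "ambiguous" or "unassigned" — the
honest outcome for overlapping groups such as Golgi and late endosomes).

## What the synthetic generator does and does not emulate

It emulates: sinusoidal two-beam illumination with s-polarized excitation
tied to pattern direction, per-emitter spectral splitting and wobble
response, Gaussian optics, Poisson + read noise, fiducial bead fields under
a known affine, and smooth illumination envelopes. It does not emulate:
vectorial high-NA effects, 3D dipole tilt out of the sample plane,
photobleaching or photokinetics, detection-path polarization, chromatic
aberration beyond an affine, or the crowded extended membrane morphologies
of real cells. Passing tests therefore certify the *algorithms* under the
stated optical model, not instrument performance on real samples.

## Problem sizes and tolerances used by the test-suite

End-to-end recovery runs 24 isolated in-focus emitters on a
$240 \times 336$ px field (tolerances: ratio 2%, $m$ 0.05, $\varphi$
2°, with $\varphi$ checked where $m \ge 0.1$ — below that the orientation
is barely identifiable by construction). Sectioning contracts use
$48 \times 48$ px planes with one emitter per pixel and a 390 nm stripe
period so that appreciable pattern contrast survives the lateral PSF;
interior means (8 px margin) avoid border-truncation artefacts of the
finite lawn. Registration uses 50 beads on $256^2$ px with sub-0.05 px RMS
recovery through localization. The two-fluorophore scene uses a
$33 \times 33$ px field. All randomized tests run under fixed seeds.

## Known limitations

* Two-phase HiLo cannot section sparse point scenes *per emitter* — an
  isolated point samples the pattern at a single phase. The
  pixel-sampled-pattern model documents the approximation under which the
  pipeline's per-emitter contracts hold; for extended structures (the
  method's actual use case) the two models coincide.
* The modulation depth saturates for crowded orientations within a PSF:
  opposing dipoles cancel their second harmonic, reading as low order
  rather than mixed orientation.
* Emission-ratio accuracy depends on both channels seeing the same
  sectioned structure; the pipeline therefore sections each channel with
  identical parameters, and $\eta$'s scale-invariance makes the ratio
  immune to the merge factor.
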