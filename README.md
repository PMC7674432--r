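# spotr

Reconstruction toolkit for **Spectrum and Polarization Optical Tomography
(SPOT)** — a structured-illumination fluorescence microscopy modality that
turns six raw images (three stripe directions × two π-shifted phases) into
three co-registered views of lipid membranes in live cells:

* **optically sectioned intensity** (morphology) via HiLo fusion per
  pattern direction,
* **lipid polarity** as the emission ratio of two spectral channels of a
  solvatochromic dye (the emission red-shifts in polar lipids),
* **lipid phase / order** as the polarization modulation depth *m* and
  ensemble dipole orientation φ, from ±1st-harmonic analysis of the three
  polarization states that s-polarized stripe illumination provides for
  free.

The package is aimed at microscopists processing SPOT/SIM acquisitions and
at method developers who need a fully testable stand-in for the
instrument: it includes a physics forward simulator (dipole emitters,
Gaussian PSF, sinusoidal illumination with an axial contrast envelope,
Poisson + read noise), bead-based channel registration and flat-field
calibration, and the accuracy-analysis framework used to quantify how
spatial resolution limits these measurements.

## The estimators in brief

For each direction the π-pair gives `U = (I0 + Iπ)/2` (pattern-free) and
`D = (I0 − Iπ)/2` (in-focus only). HiLo fuses

```
sectioned = max(Hi + α·η·Lo, 0),   Hi = U − LP[U],   Lo = (π/2)·LP[|D|]
```

with α = 1 and a Gaussian low-pass at half the pattern frequency; η
equalizes the two bands' spectral amplitudes at the cutoff. With the three
excitation polarizations θ_k the per-pixel harmonics

```
a0 = (1/3) Σ I_k,   a1 = (2/3) Σ I_k e^(−2iθ_k),
m  = |a1| / a0,     φ = (−arg a1)/2 mod π
```

recover a single-cosine response exactly. Mapping accuracy is scored as
`|V_O − V_A| / V_R` with ranges 1.2 (emission ratio), 1 (modulation
depth), π (orientation).

## Worked example

```r
library(spotr)

cfg <- spot_config(image_shape = c(96, 96), background = 2)
em <- dipole_emitters(
  x = c(1950, 4160), y = c(1950, 4160), z = 0, brightness = 8000,
  emission_ratio = c(1.2, 0.6),
  orientation = c(30, 120) * pi / 180,
  wobble = c(0.9, 0.4)
)
raw <- render_spot_stack(em, cfg) |> add_noise(seed = 7)
raw
#> <spot_stack> 96 x 96 px, 3 directions x 2 phases x 2 channel(s) [red, green]
#>   rendered from 2 emitter(s)
#>   noise seed: 7

res <- run_reconstruction(raw, pipeline_config(cfg, ratio_threshold = 5))
idx <- cbind(c(31, 65), c(31, 65))      # the emitters' pixels
round(res$ratio$ratio[idx], 3)          # emission ratio (truth 1.2, 0.6)
#> [1] 1.184 0.596
round(res$maps$m[idx], 3)               # modulation depth (truth 0.9, 0.4)
#> [1] 0.904 0.390
round(res$maps$phi[idx] * 180 / pi, 1)  # orientation, deg (truth 30, 120)
#> [1]  30.3 120.0
```

The noisy six-frame stack is sectioned, divided into a polarity map and
harmonically analysed; at each emitter's pixel the maps return its
emission ratio, wobble modulation depth and orientation to within a few
percent despite shot noise. `autoplot(res$maps)`, `autoplot(res$ratio)`
and `plot_polarity_phase()` give the standard displays;
`tidy()`/`glance()` methods return tibbles for downstream analysis.

A thin command-line front end wraps the same functions:

```sh
exec/spot simulate  --config scene.yaml --seed 3 --out simout/
exec/spot reconstruct --in simout/raw_stack.tif --out recon/
exec/spot calibrate register --a beadsA.tif --b beadsB.tif --out affine.json
exec/spot accuracy --mode both --out report.csv
exec/spot measure --map recon/modulation_depth.tif --polyline line.csv --out meas.csv
```

## Package layout

| module | contents |
|---|---|
| `R/config.R`, `R/emitters.R`, `R/render.R` | optical configuration, dipole emitter tables, forward simulator, noise, bead fields |
| `R/calibration.R` | bead localization, affine registration, resampling, flat-field estimation/correction |
| `R/sectioning.R` | HiLo pair fusion, per-direction sectioning, SPOT intensity, 5-phase SIM adapter |
| `R/polarimetry.R`, `R/spectral.R` | harmonic m/φ maps, emission-ratio maps, validity masks |
| `R/accuracy.R` | mapping error, two-fluorophore experiment, noise sweep |
| `R/stats.R` | polyline sampling, repeat-fluctuation acceptance, group ellipses, compartment classification |
| `R/pipeline.R`, `R/io.R` | channel layout/splitting, end-to-end driver with manifest, TIFF/JSON/YAML IO |

See `vignettes/spot-methods.Rmd` for the model, the estimator
conventions, and the reasoning behind every numerical choice.
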