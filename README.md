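# ppmfiber

Quantification of fibrillar collagen organization from polychromatic
polarization microscopy (PPM) images, with a full synthetic test bench.

## The scientific problem

The arrangement of fibrillar collagen around tumors carries prognostic
information, but the reference modality for imaging it — second
harmonic generation (SHG) microscopy — is slow, expensive and absent
from routine pathology labs. PPM instead exploits collagen's intrinsic
birefringence: the illumination is a *spectral polarization fan*
(every wavelength elliptically polarized at ellipticity 40°, with the
ellipse azimuth sweeping 180° across 400–700 nm). A birefringent fiber
of retardance δ and fast axis α rotates each wavelength's state on the
Poincaré sphere, and after a circular analyzer the perturbation
appears as color: hue encodes the fiber axis, brightness the
retardance. Subtracting two complementary acquisitions (fan azimuth
offsets 0° and 90°) cancels stain absorption exactly and leaves only
the birefringent signal.

`ppmfiber` implements:

* **optics** — Poincaré-sphere retarder propagation, circular-analyzer
  transmissions, and a spectral renderer (verified against an
  independent Jones-matrix oracle);
* **phantom** — a seeded synthetic stromal field with von
  Mises-distributed finite fibers, eosin-like staining, camera tint
  and sensor noise, plus an exact SHG-like ground-truth channel;
* **pipeline** — white balance, signed differential, monochrome fiber
  map, brightfield overlay;
* **fibermetrics** — structure-tensor orientation fields, 256-px block
  orientation, the sinusoid orientation map, and the alignment
  coefficient (mean resultant length on doubled angles);
* **agreement** — Bland–Altman bias, limits of agreement and
  within-limits fraction, with plotting;
* **cli** — `simulate` / `process` / `quantify` / `compare`
  subcommands with manifests and deterministic seeding.

## Worked example

Simulate a moderately aligned stromal field, run the differential
workflow, quantify per-block orientation and alignment, and compare
the PPM-derived metric against the SHG-derived one:

```r
library(ppmfiber)

spec <- fiberStudySpec(kappa = 8, meanOrientation = 30, seed = 7)
phantom <- generatePhantom(spec)
imgs <- renderPPMPair(phantom)                       # i0, i90, bf, shg
mono <- toMonochrome(differentialImage(imgs$i0, imgs$i90))
metrics <- blockMetrics(mono, reference = imgs$shg)
metrics
#>   block_id row col  coverage orientation_deg sin_orientation alignment
#> 1        1   0   0 0.3850098        33.23476       0.5480707 0.9659004
#> 2        2   0 256 0.3988647        30.97032       0.5145940 0.9641404
#> 3        3 256   0 0.3609772        32.44680       0.5365163 0.9710754
#> 4        4 256 256 0.3447571        30.60346       0.5090935 0.9634901
#>   n_pixels_used
#> 1         23203
#> 2         23899
#> 3         21876
#> 4         20747

blandAltman(metrics$sin_orientation,
            blockMetrics(imgs$shg)$sin_orientation)
#> Bland-Altman agreement over 4 pairs
#>   bias                +0.021333
#>   sd of differences   0.0050487
#>   limits of agreement [+0.011437, +0.031228]
#>   within limits       100.0%
```

The simulated mean orientation (30°) is recovered within a few degrees
in every block, and the alignment coefficients (~0.96) reflect the
strong concentration (von Mises κ = 8) of the simulated fibers.

The same chain runs from the command line; every stage writes a
manifest with the package version, seed, config echo and input
checksums:

```sh
SCRIPT=$(Rscript -e 'cat(system.file("exec", "ppm.R", package = "ppmfiber"))')
Rscript "$SCRIPT" simulate --config config.json --out sim/
Rscript "$SCRIPT" process  --i0 sim/i0.tif --i90 sim/i90.tif \
                           --bf sim/bf.tif --out proc/
Rscript "$SCRIPT" quantify --mono proc/mono.tif --reference sim/shg.tif \
                           --out metrics_ppm.csv
Rscript "$SCRIPT" compare  --a metrics_ppm.csv --b metrics_shg.csv \
                           --out report.json --plot ba.png
```

## Documentation

Design rationale and the full optical model are described in the
methods vignette, `vignettes/ppm-collagen-quantification.Rmd`.
Function-level documentation lives in roxygen comments in `R/`.

## License

MIT (see `LICENSE`).
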