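---
title: "Differential polychromatic polarization imaging of fibrillar collagen: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential polychromatic polarization imaging of fibrillar collagen: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppmfiber)
```

# The problem

Fibrillar collagen organization in the tumor stroma carries prognostic
information, but the reference modality for imaging it — second
harmonic generation (SHG) microscopy — is slow and unavailable in
routine histopathology labs. Polychromatic polarization microscopy
(PPM) exploits collagen's intrinsic birefringence to make fibers
visible in ordinary stained sections: the fiber's retardance perturbs
a carefully prepared polarized illumination, and the perturbation is
read out as color.

`ppmfiber` implements the full desk-scale chain: the polarization
optics forward model, a seeded synthetic-tissue phantom, the
differential image-processing workflow, block-based orientation and
alignment metrics, and Bland–Altman agreement analysis, all driven by
a reproducible command-line interface.

# The optical model

## States and the Poincaré sphere

A fully polarized state is described by its azimuth $\theta$ (major
ellipse axis, degrees from horizontal, mod 180) and ellipticity angle
$\chi$ (signed by handedness; $\pm 45^\circ$ is circular). Its
normalized Stokes vector is

$$ (S_1, S_2, S_3) = (\cos 2\chi \cos 2\theta,\;
   \cos 2\chi \sin 2\theta,\; \sin 2\chi). $$

A linear retarder with retardance $\delta$ and fast axis $\alpha$ acts
as a rotation of this vector by $\delta$ about the equatorial axis
$(\cos 2\alpha, \sin 2\alpha, 0)$. The sign convention is fixed by a
physical anchor: a $10^\circ$ retarder at $45^\circ$ drives a
$+40^\circ$-elliptical state with azimuth $0$ to right-circular
($\chi = 45^\circ$):

```{r}
ellipticity(applyRetarder(PolarizationState(azimuth = 0, ellipticity = 40),
                          Retarder(10, 45)))
```

The orthogonal component (azimuth $90^\circ$) loses the same
$5^\circ$, and its transmission through the left-circular analyzer
$T_\mathrm{left} = (1 - \sin 2\chi)/2$ rises about four-fold relative
to the unperturbed state:

```{r}
down <- applyRetarder(PolarizationState(azimuth = 90, ellipticity = 40),
                      Retarder(10, 45))
analyzerTransmission(down, "left") /
  analyzerTransmission(PolarizationState(ellipticity = 40), "left")
```

The unit tests verify this rotation model against an independently
written Jones-matrix oracle over a thousand random states to $10^{-9}$.

## The spectral polarization fan and color formation

The illumination is a *spectral polarization fan*: all wavelengths
share ellipticity $40^\circ$, while the ellipse azimuth varies
linearly with wavelength, spanning $180^\circ$ over 400–700 nm. A
birefringent fiber therefore perturbs different wavelengths
differently, and after the circular analyzer the perturbation becomes
a wavelength-dependent (i.e. colored) intensity change. For a single
pixel with retardance $\delta$ and fast axis $\alpha$ the analyzer
transmission at fan azimuth $\theta_\lambda$ is

$$ T(\lambda) = \tfrac12\left[1 - \cos\delta \sin 2\chi
   + \sin\delta \cos 2\chi \sin(2\theta_\lambda - 2\alpha)\right], $$

which the renderer integrates against Gaussian camera sensitivity
bands. Two exact consequences drive the workflow and are tested as
identities:

* **Complementarity.** Shifting the fan's azimuth offset by
  $90^\circ$ is equivalent to rotating the sample by $90^\circ$, so
  the two acquisitions of a PPM pair carry opposite-signed fiber
  modulation on top of identical stain absorption.
* **Hue–retardance separation.** The differential signal is
  proportional to $\sin\delta$, a wavelength-independent factor, so
  the *hue* of the differential color encodes only the fiber axis
  $\alpha$ while its *brightness* encodes the retardance.

## Camera band placement

The default camera centers are 650, 550 and 450 nm with 30 nm sigma.
Because the fan maps wavelength linearly to azimuth, these evenly
spaced centers place the three channels' modulation phases $120^\circ$
apart in doubled-angle space, which makes the axis-to-hue map
injective over the full $[0, 180)$ range. Unevenly spaced centers
leave a dead arc in which two different fiber axes rectify to the same
hue, so even spacing is a correctness requirement here, not a styling
choice.

# The differential workflow

The pipeline mirrors the acquisition protocol in five steps:

1. acquire the complementary pair $I_0$, $I_{90}$ (here: rendered from
   the phantom),
2. white-balance each against its bright background (channel means
   over a default 99th-percentile luminance mask; luminance-preserving
   and idempotent),
3. subtract, $D = I_0 - I_{90}$: stain absorption, camera tint and any
   axis-independent attenuation are identical in both images and
   cancel exactly, while birefringent fibers survive as signed color,
4. collapse to a monochrome fiber-signal map (Rec. 709 luminance of
   $|D|$),
5. overlay that map as a single boosted channel on the grayscale
   brightfield for visual review.

The null test is central: a phantom with stain, tint and geometry but
zero retardance must produce an identically zero monochrome view, and
does.

# The phantom

`PhantomSpec` describes a synthetic stromal field: finite fiber
segments with von Mises-distributed orientations (axial, i.e. on
doubled angles), random thickness and length, optional sinusoidal
waviness, anti-aliased rasterization, additive retardance on overlap
with winner-take-all axis assignment, a smooth eosin-like stain field
applied through Beer–Lambert absorption, camera tint, and Gaussian
sensor noise added last. The SHG-like reference channel is the fiber
density map itself, which makes ground truth exact by construction.

`fiberStudySpec()` freezes the canonical parameter-recovery
conditions: a 512-pixel field with 600 fibers of thickness 1–1.8 px
and length 60–120 px. These values were chosen *a priori* from the
estimator's requirements — enough independent fibers per 256-px block
(> 100) that an isotropic field's true block alignment is small, and
fibers thin enough that the structure tensor sees single-fiber edges —
and then held fixed; they are study conditions, not tuning knobs.

# Orientation and alignment estimation

Per-pixel orientation comes from the structure tensor: gradients of
the Gaussian-smoothed image (sigma 2 px) are accumulated into the
tensor, the tensor is smoothed (sigma 3 px), and the fiber orientation
is the gradient-normal eigendirection. Each pixel is weighted by
coherence (eigenvalue anisotropy) times signal, pixels below 5% of the
block's maximum weight are dropped, and the block orientation is the
weighted circular mean on doubled angles. The block *alignment
coefficient* is the weighted mean resultant length

$$ R = \frac{\lvert \sum_k w_k e^{i 2\theta_k} \rvert}{\sum_k w_k}, $$

1 for parallel fibers and near 0 for an isotropic field. Orientations
are finally reported through the sinusoid map
$\sin(\theta)$, which removes the $0/180^\circ$ wrap-around ambiguity.

The tensor-smoothing sigma deserves a note: wide tensor smoothing
performs a local majority vote among crossing fibers, which *inflates*
the apparent alignment of isotropic fields (measured inflation: block
R up to 0.4–0.6 at $\kappa = 0$ with sigma 6). Keeping the smoothing
close to the fiber radius (sigma 3) restores the correct isotropic
limit (R ≈ 0.09–0.14) while leaving aligned-field recovery intact
(median orientation error about 1 degree). This is why the default is
3 rather than a more typical 4–6.

Blocks are 256 px squares; blocks whose reference (SHG) coverage is
below 10% are excluded from analysis, matching the ROI rule used for
real tissue.

# Agreement analysis

PPM-derived and SHG-derived block metrics are compared with
Bland–Altman statistics: the bias (mean difference), the sample SD of
differences, the limits of agreement bias ± 1.96 SD, and the fraction
of differences within those limits. For Gaussian differences the
expected within-limits fraction is about 95%; the acceptance suite
verifies this at the study's block count (159) over 200 seeded
replicates.

The published clinical result (159 kept blocks across two tissue
microarrays) is **not** reproducible here — the slides are not
deposited — so the acceptance suite substitutes the ROI-rule tests and
the phantom-based parameter-recovery study above. This is a stated
limitation, not an omission.

# Reproducibility engineering

* Every stochastic step is seeded; stage seeds are derived
  deterministically from one global seed and the stage name, so a
  single `--seed` reproduces an entire CLI run byte-for-byte.
* Rasters are written as 16-bit TIFF. Signed differentials need
  negative values, which the TIFF writer available here clamps to
  [0, 1]; they are therefore stored through an affine transform with a
  JSON sidecar recording offset and scale, and reconstructed exactly
  (to 32-bit float precision) on read.
* Every CLI stage writes a manifest (package version, seed, config
  echo, input checksums) sufficient to re-run it.

# Limitations

The phantom is a thin-section, single-scattering caricature: no
depolarization, no diattenuation, no out-of-plane fiber tilt, additive
retardance on overlap, and an SHG channel that is by construction
perfectly co-registered with the ground truth. It is designed to make
estimator errors visible against exact ground truth, not to imitate
tissue realism.
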