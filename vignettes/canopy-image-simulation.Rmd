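---
title: "Radiative-transfer simulation of annotated plant canopy images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiative-transfer simulation of annotated plant canopy images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyrt)
```

## The problem

Supervised models for plant phenotyping need annotated imagery, and
annotation is the expensive part: per-pixel labels for leaf identity,
chemistry or temperature are laborious or outright impossible to collect at
scale. A physically based renderer sidesteps this: if the scene, its optical
properties and the camera are all simulated, every pixel's ground truth is
known exactly. Unlike conventional computer-graphics rendering, a
radiative-transfer formulation keeps the pixel values physically meaningful
(fluxes in W m^-2 per waveband), which is what links images to leaf
biochemistry and energy balance.

`canopyrt` implements this pipeline at desk scale, on one CPU: scene
construction (procedural plants, textured ground, mesh import), reverse
Monte Carlo ray-tracing radiation transport over arbitrary wavebands, a
thin-lens camera with per-band spectral response, leaf optics from
biochemistry, per-pixel annotation, lens distortion, and spectral-response
calibration.

## Radiation transport

### Reverse ray tracing

Rays are launched *from* primitive surfaces toward sources, not from the
sources: every element is sampled regardless of how small or skewed it is.
Per primitive, band and side the model tracks incident and absorbed flux
and two families of "to-be-scattered" buffers:

* `tbs`, weighted by the band reflectivity/transmissivity $(\rho, \tau)$,
  drives the transport iteration;
* `tbs_cam`, weighted by the camera properties $(\rho_o, \tau_o)$, is what
  the camera pass queries.

A transport run executes three initial passes — direct (external sources,
with occlusion tested per sampled surface point), diffuse sky
(cosine-weighted hemispherical sampling; rays that escape collect the sky
flux), and longwave emission ($\epsilon \sigma T^4$ per side into longwave
bands) — and then iterates scattering: every side holding buffered energy
re-emits it through cosine-weighted (Lambertian) rays, receivers absorb
$(1-\rho-\tau)$ of what arrives and refill fresh buffers, old buffers are
zeroed, and rays that miss the scene escape. All bands are processed in one
sweep per iteration. Scattering and transmission are Lambertian; specular
reflection is not modelled, and scattered radiation keeps the source's
spectral distribution (an approximation that trades accuracy of multiply
scattered light for the efficiency of precomputed band properties).

The iteration stops when the residual buffered energy drops below
`residual_fraction_tol` (default 0.005) of the injected energy, or after
`max_scattering_iterations` (default 20, the regime where scene reflectance
factors are observed to converge even in high-reflectivity scenes). By
construction the ledger `injected = absorbed + escaped + residual` closes
to machine precision at every iteration; Monte Carlo noise affects the
*spatial distribution* of energy, never its total.

### Source conventions

Collimated and sun-disk sources are specified by perpendicular flux
(W m^-2); the sun disk has angular radius 0.266 degrees and the collimated
source is its zero-width limit. Finite terrestrial sources (sphere, disk,
rectangle) are specified by radiant power per band (W) and sampled by
surface area with standard form-factor weights: Lambertian-sphere emission
for bulbs, one-sided cosine emission for planar panels. The diffuse sky is
an isotropic radiance supplying its nominal flux on an unobstructed
horizontal plane; the longwave sky supplies $\sigma T_{sky}^4$.

### Random streams

Every (primitive, pass, iteration) combination derives its own RNG stream
from the base seed, so transport results are bitwise reproducible and
invariant to primitive ordering and to how a batch is scheduled across
processes.

## Spectra and band integration

All tabulated functions of wavelength share one representation: a strictly
increasing grid (nm) with linear interpolation and zero outside the
support. The internal reference grid is 400–2500 nm at 1 nm. Band
properties are source-weighted means,

$$\rho_o = \frac{\int_{\lambda_{min}}^{\lambda_{max}} \rho_\lambda C_\lambda S_\lambda\, d\lambda}{\int_{\lambda_{min}}^{\lambda_{max}} S_\lambda\, d\lambda},$$

with the camera response $C_\lambda$ in the numerator only, and
$C_\lambda \equiv 1$ giving the plain band properties used for
object-to-object scattering.

Quadrature is composite Simpson per interval of the union knot grid of all
participating spectra. Between adjacent knots every factor is linear, so
the product $\rho_\lambda C_\lambda S_\lambda$ is a cubic and Simpson
integrates it *exactly*: the $C \equiv 1$ reduction holds to machine
precision and the integrals agree with a 0.01-nm Riemann oracle to well
below 1e-6 relative. (Plain trapezoids on the knot grid leave an
$O(h^2)$ product-curvature error of order 1e-4 on smooth spectra, which is
why Simpson was chosen.)

## Leaf optics

Leaf reflectance/transmittance spectra come from a generalized plate
model: the leaf is a pile of $N$ identical absorbing plates separated by
$N-1$ air gaps. Per wavelength the per-layer absorption is
$k = \sum_i C_i K_i(\lambda) / N$; the isotropic-beam transmission factor
through a plate is $(1-k)e^{-k} + k^2 E_1(k)$; interface reflectivities are
unpolarized Fresnel coefficients averaged over an incidence cone (40
degrees for the upper leaf surface — exposed as `alpha_deg` — and 90
degrees for diffuse internal incidence, via 64-point Gauss–Legendre
quadrature); and the $N$-plate system is solved with the Stokes closed
form, with fractional $N$ through fractional exponents. Degenerate
branches (non-reflecting, opaque, and energy-conserving layers) use their
analytic limits. Both leaf sides receive the same spectra (the model is
side-symmetric); per-side overrides are possible in the scene layer.

The refractive-index and specific-absorption tables shipped by
`synthetic_prospect_coefficients()` are **synthetic**: generated
programmatically with the qualitative structure of published leaf-optics
calibrations (chlorophyll absorption peaks near 430/680 nm, carotenoids
near 450–480 nm, anthocyanins near 545 nm, water bands at 1450/1940 nm,
dry-matter/protein/carbon-based-constituent features in the SWIR, $n$
falling from about 1.52 to 1.40). They are not a published calibration and
absolute spectra will differ from measured leaves; every structural
guarantee (conservation, monotonicity in pigments, continuity, limits)
holds for any physically plausible table, and measured tables can be
swapped in as delimited text with the same columns. The test suite checks
the implementation against an independently written reference
implementation of the same plate model (adaptive quadrature for the
interface averages, adding/doubling and eigendecomposition matrix powers
for the stack) to 1e-4 absolute.

## Camera model

The thin-lens camera is defined by HFOV, resolution, lens diameter, focal
distance, sensor size and pose. The image plane sits behind the lens at
$d = (w_{sensor}/2)/\tan(\mathrm{HFOV}/2)$; a pixel ray starts at a
jitter-sampled point of the lens disk and passes through the focal-plane
point conjugate to a jitter-sampled point of the pixel (the line through
the pixel point and the lens center). Zero lens diameter degenerates to a
pinhole and everything is in focus; larger lenses blur off-focal-plane
objects with a monotonically growing point spread.

**Radiometric contract.** A pixel records the sample-averaged
camera-weighted scattered exitance (W m^-2) of the surface side it sees,
accumulated over all scattering iterations (the camera pass reads the
per-iteration `tbs_cam` snapshots; hits are traced once and reused). A
uniform Lambertian plate under a collimated source $S$ at incidence
$\theta$ images to exactly $\rho_o S \cos\theta$, and the reflectance
factor of a uniform Lambertian ground is its $\rho$ at every view angle.
Longwave emission reaches the camera through the same buffers, so thermal
bands show emitted plus scattered longwave radiation; shortwave bands do
not include emission.

**Annotation.** Label, depth and thermal maps use one deterministic ray
per pixel from the lens center through the pixel center; the nearest
primitive's datum is returned without blending (a mixed pixel carries
exactly one label). Depth is the lens-to-hit distance; sky pixels carry a
background sentinel.

**Distortion.** Radial and tangential distortion is applied as a forward
remap of pixel positions relative to the image center,
$\delta u = u(p_1 r^2 + p_2 r^4) + 2 p_3 u v + p_4 (r^2 + 2u^2)$ (and
symmetrically for $v$), destination rounded to the nearest pixel,
collisions resolved last-write in row-major order, and unfilled
destinations left at the background value — reproducing the characteristic
dark border gaps of barrel parameters. Zero coefficients are a bitwise
no-op.

## Camera spectral response calibration

Imaging a reference color board under a known illuminant in open
surroundings makes each patch's normalized image value equal its
$\rho_o$. The effective per-channel response is recovered by
box-constrained least squares over a basis of Gaussian bumps normalized to
a partition of unity (12 per channel by default), so coefficients in
$[0,1]$ guarantee $C_\lambda \in [0,1]$ by construction. A squared
second-difference penalty on the coefficients (weight 1e-3) encourages
smooth responses; the patch predictions are linear in the coefficients, so
the quadratic objective is solved with L-BFGS-B and analytic gradients.
With 18 spectrally diverse patches the fit recovers in-span responses to
patch-value $R^2 \ge 0.999$ noise-free and $\ge 0.99$ under 1%
multiplicative noise. Supplying chosen patch values instead of measured
ones designs a new simulated response with no physical camera ("no-target"
mode).

## Scene construction and the synthetic generator

Scenes are collections of planar primitives — triangles and rectangular
patches, the latter optionally cut out by a binary PNG alpha mask
(alpha > 0.5 is opaque; masked-out texels are transparent to rays and do
not count toward area). Meshes import from ASCII OBJ/PLY with fan
triangulation. The world frame is right-handed, z up, meters.

The procedural plants are deliberately simplified parametric models
(stem/petiole/leaf/fruit placement with seeded jitter inside configured
ranges); their contract is statistical — counts, size ranges, identifiers,
bit-reproducibility under a fixed seed — not geometric fidelity to any
crop architecture model. The fixture generator supplies canonical scenes
with closed-form expectations (`single_plate`, `occlusion_pair`,
`mini_canopy`, `color_board`), which is what makes the package fully
testable without downloads. What the generator does *not* emulate — real
leaf angle distributions, soil BRDF, specular glint, sensor noise — bounds
what passing tests say about real imagery: they validate the transport,
camera and annotation machinery, not agronomic realism of any particular
scene.

## Numerical choices

* Intersection epsilon 1e-6 m guards against self-intersection after
  scattering.
* Ray–scene intersection is a vectorized exhaustive sweep over primitives;
  at the package's design scale (hundreds of primitives) this outruns a
  bounding-volume hierarchy in R, and its semantics are pinned to a scalar
  brute-force oracle in the tests. A hierarchy would be an optimization,
  never a semantics change.
* Transport defaults: 100 direct rays per primitive per source, 50 diffuse
  rays per primitive side, residual tolerance 0.005, at most 20
  iterations.
* Test and acceptance problem sizes: the canopy fixture uses 124
  primitives and two bands; images are 16–96 px across with 2–48 samples
  per pixel. These sizes make every closed-form comparison
  statistically meaningful while keeping a full run in seconds.
* Degenerate inputs error early: empty scenes, duplicate uids, zero-energy
  band weighting, non-physical plate inputs, missing temperatures.

## Limitations

Lambertian surfaces only (no specular or anisotropic scattering); no
within-leaf lateral transport; no atmosphere; scattered radiation retains
the source spectrum; non-leaf optical properties are set empirically; the
leaf-optics coefficient tables are synthetic stand-ins. These mirror the
stated scope of the modelling approach the package implements, and each is
a documented extension point rather than a hidden assumption.
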