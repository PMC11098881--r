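---
title: "Ray-traced ultrasound intermediate representations from tissue labelmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ray-traced ultrasound intermediate representations from tissue labelmaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 5)
library(ultrasim)
```

## The problem

Abdominal aortic aneurysm (AAA) screening measures the anterior-posterior
(AP) diameter of the abdominal aorta in ultrasound; a measurement error
below 8 mm is considered clinically acceptable for diagnosis. Training
segmentation networks for this task is hampered by the scarcity of
annotated B-mode images, while labelled CT volumes are abundant. One way
around the annotation bottleneck is to render labelled anatomy into a
*simulated* ultrasound-like modality and train the segmenter on those
synthetic images, for which ground-truth masks come free.

`ultrasim` implements this pipeline end to end:

1. a **physics-based ray-traced simulator** over integer tissue labelmaps,
   with a boundary-only *intermediate representation* (IR) preset that
   suppresses speckle so that only tissue interfaces echo;
2. a **synthetic abdominal phantom generator** with controllable aorta
   diameter, plus **AAA synthesis** by dilation and thin-plate-spline
   deformation under a rigid spine constraint;
3. **alternative representations** (edge maps, speckled simulation) used
   as comparison baselines;
4. a compact **U-Net segmenter** trained purely on simulated IRs, and
   evaluation by Dice overlap and AP-diameter error against the 8 mm
   clinical bound.

## The acoustic model

Each tissue label carries six acoustic parameters: speed of sound $c$
(m/s), acoustic impedance $Z$ (g cm$^{-2}$ s$^{-1}$), attenuation
coefficient $\alpha$ (dB cm$^{-1}$ MHz$^{-1}$), and speckle parameters
$(\mu_0, \mu_1, \sigma_0)$ — scatterer density, amplitude mean and
amplitude spread. The defaults (`tissue_table()`) cover nine abdominal
tissues: fat, muscle, liver, kidney, blood, background, generic soft
tissue, bone and air.

A scan line is marched with step $\Delta = \text{image depth}/
\text{axial samples}$. Along the path the one-way amplitude transmission
is accumulated as

$$T(k) \;=\; \prod_{\text{steps}} 10^{-\alpha f \Delta / 20}
       \;\prod_{\text{passed interfaces}} (1 - R_i),$$

and at each label change $a \to b$ an echo

$$e(k) \;=\; T(k)^2 \, R(Z_a, Z_b)\, |\cos\theta_k|^{p}, \qquad
R(Z_a,Z_b) = \left(\frac{Z_b - Z_a}{Z_b + Z_a}\right)^{2}$$

is recorded, where $\theta_k$ is the angle between the ray and the local
boundary normal (the gradient of a $\sigma = 1$ px Gaussian-smoothed
impedance map) and $p$ is the specular exponent (default 1). The squared
transmission encodes the two-way path; interface losses $(1-R)$ are
applied on the outbound pass only — a deliberate simplification of a full
two-way ray model. Refraction is not modelled (straight rays).

This model reproduces, by construction, the qualitative signatures that
distinguish ultrasound from plain edge maps: echoes weaken with interface
obliquity (anisotropy), and strongly reflective or attenuating structures
(bone, air) shadow everything beneath them.

Speckle is an optional additive term: per axial sample a scatterer fires
with probability $\mu_0$ and amplitude $\max(0, N(\mu_1, \sigma_0^2))$,
weighted by $T(k)^2$ and blurred axially by a Gaussian point-spread
function whose width is minimal at the focus depth and grows linearly
away from it (an idealization; lateral blur is not modelled). The IR
preset sets $\mu_0 = \mu_1 = \sigma_0 = 0$ for every tissue, rendering
tissue interiors black — with the default `rf_noise = 0` the IR image is
bit-reproducible.

The envelope combines both terms with time-gain compensation
$g(d) = 1 + s\,(e^{a d} - 1)$ (defaults $a = 0.65$, $s = 0.2$; the
functional form — a saturating exponential with $g(0)=1$ — is this
package's choice, as is assigning scale exponent 1 to the reflection term
and exponent 2 to the scatter term):

$$\text{env} = (\text{refl}\cdot g)^{e_1} + (\text{scat}\cdot g)^{e_2},$$

normalized so that the 0.9 quantile of the *nonzero* (echo) samples maps
to 1, clipped to $[0,1]$, and passed through a display reject that zeroes
values below 0.03 (about $-30$ dB). Referencing the echo population
rather than the whole frame matters: a handful of shallow air or bone
flashes would otherwise set the scale and push deep vessel boundaries to
$\sim 10^{-3}$ intensity — invisible, which defeats the purpose of a
boundary-highlighting representation. The reject keeps the IR sparse
(typically under 10% of fan pixels) despite the finite pulse width.
Realistic mode additionally applies 60 dB log compression (configurable,
and disabled when `log_compression_db = 0`).

The axial point-spread function applies to specular echoes as well as to
speckle: each boundary return is spread by a Gaussian pulse envelope
whose width (`psf_axial_mm`, 0.5 mm at the focus) is minimal at the focus
depth and grows linearly away from it. Without it an echo is a single
0.1 mm axial sample, and resampling to 0.5–1 mm display pixels would
dilute its amplitude by an arbitrary geometry-dependent factor.

## Fan geometry and scan conversion

The convex probe (59 mm footprint, 40° opening) is modelled as an arc of
radius $r_0 = w/(2\sin(\phi/2)) \approx 86.3$ mm about a virtual apex;
scan lines leave the arc radially at uniform angles. Beam space (line
angle × radius) is resampled to a Cartesian image by per-pixel inverse
mapping with bilinear interpolation; pixels without a valid pre-image
form the complement of the fan mask and are exactly zero.

With these machine defaults the full fan is 127.4 mm wide and 105.2 mm
tall, so the output window is the square bounding the fan
(side $S = 2(r_0 + d)\sin(\phi/2)$) and the pixel spacing is $S/\text{out
size}$ — at 256 px about 0.50 mm, at 128 px about 1.0 mm. Defining the
window from the image depth alone would crop the fan laterally; deriving
it from the fan extent keeps the analytic annular-sector area usable as a
geometry self-check (the rasterized fan fraction matches
$\tfrac{\phi}{2}\big((r_0+d)^2 - r_0^2\big)/S^2$ to better than 2%).

Ground-truth masks are exported through the *identical* geometry
(`simulate_mask()`): the slice-space mask is sampled along every ray and
scan-converted with the same mapping, so mask and image are aligned by
construction.

## The synthetic phantom

`generate_phantom()` rasterizes a 130 × 130 mm axial abdominal
cross-section at 0.5 mm: a thin gel stand-off, skin/fat and muscle bands
(thicknesses drawn from 8–15 mm and 8–16 mm), a soft-tissue cavity with a
liver region and two kidneys, optional bowel-gas pockets, a circular
vertebral body (bone, radius 11 mm, posterior-central) and the aorta — a
blood disc anterior-left of the spine with diameter drawn from 15–25 mm
(the healthy range). All placements are jittered ±4 mm, deterministically
from the seed. The aorta–spine layout leaves enough clearance that
aneurysms up to the 70 mm cap can be synthesized without touching bone.

What the phantom does *not* emulate: true CT anatomy (organ shapes are
ellipses), out-of-plane structure, vessel wall thickness, pulsatility, or
patient-specific variation. Passing the end-to-end test therefore shows
that the pipeline is self-consistent — simulate, train, segment, measure
— not that a network trained on these phantoms transfers to clinical
B-modes; bridging simulated and in-vivo appearance additionally requires
an image-to-image translation step, which is out of scope here (the
dataset export exists precisely as the hand-off interface for it).

## AAA synthesis

Aneurysms are synthesized in three steps (`synthesize_aaa()`):

1. **Dilation**: the aorta cross-section is scaled about its centroid
   until its AP diameter matches a target drawn from the requested class
   (small 30–45 mm, medium 45–55 mm, large 55–70 mm; the 70 mm cap is
   this package's choice for an open-ended class).
2. **Deformation estimate**: boundary points of the healthy and dilated
   aorta are paired by radial correspondence about the centroid (adequate
   for near-circular cross-sections; a general mesh registration is not
   attempted). Every 4th source-boundary pixel becomes a control point;
   zero-displacement constraints are added on every 8th spine-surface
   pixel and 16 border points. An interpolating thin-plate spline
   ($U(r) = r^2 \log r$ with affine part, ridge $10^{-9}$ for numerical
   safety) extrapolates the displacement across the slice, reproducing
   every control displacement to well below 1e-6 mm.
3. **Warping**: backward nearest-neighbour warping (no labels invented),
   after which the dilated aorta is re-stamped as blood. The field is
   zeroed exactly on every bone voxel, and any stray pixel that a
   neighbouring lookup pulled out of the spine is restored — spine
   rigidity holds exactly (bone Dice 1.0), not just at the sampled
   constraints.

## Segmentation at desk scale

The segmenter is a standard U-Net (two 3×3 conv + ReLU per level, 2×2
max-pooling, nearest-neighbour upsampling with skip concatenation, 1×1
output head) implemented in single-precision RcppArmadillo with
hand-derived backpropagation, verified against finite differences.
Each level is two (convolution → instance normalization → leaky ReLU)
pairs; plain ReLU blocks can die permanently on such sparse inputs, and
normalization keeps the short training runs stable. Training uses a
squared-denominator soft Dice loss with auxiliary (deeply supervised)
Dice terms at the coarser decoder scales, Adam (lr $10^{-3}$, stepped
down twice late in the run under the desk preset), a seeded random 80–20
train/validation split, on-the-fly augmentation (rotation ±15°,
translation ±10%, scale 0.9–1.1 firing with probability 0.5, Gaussian
noise $\sigma = 0.02$ always on — ranges are this package's defaults),
and keeps the best-validation-Dice epoch. Predicted masks keep the
largest connected component with holes filled, since a single structure
is sought.

The *reference* recipe (50 epochs, batch 64, 256 px) is the default
configuration; the **desk preset** used by the tests and the acceptance
script scales the experiment to a single CPU: 4 levels × 16 base
channels, 128 × 128 inputs, single-image batches, 8 epochs, 200 training + 40 held-out
phantoms. These problem sizes are the package's chosen benchmark
conditions; the pipeline accepts the full-scale settings unchanged.

The AP diameter of a mask is the maximum contiguous vertical run over the
columns of its largest connected component, times the pixel spacing (a
caliper-style extent on the depth axis; the depth axis is the AP axis in
anterior abdominal screening). Empty predictions raise an explicit
failure, are excluded from the MAE and reported as a failure fraction.
Dice of two empty masks is defined as 1, empty versus non-empty as 0.

## Numerical choices and degenerate inputs

* Labelmaps are resampled by nearest neighbour everywhere (slicing,
  warping, dilation) so no interpolated pseudo-labels can appear.
* Samples outside the slice contribute neither echoes nor attenuation;
  a homogeneous slice is exactly anechoic.
* Boundary normals with zero gradient (flat regions) default to
  $\cos\theta = 1$; the cosine is taken in absolute value.
* The two-layer closed form $T^2 R$ is reproduced to relative error
  below $10^{-6}$ when the interface is aligned with the marching grid;
  off-grid interfaces are quantized to the nearest sample (half a step,
  ≈ 0.05 mm, at the defaults).
* The attenuation table is read as dB cm$^{-1}$ MHz$^{-1}$ and the
  center frequency (2.5 MHz, a typical convex abdominal transducer) is a
  configurable machine parameter — attenuation must scale with both path
  length and frequency to be physical.
* Thin-plate-spline systems are solved densely; duplicate control points
  are removed first. `estimate_deformation()` refuses inconsistent
  constraints (rigid mask intersecting the dilated aorta).
* Single-precision training limits finite-difference gradient agreement
  to ~1e-2 relative on small entries; the gradient test accounts for it.

## Known limitations

Straight-ray propagation (no refraction), no lateral point-spread blur,
no RF-domain realism, elevational averaging degenerates to a no-op on 2D
slices, and the edge/realistic baselines use fixed default parameters for
the bilateral filter and Canny thresholds (the median rule). The
reference recipe's full-scale training on real scanner data — and any
claim about in-vivo performance — is outside what this package can or
does test.

## A short tour

```{r tour, eval = FALSE}
ph <- generate_phantom(phantom_config(seed = 7))
img <- simulate_us(ph$labelmap, out_size = 256)   # boundary-only IR
plot(img)

aaa <- synthesize_aaa(ph$labelmap, "medium", seed = 3)
aaa$diameter_mm

rec <- recovery_experiment(n_train = 200, n_test = 40,
                           phantom_seeds = 0:239, seed = 1)
rec$report
```
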