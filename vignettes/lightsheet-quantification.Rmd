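---
title: "Quantifying light-sheet stacks of organoids: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying light-sheet stacks of organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsquant)
```

# What this package computes

Light-sheet fluorescence microscopy (LSFM) delivers 3D stacks of organoids —
multicellular cultures in which a cell monolayer encloses a hollow lumen —
with strongly anisotropic voxels: the axial (z) step is typically four times
the lateral pixel pitch. `lsquant` implements the quantitative chain that
turns such stacks, and calibration stacks of sub-resolution fluorescent
beads, into numbers:

1. **Pre-processing** — cropping, rolling-ball background subtraction,
   linear rescaling along z to isotropic voxels, and rotational
   maximum-intensity ("brightest point") projections.
2. **3D nuclei segmentation** — median filtering, local-mean thresholding,
   multiscale Laplacian-of-Gaussian (LoG) seed detection, marker dilation,
   and a marker-controlled immersion watershed, followed by a strict volume
   gate.
3. **Morphometry** — an alpha shape over the nucleus centroids (organoid
   volume and surface), a cell graph (local cell density), and nucleus
   volume distributions.
4. **Resolution assay** — line profiles through bead images, Gaussian fits,
   and FWHM statistics compared between imaging media.
5. **Optics** — a planar-slab refraction model quantifying how a thin
   container wall shifts the focus and introduces spherical aberration.
6. **Phantoms** — synthetic bead and organoid stacks with ground truth, so
   that every stage above is testable without microscope data.

Throughout the package a stack is an `image_stack`: an array ordered
`(z, y, x)` with z the optical axis, plus the lateral and axial pitch in
micrometres. Voxel coordinates are 1-based array indices (R's native
convention), and centroids are intensity-unweighted means of member voxel
indices.

# The segmentation model and its parameters

Segmentation operates on the isotropic grid produced by `rescale_z()`
(default pitch 0.654 µm). The default parameter set is, in voxels of that
grid:

| parameter | default | role |
|---|---|---|
| `ball_radius` | 60 | rolling-ball background radius |
| `z_rescale_factor` | 4 | axial rescale to isotropic voxels |
| `target_pitch` | 0.654 µm | isotropic voxel pitch |
| `median_range` | 3 | median window (3×3×3 cube) |
| `local_threshold_range` | 10 | local-mean window radius (21³ window) |
| `log_range_min`, `log_range_max` | 8, 12 | LoG blob-diameter range |
| `dilation_radius` | 3 | marker ball radius (123-voxel ball) |
| `volume_min`, `volume_max` | 500, 18000 | strict volume gate |
| `alpha` | 240 | alpha-shape circumradius threshold |
| `edge_threshold` | 60 | cell-graph edge length |
| `outlier_distance` | 55 | isolated-node outlier distance |

Two wording ambiguities had to be resolved. A filter "range" is read as the
full window width for the median (range 3 → 3×3×3 cube) and as the window
*radius* for the local threshold (range 10 → 21³ window); both readings are
common usage for the respective filter, and both are configurable. The
threshold rule is strict (`intensity > window mean`), so a constant stack
yields an all-background mask.

The LoG detector maps a "range" value to a blob diameter $D$ and evaluates
the scale-normalised response $\sigma^2 \nabla^2 (G_\sigma * I)$ at
$\sigma = D / (2\sqrt{3})$ — the scale at which the 3D response of a ball of
diameter $D$ peaks — at five evenly spaced diameters across
$[D_{\min}, D_{\max}]$. Five scales and the relative response threshold
(0.1 of the global maximum) are free choices exposed in the configuration;
some response threshold is required to suppress noise maxima. Seeds are
strict local maxima over the joint space–scale neighbourhood, which yields
at most one seed per distinct blob.

The watershed floods the *inverted* median-filtered intensity (the last
computed intensity volume) from the dilated seeds, restricted to the
threshold mask, with 26-connectivity. Determinism is guaranteed by an
explicit tie-break: equal-intensity voxels flood in FIFO order of queue
insertion, with markers enqueued in increasing linear-index order and
neighbours in a fixed `(dz, dy, dx)` order. This makes the result
bit-reproducible and allows an exact brute-force priority-flood oracle in
the test suite. Dilated markers that would overlap raise an error instead
of silently merging — an overlap means the seeding failed, and merging it
away would corrupt counts. In the composed pipeline, seeds outside the
foreground mask are dropped and marker balls are clipped to the mask, so
the watershed precondition holds by construction.

The volume gate keeps regions with `500 < volume < 18000` voxels, both
bounds strict: regions of exactly 500 or exactly 18000 voxels are rejected.

## Cell-graph rule

A node participates in an edge whenever two centroids lie within
`edge_threshold` (≤ 60 voxels, ties included). Outliers are nodes with *no*
edge whose nearest neighbour is farther than `outlier_distance`. Under the
default 60/55 thresholds this means two nuclei 59 voxels apart form an edge
and are kept, while two nuclei 61 voxels apart are both outliers. The
alternative rule "remove any node with nearest neighbour beyond 55 before
building edges" would contradict the first of these behaviours, which is
the intended one; outlier removal therefore never removes edges between
retained nodes.

## Alpha shape

The alpha shape is computed from a 3D Delaunay tetrahedralization
(incremental Bowyer–Watson insertion, implemented in the package) filtered
to tetrahedra whose circumsphere radius is strictly below `alpha`; volume
is the sum of kept tetrahedron volumes and surface area the sum of
boundary-face areas. Strict "<" makes the filtering deterministic under
ties. The volume is non-decreasing in `alpha` and saturates at the convex
hull once `alpha` exceeds the largest circumradius. Degenerate inputs
(fewer than 4 points, coplanar points) yield a zero-volume result with a
warning rather than an error. Numerically, insertion uses a deterministic
scrambled order and a relative tolerance of $10^{-12}$ on the insphere
test; near-cospherical point sets (e.g. centroids of a hollow monolayer)
are the hard case, and the test suite exercises exactly that geometry
(500 points rounded onto a digital sphere).

# What the phantoms emulate — and what they do not

`generate_bead_stack()` renders sub-resolution (0.5 µm) beads as point
sources convolved with a separable anisotropic Gaussian PSF (defaults:
lateral σ 0.6 µm, axial σ 1.8 µm — a detection lens of moderate NA with a
light-sheet axial profile), plus a constant background and additive
Gaussian noise. `generate_organoid_stack()` places axis-aligned ellipsoidal
nuclei (semi-axes 5.2 × 4.3 × 4.3 µm, about 1440 isotropic voxels — strictly
inside the volume gate, so recall is attributable to segmentation rather
than gating) on a spherical shell of radius 30 µm around an empty lumen,
using golden-angle spiral positions with seeded jitter and
rejection-sampled minimum spacing, rasterises them into a ground-truth
label map on the 4:1 anisotropic grid, blurs with the PSF and adds noise.
Default contrast is 120 intensity units over a background of 10 with noise
SD 6, i.e. nuclei exceed the lumen by 20 noise SDs.

The Gaussian PSF choice matches the package's own resolution metric (a
Gaussian-fit FWHM); the phantoms deliberately omit Airy rings, stripe
artefacts, depth-dependent attenuation and refraction-dependent blur (the
optics module treats refraction analytically instead). Noise is additive
Gaussian by default — a Poisson component is not simulated — so oracle
values stay exact. Passing tests on these phantoms therefore demonstrate
the *algorithmic* correctness and recovery behaviour of the chain, not its
performance on real tissue with scattering, stripes or clipped dynamic
range.

## A known, quantified limitation: volume inflation of blurred nuclei

On the default phantom the pipeline finds every nucleus (50/50 detected,
100% centroid recall at 3-voxel tolerance) but overestimates per-nucleus
volume by roughly +50%. The cause is structural, not a bug: the local
threshold compares each voxel to the mean over a 21³ window, which is much
larger than a ~1440-voxel nucleus. Near a nucleus the window mean is only
about `background + 0.1 × amplitude`, so the foreground mask reaches the
~1.3σ isosurface of the blurred edge rather than the half-maximum surface.
With an axial edge smeared by both the PSF and the ×4 linear z-rescaling
(an effective σ of ~2 isotropic voxels), the mask gains 1–4 voxels on every
face. The watershed basin equals the mask region, so segmented volumes
inherit the inflation. Measured on noise-free phantoms: +54% under default
rendering, +24% with a hypothetically blur-free phantom (the rescaling
smear alone), and −3.5% on a sharp-edged isotropic phantom — within the
boundary-voxel discretisation error, which shows the geometric pipeline
itself is accurate. A smaller threshold window (half-width 5) was measured
as well and still yields +24%, so the window convention is not the lever.
Relative volume comparisons (e.g. median nucleus volume between organoids)
remain meaningful because the inflation is systematic; absolute volumes
from this thresholding scheme should be treated with caution for objects
whose size is comparable to the blur.

# The resolution assay

`extract_profile()` samples the stack through a bead centre along the
lateral axis or the optical axis, with a physical abscissa (µm) and
max-normalised intensities; `fit_gaussian()` fits
$A\,e^{-(x-\mu)^2/(2\sigma^2)} + b$ by Levenberg–Marquardt and reports
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$. Fitting uses the raw LM driver
(`minpack.lm::nls.lm`) with two starting widths — the second moment of the
profile and its half-maximum width — keeping the converged fit with the
lower residual. The moment start alone is unreliable for profiles much
narrower than the sampling window (noisy baseline tails inflate it), and an
LM run from a bad start can collapse σ onto a single sample; such
degenerate fits (σ below 5% of the sample spacing) are rejected. The
`nls.lm` driver is used instead of `nlsLM` because the latter rebuilds a
`stats::nlsModel` whose numeric-derivative step scales with the parameter
magnitude and spuriously reports a singular gradient whenever the fitted
centre is ~0 — the normal case for centred profiles.

`summarize_fwhm()` reports per-condition means with sample standard
deviations (n−1) and the percent difference
$(\bar{F}_A - \bar{F}_B)/\bar{F}_A \times 100$ against a declared reference
condition A. Bead centres can be supplied manually (mirroring interactive
profile measurement) or taken from the phantom ground truth.

# The slab refraction model

A fluorophore at the inner surface of a container wall of thickness $d$ and
index $n_1$ emits into a bath of index $n_b$; the medium around the
specimen has index $n_2$. Applying Snell's law at both planar interfaces,
the ray leaving at angle $\alpha_1$ appears to originate at depth
$d \tan\alpha_w / \tan\alpha_b$ behind the outer surface. The paraxial
focal shift is $d\,(1 - n_b/n_1)$ — linear in the wall thickness — and the
longitudinal spherical aberration is reported as the magnitude of the
marginal-minus-paraxial intercept difference at the detection aperture's
marginal angle. Both vanish for $d = 0$ or matched indices and grow
linearly (hence monotonically) with $d$: a 12.4 µm foil wall produces a
~0.13 µm paraxial shift (FEP against water), while a 400 µm cylinder wall
produces ~4 µm. Placing the source at the inner wall isolates the wall's
own contribution; the depth-dependent aberration of the $n_2/n_b$ mismatch
itself is outside this model, as is the illumination path (a much smaller
contribution at low illumination NA) and any wave-optical treatment.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full chain on phantoms of
32×128×128 anisotropic voxels (128³ after rescaling, ~2 million voxels, 10
or 50 nuclei), 100-instance brute-force oracle comparisons on random stacks
of up to 10³ voxels, 500-point alpha shapes, and 10-bead-per-condition
resolution assays — sizes chosen so the whole suite completes in minutes on
one CPU while every code path (anisotropy, noise, crowding, near-degenerate
geometry) is exercised. Gaussian smoothing kernels are truncated at 4σ;
borders use symmetric reflection everywhere; the rescaling convention fixes
slice centres and replicates the last slice beyond the final sample;
rotational projections use nearest-neighbour forward mapping so that maxima
are true voxel values and frame 0 equals the axis-aligned projection
exactly.
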