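---
title: "Inferring the lethal electric-field threshold of irreversible electroporation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the lethal electric-field threshold of irreversible electroporation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irethreshold)
```

## The problem

Irreversible electroporation (IRE) ablates soft tissue non-thermally:
trains of ~70 microsecond pulses at kilovolt amplitudes are delivered
between pairs of needle electrodes, and cells die wherever the local
electric field exceeds a tissue-specific lethal threshold. Planning an IRE
treatment therefore hinges on knowing that threshold — yet for human tumor
tissue it cannot be measured directly. What *can* be observed per patient
is (i) the electrode geometry and applied voltages, (ii) the current the
generator delivered, and (iii) the ablation volume visible on follow-up
imaging. This package infers the lethal threshold from exactly those
observables.

The procedure has three stages, each exposed as ordinary R functions:

1. **Forward electrostatics.** For each electrode-pair activation, solve
   $\nabla \cdot \sigma \nabla \phi = 0$ on a voxelized cube with the
   applied potential on the energized needle, ground on the return needle,
   and an insulated outer boundary. The field magnitude is
   $|E| = |\nabla\phi|$, reported in V/cm.
2. **Conductivity calibration.** Electroporation opens membrane pores, so
   tissue conductivity rises with the local field. We model
   $\sigma(|E|)$ as a smoothed step from a baseline $\sigma_0$ to a
   ceiling $\sigma_{max}$, and calibrate $\sigma_{max}$ per patient so the
   simulated current of the first pair activation matches the measured
   current.
3. **Threshold extraction.** Per-pair fields are aggregated by voxelwise
   maximum; field iso-contours are scanned in 1 V/cm steps and the lethal
   threshold is the contour whose super-level-set volume is nearest the
   observed ablation volume.

A cohort statistics layer reproduces the published correlation analysis
(Pearson r, two-sided p, post-hoc power) between the inferred threshold
and pre-treatment PSA, and a synthetic-patient generator closes the loop:
it plants a known $\sigma_{max}$ and threshold, simulates the observables,
and lets the test-suite verify the inversion recovers them.

## The conductivity model

The dynamic law is

$$\sigma(|E|) = \sigma_0 + (\sigma_{max} - \sigma_0)\, s\!\left(\frac{|E| - (E_c - w/2)}{w}\right),$$

with transition center $E_c = 500$ V/cm and width $w = 800$ V/cm by
default, and $s$ a polynomial smoothstep. The transition is the range over
which progressively more of the cell population is permeabilized; below
$E_c - w/2 = 100$ V/cm the tissue keeps its baseline conductivity
$\sigma_0 = 0.284$ S/m (a low-voltage pre-pulse measurement in prostate —
the clinical generator cannot measure it per patient, so it is fixed), and
above $E_c + w/2 = 900$ V/cm the tissue is fully electroporated at
$\sigma_{max}$.

The smoothing family matters only through its smoothness class. We use the
quintic smoothstep $s(t) = 6t^5 - 15t^4 + 10t^3$, the minimal-order
polynomial whose first *and second* derivatives vanish at both edges; this
keeps $\sigma(|E|)$ twice continuously differentiable, which the Picard
iteration rewards with stable convergence. A cosine ($C^1$) family is
available (`tissue_model(smoothing = "cosine")`) for sensitivity checks.
At the center the law passes exactly through
$(\sigma_0 + \sigma_{max})/2$:

```{r}
m <- tissue_model(sigma_max = 0.72)
sigma_of_e(c(0, 100, 500, 900, 2000), m)
```

## Discretization and solver

Fields are solved on a cell-centered, isotropic voxel grid (default: a
7.5 cm cube at resolution 64, i.e. 0.117 cm voxels) with a 7-point
finite-volume stencil and harmonic-mean face conductivities. Finite
volumes conserve current discretely — the flux that leaves the source
needle equals the flux entering the return needle up to the linear-solver
tolerance — which is exactly the property the calibration stage leans on.

Choices a user may want to know about:

* **Electrodes.** Needles are stainless-steel cylinders
  ($2\times10^6$ S/m) spanning the exposure length (1.5 or 2.0 cm
  clinically); insulated shaft and trocar tip are omitted. Active
  electrodes enter as Dirichlet voxels (metal is equipotential to machine
  precision); the two inactive needles of each activation remain in the
  model as passive conductors. Their conductivity is capped at
  $10^4\sigma_0$: beyond a contrast of $\sim10^3$ the solution is
  insensitive (asserted by a test) while the conditioning of the linear
  system degrades.
* **Electrode radius** is not part of the treatment record; the default is
  0.05 cm (1 mm diameter needle). On grids coarser than the radius the
  rasterizer widens the needle to half a voxel so it always owns a voxel
  column. Delivered current depends logarithmically on the needle radius,
  so the *calibrated* $\sigma_{max}$ absorbs this grid-dependent effective
  radius and shifts by roughly 5-10% per resolution step when observables
  from one grid are inverted on another; the *threshold*, which the
  calibration step exists to serve, is robust — the cross-resolution test
  bounds its drift at 5% while same-grid recovery is accurate to a few
  V/cm. Comparing $\sigma_{max}$ values across resolutions (or with
  published values) therefore requires matching the needle rasterization,
  not just the physical radius.
* **Outer boundary** is electrically insulating (zero normal current), the
  conventional choice when the true far-field boundary is remote.
* **Linear solves** use Jacobi-preconditioned conjugate gradients
  (relative residual $10^{-7}$, warm-started across nonlinear iterations
  and calibration sweeps).
* **Nonlinearity.** Dynamic mode iterates
  $\sigma^{(k)} = \sigma(|E^{(k-1)}|)$ with under-relaxation 0.7, stopping
  when the source current changes by less than $10^{-3}$ relatively
  (typically 6-10 iterations). When $\sigma_{max} = \sigma_0$ the update
  is the identity and the solve reduces, bitwise, to the static one.
* **Field magnitudes** attached to solutions are flux-consistent: each
  component is the face flux divided by the voxel conductivity, which is
  exact next to electrode voxels where a plain central difference is
  biased 25% low. The standalone `field_magnitude()` is the plain central
  difference for use on arbitrary potential arrays.

The solver is validated against closed forms: a parallel-plate surrogate
(uniform field, exact to the 0.1% level at any resolution) and a
concentric-cylinder surrogate ($\phi(r) = V \ln(b/r)/\ln(b/a)$, current
$2\pi\sigma L V / \ln(b/a)$, within 2% at resolution 128).

## Treatment-protocol emulation

The clinical generator applies $\min(1500 \times d, 3000)$ volts to a pair
at spacing $d$ cm, fires all $\binom{n}{2}$ pairs (six for the four-needle
square), and orders activations from the highest voltage — equivalently
largest spacing — downward. Ties at the 3000 V cap are ordered by spacing
(diagonals before sides), then by electrode index; the first entry of the
ordered plan is the pair whose current is used for calibration. Pulse
metadata (90 pulses of 70 us per pair) is carried for reporting only: the
model is electrostatic, and pulse-train dynamics, inter-pulse memory and
Joule heating are out of scope.

## The two inversions

**Calibration.** Delivered current is monotone non-decreasing in
$\sigma_{max}$ (a property the test-suite asserts over a sweep), so
matching the measured current is a one-dimensional root-finding problem.
We use bisection on $[\sigma_0, 2.0]$ S/m, stopping at a relative current
mismatch of $10^{-3}$ or a bracket of $10^{-4}$ S/m; a parametric sweep
(step 0.01 S/m) is retained behind `method = "sweep"`. Currents outside
the achievable interval raise an error that names the interval rather
than silently clamping.

**Threshold matching.** `find_threshold()` scans integer contours
1, 2, ..., $\lceil\max|E|\rceil$ V/cm and returns the contour minimizing
the absolute volume mismatch. Exact equality is impossible on a voxel
grid; ties are broken toward the *lower* contour because it predicts the
larger kill zone — the conservative direction for treatment planning. The
volume integral runs over the whole tissue domain, not only the observed
ablation mask, since the matched contour is itself the model's estimate of
that region.

## The synthetic cohort

`generate_cohort()` draws, per patient: electrode spacing uniform on
1.4-2.2 cm and exposure from {1.5, 2.0} cm (the clinical ranges),
$\sigma_{max}$ uniform on 0.55-1.0 S/m and the planted threshold uniform
on 412-614 V/cm (the published per-patient ranges), and PSA on
3.8-10.03 ng/mL through a Gaussian copula with latent correlation -0.624
to the threshold — the generator *plants* the observed association rather
than modeling a mechanism, and the copula's $\rho$ is a free parameter.
The measured current is the forward dynamic first-pair current with
multiplicative Gaussian noise (1% relative by default), the ablation mask
is the super-level set of the forward aggregated field at the planted
threshold, and the change in current is defined as the first-pair dynamic
minus static current (the clinical definition of that column is not
recorded, so the generator fixes its own and documents it). Each patient
draws from a seeded substream, so cohorts are bit-reproducible and
extensible without reshuffling.

What the generator does *not* emulate: MRI appearance or segmentation
error on the ablation mask, lesion remodeling between treatment and
imaging, tissue heterogeneity (urethra, vessels, capsule), or any pulse-
number dependence of the threshold. Passing closed-loop tests therefore
demonstrate that the inversion is consistent with its own forward physics
at clinical geometry and noise levels — not that the clinical thresholds
themselves are recovered, which would require the original imaging data.

Problem sizes used by the validation suite: closed-loop recovery runs five
noise-free synthetic patients at resolution 64 (plus ten noisy patients
for the calibration-error bound), and the analytic solver oracles run at
resolution 128; both recover the planted parameters with margins reported
by the tests themselves.

## Cohort statistics

`cohort_correlations()` recomputes the published correlation table from the
shipped ten-patient record: Pearson r with the exact t-transform p-value,
and retrospective power. For power we evaluate the noncentral-t
distribution of the test statistic at noncentrality
$|r|\sqrt{(n-2)/(1-r^2)}$, which reproduces the published power column to
0.1 percentage points on every recoverable row; the Fisher-z approximation
(also available) deviates by up to ~5 points at $n = 10$ and is retained
only for comparison. The change-in-PSA row of the published table cannot
be recomputed because post-treatment PSA is not part of the record; the
function flags it rather than guessing.

```{r}
cohort_correlations()
```

## Known limitations

* The whole-domain conductivity assignment and the cubic outer boundary
  are idealizations; the clinical analysis confined the mesh to the
  reconstructed ablation geometry.
* $\sigma_0$ is fixed, not jointly inverted — single-current data cannot
  constrain both ends of the conductivity step.
* The per-patient thresholds of the published cohort depend on
  unreleased imaging reconstructions; the package reproduces the
  published *statistics* exactly and validates the *procedure* in closed
  loop, but cannot re-derive those ten thresholds.
* Volumes from the synthetic generator trend larger than the clinical
  ones at matched spacing (no anatomical confinement); their ranges
  overlap, which is what the cohort-realism test asserts.
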