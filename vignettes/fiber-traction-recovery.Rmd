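---
title: "Reference-free traction recovery on deformable fiber arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free traction recovery on deformable fiber arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibertfm)
```

`fibertfm` recovers 3D cell traction forces from the deflections of
suspended microfabricated fibers. This vignette is the package's account of
the underlying science: the mechanical model and its assumptions, the
inverse problem and its regularization, how deflections are measured from
image stacks, what the synthetic phantoms emulate, and the numerical and
design choices made where more than one defensible option existed.

## 1. Fiber mechanics

### Model and assumptions

Each fiber is treated as a straight, prismatic Euler–Bernoulli beam of
length $L$ (distance between the rigid scaffold walls), clamped at both
ends, carrying a constant axial tension $T \ge 0$ built in by shrinkage
during fabrication. The elliptical photopolymerized cross-section is
approximated by a rectangle of the measured axial width $w$ and average
height $h$, giving area $A = wh$ and the two second moments
$I_\mathrm{inplane} = h w^3/12$ (bending within the layer plane) and
$I_\mathrm{lateral} = w h^3/12$ (vertical bending). The transverse
equilibrium equation per bending plane is

$$EI\,w''''(x) - T\,w''(x) = q(x),$$

with clamped boundary conditions. Assumptions, all inherited from the
regime the platform operates in:

* **Linear kinematics.** Deflections (≈1–3 μm) are small against $L$
  (80–200 μm); geometric nonlinearity and tension changes due to stretching
  are neglected.
* **No axial or torsional degrees of freedom.** Cells certainly exert
  axial forces (the axial stiffness $k_\mathrm{axial} = AE/L$, about
  16–47 nN/μm for 80 μm fibers, is comparable to the lateral stiffness),
  but axial deformation is invisible to a reference-free centerline
  measurement. The package reports $k_\mathrm{axial}$ as a diagnostic and
  the *residual force* (vector sum of recovered transverse forces, which a
  self-equilibrated cell should keep near zero) as the tell-tale of
  unmodeled axial loading. Buckling is likewise out of scope.
* **Pure nodal forces.** Cells are assumed not to exert concentrated
  moments.

Two closed-form limits anchor the model. At $T = 0$ the midpoint stiffness
is $k_\mathrm{struct} = 192\,EI/L^3$; when tension dominates it is
$k_\mathrm{tension} = 4T/L$. For the soft fiber condition
(`preset_spec("600us")`: $w = 1.56$ μm, $h = 0.073$ μm, $E = 11.32$ MPa,
$L = 80$ μm) the structural part is below 3% of the measured apparent
stiffness, which is why tension is calibrated from AFM midpoint stiffness
by the direct inversion $T = kL/4$ (`calibrate_tension()`, mode
`"tension-only"`). A `"corrected"` mode solves the full finite-element
midpoint relation for $T$ by bracketed root finding (relative tolerance
$10^{-6}$); it is always at or below the tension-only value and matters
only when bending is non-negligible.

### Discretization: a nodally exact element

The fiber is divided into `n_elements` equal elements; interior nodes carry
two transverse deflections and two rotations, and the two bending planes
are assembled independently (they are uncoupled for a straight beam). The
element stiffness uses the exact homogeneous solutions of
$EI w'''' - Tw'' = 0$, $\{1, x, e^{-a x}, e^{a(x-h_e)}\}$ with
$a = \sqrt{T/EI}$, as shape functions. Because the problem is self-adjoint
and the shape functions solve the governing equation, the Galerkin
stiffness is *nodally exact*: nodal deflections under nodal point loads are
independent of the mesh. The energy integrals have stable closed forms (the
exponentials are normalized to at most one on the element, and the cross
term between the two boundary-layer functions cancels identically because
$T = EIa^2$). Below $a h_e = 10^{-2}$ the basis degenerates numerically and
the code switches to the standard cubic-Hermite bending matrix plus the
consistent geometric-stiffness matrix, whose error there is
$O((a h_e)^4)$ — in particular, at $T = 0$ the Hermite element is itself
nodally exact.

This element was chosen over the plain Hermite-plus-geometric combination
after observing that the study fibers are so tension-dominated that the
clamp boundary layer $\sqrt{EI/T} \approx 1.9$ μm spans barely more than
one element at the default mesh, leaving the Hermite element ≈0.2% from
convergence at 64 elements — outside the package's 0.1% mesh-convergence
contract. With the exact element the contract is met trivially, and the
closed-form limits above are reproduced to machine precision
(tension-dominated midpoint stiffness still sits ≈0.5% above $4T/L$ — that
is physics, the finite-$EI$ boundary-layer correction, not discretization
error).

`n_elements = 64` remains the default so that node spacing (1.25 μm on an
80 μm fiber) comfortably resolves measured deflection profiles and gives
the inverse problem a force grid finer than a cell protrusion. Positions
between nodes snap to the nearest node (ties toward the lower-index clamp).

## 2. The inverse problem

### Loss and solver

With deflections linear in the nodal forces, $\Delta_\mathrm{mod} = Gp$,
where the influence matrix $G$ stacks unit-load forward solves
(`influence_matrix()`), the force vector on the contact set minimizes

$$\mathrm{Loss}(p) = \sum_k \left(
 |\Delta^\mathrm{seg}_{y,k} - \Delta^\mathrm{mod}_{y,k}| +
 |\Delta^\mathrm{seg}_{z,k} - \Delta^\mathrm{mod}_{z,k}|\right)
 + \lambda_1 \lVert p\rVert_1 + \lambda_2 \lVert p\rVert_2^2 .$$

Choices fixed here, with rationale:

* **L1 data fidelity is kept as stated** (sum of absolute residuals, not
  squared); an L2-data variant is available behind `data_norm = "l2"` for
  sensitivity checks.
* **The λ₁ term penalizes force components** (elementwise L1). A grouped
  variant (per-node Euclidean magnitude, `l1_grouped = TRUE`) is exposed
  but not default.
* **Deflection observations enter at every interior node** of a segmented
  fiber, not only at contact nodes: off-contact nodes carry information
  about the force distribution and cost nothing.
* **Optional per-axis weighting** (`axis_weights`) rescales the y and z
  residuals by $1/\sigma_y, 1/\sigma_z$; off by default, matching the
  unweighted objective.

The objective is convex (piecewise linear plus convex penalties), so the
randomized initialization — uniform in $[-f_0, f_0]$ per component,
honoring the original workflow's random warm start — cannot change the
minimizer beyond solver tolerance; tests assert seed-independence to
$10^{-4}$ relative. The nonsmooth terms are handled by smoothing
continuation: $|x|$ is replaced by $\sqrt{x^2+\varepsilon^2}-\varepsilon$
with $\varepsilon$ driven down the ladder $10^{-1},10^{-3},\dots,10^{-9}$
μm, BFGS minimizing each stage from the previous solution. Convergence is
declared when the true, unsmoothed loss moves by less than $10^{-6}$
(relative); non-convergence is flagged on the returned object, never
silent. For noiseless data with $\lambda = 0$ the smoothed problem shares
its minimizer with the original one exactly, and recovery is exact to
machine precision. Tests cross-check the solver against an exhaustive
multiscale grid search (final step 0.01 nN) on small instances — a check
that is meaningful only when the minimizer is sharply determined, i.e.
for well-separated contacts with a substantive ridge term (see
"identifiability" below).

### Regularization selection

`select_regularization()` follows the simulation recipe: draw artificial
force patterns on the contact set (log-normal magnitudes, uniform
transverse directions), push them through the forward model, add the
characteristic per-axis Gaussian measurement noise, recover at every grid
point of a λ ladder (default $5\times5$ logarithmic, $10^{-3}$–$10^1$,
20 replicates), and return the grid point minimizing the mean relative
force error together with the full error table. The same simulated
instances are reused across the grid, so the table is reproducible at a
fixed seed.

What to plug in as the noise scale matters. The platform's stated
measurement resolution is 0.3 μm in-plane and 1 μm vertically — these are
voxel-scale figures and remain the package defaults for beam-level
simulation. The actual per-node noise of the full pipeline is considerably
smaller, because each centerline point is an intensity-weighted centroid
over many voxels; on rendered phantoms the extraction error is ≈0.03–0.07
μm RMS. Tuning λ at the voxel-scale noise therefore over-regularizes real
pipeline output and biases contractility markedly downward. The
end-to-end validation consequently estimates the characteristic extraction
noise on a held-out calibration phantom and tunes at that scale — the
package's reading of "characteristic measurement noise", applied
self-consistently.

### Identifiability and what per-node accuracy means

The compliance profiles of neighboring nodes on a taut fiber are nearly
collinear tents, so the per-node force decomposition degrades quickly with
contact density: a least-squares error analysis at the voxel-scale noise
(0.3/1 μm per node) gives a per-node relative error floor of ≈15% for a
single contact node, ≈33% for two contacts 30 μm apart, and ≈58% for three
contacts 16 μm apart — independent of the estimator. The package therefore
states its parameter-recovery guarantee (< 20% median relative force error
at tuned λ) for *localized point contacts*, the protrusion-tip loading
regime typical of immune cells; for dense adhesive contact runs the
per-node decomposition is regularization-dominated while aggregate
quantities (contractility, force maps, per-node averages) remain accurate,
as the end-to-end phantom loop demonstrates under dense contact patterns.

Metrics: `contractility()` sums per-node vector magnitudes
$\sqrt{F_y^2+F_z^2}$ (the `per_component` flag sums $|F_y|+|F_z|$ instead,
since the published wording does not disambiguate); `force_metrics()`
reports contacted-node counts, totals and per-node forces with the
"central part of the fiber" defined as the open window of fraction
`central_fraction` (default 0.5 — the notion is not defined numerically in
the source experiments) around the midpoint, boundary nodes counting as
outside; `fit_log_force_vs_nodes()` fits $F = a\ln n + b$ by ordinary
least squares.

## 3. Deflection measurement from stacks

The pipeline is reference-free because the anchors come from the scaffold
layout: the walls are rigid and their positions are set by the fabrication
design, so no stress-free image is needed. All geometry is computed in μm
world coordinates, which makes voxel anisotropy (0.3 μm in-plane vs 1 μm
axial by default) transparent; world coordinates of voxel centers are
`origin + (index − 0.5) · voxel_size` with 1-based indices.

Steps, with the package's choices:

1. **Foreground detection** — median background subtraction, light
   Gaussian pre-smoothing (σ = 0.7 voxel), global Otsu threshold. A
   Gaussian was preferred to a median filter: with Poisson-plus-read noise
   and tube-like structures the two perform equivalently here, and the
   separable Gaussian is exact, fast and dependency-free.
2. **Component labeling** (`segment_fibers()`) — 6-connected components via
   the voxel adjacency graph, size floor 64 voxels. One label per fiber on
   well-separated scaffolds.
3. **Fiber attribution** (`trace_fibers()`) — foreground voxels are
   assigned to the *nearest nominal fiber line*. This is deliberately not
   component-identity based: strongly deflected neighbors can approach and
   merge into one component, while nearest-line attribution stays
   unambiguous whenever deflections remain below about half the fiber
   spacing (5 μm here — beyond that the fibers would physically collide).
4. **Centerline extraction** (`extract_centerline()`) — one-voxel slabs
   along the nominal axis; per slab the intensity-weighted centroid of
   attributed voxels. Gaps up to 3 slabs are linearly interpolated; more
   than 20% missing slabs is an error (badly segmented fiber). Layout
   anchors are prepended/appended as terminal samples, and the trace span
   must be within 20% of the nominal length.
5. **Deflection** (`compute_deflection()`) — signed perpendicular offsets
   from the anchor-to-anchor chord, decomposed into the in-plane and
   vertical transverse directions and interpolated onto the model nodes.
   Translating trace and anchors together changes nothing (tested to
   $10^{-9}$).
6. **Cell mask and contacts** (`segment_cell()`, `contact_nodes()`) — Otsu
   threshold on the cell channel, largest component, interior holes
   filled; a node is contacted when its deformed position lies in a mask
   voxel or within `reach_um` (default 0.5 μm, about one in-plane
   resolution element) of a mask voxel center. Empty contact sets are
   allowed here; force recovery then refuses explicitly.

## 4. Synthetic phantoms

The generator exists so that every stage — and the whole loop — is testable
without experimental data. It emulates:

* **Scaffold geometry**: two orthogonal layers of parallel fibers
  (80–200 μm long, 5 or 10 μm lateral spacing, 10 μm vertical gap), and the
  four-layer density-gradient design (180 μm fibers, 15/10/5 μm spacings in
  three regions, 5 μm vertical steps, successive layers staggered by half
  the local spacing). Spacings below the 5 μm fabrication limit are
  rejected. Layouts are deterministic, so serializations are byte-identical
  across runs.
* **Traction patterns**: an ellipsoidal cell region; every interior node
  inside it becomes a contact; directions are centripetally biased toward
  the cell center (with angular jitter), mimicking inward-pulling
  peripheral tractions, and magnitudes are log-normal. The default scale is
  0.67 nN per node — the measured average per-node force for the soft-fiber,
  10 μm-spacing condition — which reproduces the observed 1–3 μm deflection
  range on 15–25-node contact runs. (An early draft used 1 nN/node, which
  produced tail deflections beyond the linear regime.) A fully random
  direction mode exists.
* **Ground truth**: deflections are exact finite-element forward solves of
  the sampled forces — by construction, not by simulation.
* **Image formation**: deformed centerlines drawn as Gaussian-profile tubes
  (radii from the section, floored at half a voxel), anisotropic Gaussian
  PSF (default σ = 0.25/0.25/1.0 μm), scaling to photon counts, Poisson
  shot noise, additive Gaussian read noise (defaults: 150 peak photons,
  10 background, read SD 2 — SNR ≈ 10). Seeded and bit-reproducible.

What phantoms do **not** emulate: photobleaching, scattering, spherical
aberration, uneven illumination, cell-shape realism (the mask is a smoothed
ellipsoid), fiber surface nanostructure, buckling, or axial deformation.
Passing the phantom loop therefore demonstrates the *inferential* chain —
segmentation geometry, reference-free deflection decomposition, convex
recovery, regularization selection — under controlled optics, not
robustness to every instrumental artifact of real stacks.

## 5. Validation summary and problem sizes

The test suite asserts, among others: the closed-form stiffness values and
printed calibration figures (T = 71 and 374 nN; $k_\mathrm{axial} \approx
16$ nN/μm; $k_\mathrm{struct} \approx 0.098$ nN/μm, under 3% of the
apparent stiffness); FEM agreement with both stiffness limits;
Maxwell–Betti reciprocity to $10^{-9}$; exact noiseless recovery;
solver–oracle agreement within 0.01 nN; sub-resolution centerline and
deflection errors on rendered phantoms; and an end-to-end loop —
render → segment → trace → deflect → tune λ → recover — over 20 seeded
phantoms at the experimental voxel sizes, with median contractility error
required below 20%.

Problem sizes were chosen to make the full suite complete in a few minutes
on a laptop while remaining at the experimental imaging scale: phantoms
render the full 80 μm two-layer scaffold at 0.3/0.3/1 μm voxels
(≈320×320×26 voxels); regularization tuning uses the default 5×5 grid with
20 replicates; the end-to-end check uses 20 phantom seeds plus one
held-out calibration seed.

## 6. Known limitations

* Axial forces are structurally unobservable; contractility is a lower
  bound for cells loading fibers axially. Watch the residual force.
* Per-node forces on dense contact runs are regularization-dominated
  (Section 2); interpret per-node maps qualitatively there, aggregates
  quantitatively.
* Nearest-line fiber attribution assumes deflections below half the fiber
  spacing; beyond that, neighboring fibers are physically entangled and no
  centerline method will separate them.
* The mechanical model is linear; very soft, long fibers under strong
  cells (where buckling was observed experimentally) are outside its
  validity, and the pipeline should not be applied there.
* Tension calibration inherits the AFM measurement's assumptions (midpoint
  loading, small indentation); the `corrected` mode removes only the
  bending contribution, not instrument systematics.
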