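---
title: "Finite-difference EEG forward modeling and matching-pursuit source localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-difference EEG forward modeling and matching-pursuit source localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An EEG electrode array measures scalp potentials generated by small patches
of synchronized cortical current. Recovering the generator location from the
electrode vector — the EEG inverse problem — requires two ingredients: a
*forward model* that predicts the scalp potentials of any candidate source
through the conductive head (the volume conductor), and an *inverse rule*
that inverts the many-to-one map. `spfdeeg` implements a complete desk-scale
version of one such stack: a voxel-based scalar-potential finite-difference
(SPFD) forward solver, a lead-field matrix assembled by the reciprocity
principle, and a greedy matching-pursuit localizer, together with the
synthetic head phantoms and the Monte-Carlo harness needed to characterize
the pipeline under noise.

## Forward model

In the quasi-static regime the potential $\varphi$ in a medium of
conductivity $\sigma(\mathbf{r})$ with impressed source current density
$\mathbf{J}$ obeys the Poisson problem

$$\nabla \cdot (\sigma \nabla \varphi) = -\nabla \cdot \mathbf{J},$$

with no current leaving the scalp. The SPFD discretization places potential
unknowns on the voxel corner nodes and writes Kirchhoff's current law at
each node over its (up to) six incident lattice edges:

$$\sum_{n=1}^{6} S_n \varphi_n - \Big(\sum_{n=1}^{6} S_n\Big)\varphi_0 = -I_0,$$

where $I_0$ is the current injected at the node and $S_n$ is the edge
conductance. For cubic voxels of edge $h$ each edge is flanked by up to four
voxels and

$$S = \bar\sigma\, h, \qquad
  \bar\sigma = \tfrac14 \textstyle\sum_{\text{flanking voxels}} \sigma,$$

with air (and out-of-grid positions) contributing zero to the sum. The
arithmetic four-voxel mean is the standard SPFD convention; edges entirely
inside air get $S = 0$, which realizes the insulating boundary without any
explicit boundary bookkeeping. Sources are represented as equivalent nodal
current injections: an electrode pair maps to $\pm I$ at two scalp nodes,
and a current dipole of one edge length to $\pm I$ at two adjacent nodes
(moment $I\,h$).

The resulting operator is a symmetric weighted graph Laplacian whose
nullspace is the constant vector; all sources sum to zero, so the system is
consistent. We keep iterates on the zero-mean subspace over head nodes
(deflation) rather than pinning a node, which keeps the operator symmetric
for the multigrid-preconditioned conjugate-gradient option; potentials are
referenced afterwards (to the ground electrode, or by any re-referencing the
caller applies). The head region must be a single 6-connected component —
`assemble_system()` refuses otherwise, since potentials between
galvanically isolated components are undefined.

### Solvers

Two iterative solvers share the convergence contract
$\lVert b - A\varphi\rVert / \lVert b \rVert < \texttt{tol}$ (default
$10^{-6}$):

* `solve_sor()` — successive over-relaxation, default $\omega = 1.9$. Kept
  primarily as a transparent reference; on large grids it needs thousands
  of sweeps.
* `solve_multigrid()` — geometric multigrid. The conductivity volume is
  coarsened by factor 2 (eight-voxel averages; coarse edge conductances are
  re-derived from the coarse conductivity rather than by Galerkin products),
  by default until the smallest node dimension drops below 8. V-cycles use
  SOR smoothing ($\omega = 1.4$, two pre- and two post-sweeps, the
  post-sweeps in reversed order so the cycle is symmetric); restriction is
  full weighting with weights summing to $2^3$, the transpose of trilinear
  prolongation, which keeps injected-current quantities consistent across
  levels. With `accel = "cg"` (the default) the V-cycle acts as a
  preconditioner for conjugate gradients, which is noticeably more robust on
  the two-orders-of-magnitude CSF/skull conductivity contrast; the plain
  V-cycle iteration (`accel = "none"`) is retained and tested, and a
  single-level hierarchy degenerates exactly to plain SOR. On the 2 mm
  sphere phantom (about $7 \times 10^5$ nodes) a solve converges in roughly
  5–12 cycles, about a second of wall time.

The number of multigrid levels is configurable (`mg_levels`) rather than
fixed, because reasonable implementations differ on how deep to coarsen;
the default rule above works well from $16^3$ up to the 0.5 mm scale.

### Fields and current density

`current_density()` recovers $\mathbf{j} = -\sigma \nabla \varphi$ at voxel
centers: per axis, the voxel's field is the mean of the four parallel edge
differences (equivalently the central difference of face-averaged
potentials), times $-\sigma$ of the voxel. Air voxels carry zero current.

## Lead-field matrix by reciprocity

The lead-field matrix $L$ ($M \times 3N$; $M$ electrodes, $N$ gray-matter
voxels, columns voxel-major with $x, y, z$ interleaved) maps a gray-matter
dipole-moment vector to ground-referenced electrode potentials. Building it
column-wise would need $3N$ forward solves; reciprocity needs $M - 1$: for
each non-ground electrode, inject unit current across (electrode, ground),
solve once, and read the electric field at every gray voxel center. For the
75-electrode 10-10 montage that is 74 solves, and 20 for the 21-electrode
10-20 montage.

One sign convention is worth stating explicitly: with $E = -\nabla\varphi$
and the current injected *into* the electrode, reciprocity yields
$\varphi = -L^{E/I}\,p$. We store the rows negated so that
`lfm_predict(L, j)` equals the forward-solved, ground-referenced potentials
exactly (to solver tolerance) — the matching-pursuit correlation is
insensitive to this choice, but an exact $L j = \varphi$ identity makes the
reciprocity property directly testable. The ground electrode's row is
identically zero, and columns are stored raw (no normalization); the
pursuit normalizes per column at query time, which keeps $L$ reusable for
minimum-norm-style extensions.

## Matching-pursuit localization

Given observed potentials $\varphi$, each column is scored by

$$\mathrm{corrcoef}(i) = \frac{\varphi \cdot L_i}{\lVert\varphi\rVert\,\lVert L_i\rVert},$$

and the estimate is the argmax, converted to (voxel, axis) and a mm
location. Cost and memory are linear in $N$; no $3N \times 3N$ object is
ever formed. Two scoring modes exist because the literal argmax of the
signed correlation cannot see a polarity-reversed dipole (its column scores
$-1$): `mode = "abs"` (default) maximizes $|\mathrm{corrcoef}|$ and returns
the sign separately, `mode = "signed"` is the literal rule. Ties beyond
$10^{-12}$ resolve to the lowest column index, deterministically. Columns
with zero norm (gray voxels electrically shielded at coarse resolution) get
correlation 0. `mp_iterative()` extends the rule to $k$ sources by
orthogonal projection: after each selection the least-squares fit on all
selected columns is removed and the residual is scored next; $k = 1$
reduces exactly to `mp_localize()`. `reconstruct_distribution()` re-solves
the forward problem with a dipole at the estimate rather than reading a
current off the pursuit coefficient, so the reconstructed distribution
satisfies the discrete Kirchhoff balance.

## Head phantoms

Real segmented head anatomy is not redistributable, so the package
generates layered-sphere phantoms that preserve the contrast structure that
matters for this pipeline — a thin, highly conductive CSF shell (2.0 S/m)
wedged between resistive skull (0.02 S/m) and brain (about 0.03 S/m):

* **anatomical analog** — five shells (skin, cortical bone, CSF, gray
  matter, white matter; default radii 85/78/72/70/55 mm) with tabulated
  conductivities. The full table covers fourteen tissues for users building
  richer phantoms.
* **homogeneous** — every head voxel at the gray-matter value, 0.0275 S/m.
* **CSF-insert** — homogeneous plus the CSF shell restored, isolating the
  effect of the dominant conductivity contrast.
* **segmentation-free** — the anatomical conductivity smoothed by a masked
  Gaussian (default FWHM 2 mm), emulating volume conductors whose
  conductivity varies smoothly across tissue boundaries instead of jumping
  at segmentation edges.

All four variants share one grid and head mask, so lead fields from
different variants are column-compatible — that is what makes the
model-mismatch experiment well defined. The grid is sized so the sphere
center sits on a voxel center, making the phantom mirror-symmetric about
all three axes (used by the montage symmetry tests).

The smoothing uses *target-normalized* masked convolution: each output
voxel is a convex combination of input head conductivities, so values stay
within the input range exactly and air never bleeds in. The price is that
the conductivity integral over the head is conserved only approximately
(a few tenths of a percent at the default width, from renormalization at
the head boundary); we consider the range guarantee the physically
meaningful property — smoothing should never manufacture conductivities
outside the observed tissue range. Sub-voxel FWHM values fall back to the
identity once the kernel weights underflow, which is the correct limit.

What the phantoms do *not* emulate: gyral folding, realistic CSF thickness
variation, the skull's cortical/cancellous layering, anisotropy, or any of
the remaining nine tissue classes. Passing tests therefore demonstrate the
*algorithmic* correctness and noise behavior of the pipeline, not
millimeter-level accuracy on a real head; absolute errors on anatomical
data depend on anatomy the phantom does not contain.

## Electrode montages

The 10-20 (21 electrodes) and 10-10 (75 electrodes) montages are generated
from the proportional placement scheme on the idealized sphere: the
nasion–inion and ear-to-ear arcs divided in 10 % (18°) steps, the head
circumference ring 10 % above the nasion–inion plane, interior rows by
great-circle interpolation between midline and ring electrodes, and the
`9/10`-suffixed positions on the nasion–inion plane itself. Published
enumerations of "the" 10-10 system differ slightly in which boundary labels
they include; the compiled set here is a principled 75-label superset built
from those rules, not a copied coordinate table. Each electrode direction
is snapped to the nearest scalp-surface grid node; snapping two electrodes
to one node (possible on very coarse grids) is an error advising a finer
grid. The ground electrode defaults to the first label in canonical order
and is configurable; all correlation-based results are
reference-invariant, which is tested.

## Evaluation protocol

A trial draws a gray-matter voxel (uniform), a coordinate axis, and a
polarity; solves the forward problem; adds Gaussian white noise per
electrode at a nominal SNR; and localizes with matching pursuit. The SNR is
defined on ground-referenced potentials excluding the always-zero ground
channel: noise variance is $P_\text{signal} \cdot 10^{-\text{SNR}/10}$ with
$P_\text{signal}$ the mean squared non-ground potential. Noise draws are
shared across lead fields with the same montage, so model comparisons are
paired. The localization error is the Euclidean distance between true and
estimated locations; depth is the distance to the brain center (the sphere
centroid here). Summaries report mean ± SD, maxima, the cumulative error
distribution in 0.5 mm bins, the fraction below 10 mm, and the
depth–error Pearson correlation; `compare_models()` pools each report's
errors across SNR levels into a classic pooled-variance two-sample
two-tailed t-test (Welch via `var_equal = FALSE`).

### The test dipole and exact zero-noise recovery

The evaluation dipole deserves a note. A literal one-edge dipole sits on a
lattice edge, which is offset from every voxel center by half an edge in
two axes; at 2 mm spacing that alone is a 1.4 mm bookkeeping "error" even
for a perfect localizer, purely from comparing an edge midpoint against a
voxel-center estimate. The harness therefore uses the *voxel dipole*
(`voxel_dipole_term()`): $\pm I/4$ spread over the two voxel faces normal
to the axis. This source is the exact discrete adjoint of the lead-field
field extraction, so its scalp pattern equals the lead-field column of its
(voxel, axis) up to solver tolerance, and its nominal location is the voxel
center. With matched forward and lead-field models at infinite SNR,
matching pursuit then recovers the exact voxel — error 0 — as a genuine
consequence of discrete reciprocity, and every nonzero error under noise is
attributable to the noise, not to source bookkeeping. The literal one-edge
dipole remains available (`dipole_source()` / `dipole_source_term()`) and
is what the analytic-sphere validation uses.

## Numerical choices and degenerate inputs

* Relative-residual tolerance $10^{-6}$ throughout; cross-solver agreement
  is tested at $10\times$ the tolerance against a sparse direct
  factorization.
* SOR's residual is recorded every sweep; over-relaxation makes it
  oscillate locally, so monotonicity holds over checkpoint intervals, not
  per sweep. Hitting `max_iter` raises an error carrying the residual
  history.
* A zero right-hand side short-circuits to the zero solution.
* Injected sources must sum to zero (checked); dipole poles must touch gray
  matter when a gray-matter index is supplied.
* Correlation against a zero-norm observation is an error ("no signal");
  zero-norm columns score 0.
* `compare_models()` on two zero-variance samples returns $p = 1$ (equal
  means) or $p = 0$, with a warning, instead of a division by zero.

## Problem sizes

The solver and phantom generator support the native 0.5 mm resolution of
high-resolution head models (the five-shell sphere then has tens of
millions of nodes; a full-resolution lead field is correspondingly
memory-hungry, since it is held dense — electrodes are few, so rows are
cheap, but $3N$ columns grow with the gray-matter count), but all shipped
tests and the reproduction script run at 2 mm spacing: $89^3$ voxels, $N \approx 9.2 \times 10^4$ gray voxels, a 74-solve
10-10 lead field in about two minutes, and Monte-Carlo runs of 30–100
trials — sizes chosen so the whole validation suite runs on one desktop
core. The Monte-Carlo harness accepts the paper-scale 500 trials; the
shipped runs use fewer because the assertions are ordinal (monotonicity,
montage ordering, mismatch ordering) and stable at these sizes.

## Known limitations

Isotropic conductivity only; single-sample (static) potentials, no temporal
model; greedy pursuit assumes a spatially concentrated source — distributed
sources are outside its model class; the phantom's spherical symmetry makes
depth and eccentricity collinear, so depth–error correlations on the
phantom are not comparable to anatomical values; and absolute millimeter
errors depend on anatomy that the synthetic phantoms deliberately do not
contain.
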