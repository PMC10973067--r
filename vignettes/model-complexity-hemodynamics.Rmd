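---
title: "How model complexity shapes simulated cerebral hemodynamics: methods and design"
author: "cowflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How model complexity shapes simulated cerebral hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowflow)
```

## The scientific question

Image-based blood-flow simulations of intracranial aneurysms usually retain
only a handful of outflow branches around the lesion. High-resolution
time-of-flight angiography, however, can resolve dozens of outlets of the
Circle of Willis (CoW). How much does that *model complexity* — the number
of outlets retained — change the computed hemodynamics: centerline
velocities, wall shear stress (WSS), and the flow entering an aneurysm sac
through its neck?

`cowflow` implements this study design end to end on synthetic data: a
CoW-like phantom generator, the image-to-surface segmentation chain, a
centerline network builder with outlet trimming and parametric aneurysm
attachment, a reduced-order pulsatile flow solver, and the comparison
metrics. Because no subject data are distributed, every input is generated
by code, with exact ground truth, so every stage can be scored.

## The synthetic phantom

`generateCowTemplate()` builds a vessel graph with exactly three inlets
(left/right internal carotid arteries and the basilar artery, labelled
`ICAl`, `ICAr`, `BA`), the communicating ring (anterior communicating
artery plus both posterior communicating arteries, so the graph always
contains a cycle and the pressure solve must resolve loop flow), six main
trunks (left/right MCA, ACA, PCA) and a configurable outlet count: the
first six outlets terminate the trunks, the rest are side branches placed
at seeded positions with golden-angle azimuths (which keeps neighboring
branch tubes from merging when rasterized).

Geometric choices, made once and fixed:

* Ring radii are physiological constants (ICA 2.0 mm, BA 1.6 mm, A1 1.1,
  P1 1.0, Acom/Pcom 0.7 mm). The template emulates topology and caliber
  scales, not any subject's anatomy.
* Side-branch radii follow Murray's cube law
  \(r_p^3 = \sum_i r_{c,i}^3\), so trunks taper distally. Two floors
  modify the pure law: every radius is clamped at `minRadius`
  (default 0.7 mm, about 2.2 voxels at the default 0.32 mm spacing, so the
  imaging stage can resolve every branch — the source acquisitions resolve
  all the outlets they segment), and the trunk taper is floored at 75 % of
  the trunk root so that each trunk's distal outlet remains its most
  prominent one; without this, the resolution-inflated side branches
  out-rank the trunk ends and trimming would sever the very paths the
  complex/trimmed comparison needs.
* `rasterizeNetwork()` renders edges as capsules into an isotropic grid
  (default 0.32 mm). Partial-volume mixing at the lumen boundary is
  modelled by supersampling the indicator 3× per axis and box-averaging;
  noise is additive Gaussian (magnitude-MRI Rician noise is deliberately
  not modelled — at the contrast-to-noise ratios used here the difference
  is second-order). The paired `GroundTruth` holds the exact half-maximum
  lumen mask, centerlines and radii.
* Inlet waveforms (`generateInflowWaveform()`) use a periodic von-Mises
  systolic bump over a diastolic baseline, peak at 15 % of the period,
  with the discrete mean equal to the requested mean flow to machine
  precision. Mean flows default to the phase-contrast-MRI values for the
  three inlets (ICAr 3.434, ICAl 3.065, BA 2.332 ×10⁻³ l/s). Period
  (1.0 s) and pulsatility (0.5, i.e. the minimum is half the mean) are not
  derivable from published tables and are declared defaults, both
  configurable.

## The segmentation chain

`vesselnessMultiscale()` computes the Hessian-eigenvalue tubular-structure
measure at six Gaussian scales (σ = 1…6 voxels), γ-normalized with σ², and
fuses them by per-voxel maximum. Shape parameters default to α = β = 0.5
and a structure-norm cutoff of half the maximum Hessian norm per scale.

`regionGrow()` implements seeded flood fill over 26-neighborhoods with a
*static per-seed band*: voxel \(v\) is admitted iff it is connected to a
seed through admitted voxels and \(|I(v) - I_{ref}| \le 0.02\, I_{ref}\),
where \(I_{ref}\) is that seed's intensity. Static bands make the result
independent of traversal order; the mask is the union over seeds.

One design point deserves emphasis. The growing criterion is only
meaningful on an image that is nearly flat inside the lumen. The multiscale
vesselness response is *not* flat — it varies several-fold between the
centerline and the wall — so a ±2 % band on the vesselness intermediate
captures a thin core only. `segmentVolume()` therefore grows on the
(optionally presmoothed) intensity volume by default and offers vesselness
growing behind a flag. A second consequence is a known, quantifiable bias:
the band places the mask boundary at the 98 % intensity level, which on a
one-voxel partial-volume edge lies ≈ 0.48 voxel *inside* the half-maximum
lumen surface. Two things follow:

* Overlap with the half-maximum ground truth is intrinsically capped near
  \(2(r - \tfrac12)^2 / ((r-\tfrac12)^2 + r^2)\) for a tube of radius *r*
  voxels — about 0.83 at r = 3 and 0.95 only above r ≈ 11. Dice ≈ 0.85 on
  a phantom with 3–5-voxel radii is therefore the *expected* score of a
  faithful implementation, not a defect.
* Radius estimation can undo the bias exactly: the `SegmentationMask`
  carries its `boundaryLevel` (1 − tolerance for band growing) and
  `skeletonizeNetwork()` adds `0.25 + (boundaryLevel − 0.5)` voxels to the
  distance-transform radius (0.25 voxel is the expected offset between the
  nearest background voxel *center* and the actual surface). With this
  correction, boundary-edge radii are recovered to well under half a voxel
  and template-direct versus image-derived simulations agree within 10 %.

Under heavy noise the band criterion degrades sharply: suppressing 10 %-of-
contrast noise enough for a ±2 % band to percolate requires presmoothing
that moves the 98 % level several voxels into the lumen. This is an honest
property of the criterion, reported as-is by the acceptance script.

Surfaces are extracted by marching cubes in its tetrahedral-decomposition
variant (six tetrahedra per cell sharing the main diagonal, consistent
across cells), which is guaranteed watertight; masks are smoothed with a
σ = 0.5 voxel Gaussian first (iso-level 0.5) to reduce stair-stepping, and
grey-level isosurfacing of the partial-volume field is available for
sub-voxel accuracy. `smoothSurface()` is plain umbrella-weight Laplacian
smoothing (default 20 iterations, step 0.5; volume-preserving variants were
considered and rejected for fidelity to the simplest published chain).
`cutAndExtrudeEnds()` slices each inlet/outlet perpendicular to the local
centerline direction, removes the distal cap (found by flooding the mesh
graph on the distal side of the plane, so a global plane cannot damage
distant vessels), records the planar cross-section area, and appends a
prismatic extension ending in an open boundary loop. Cut vertices snap to
existing vertices when the plane passes through them, keeping the cut rim
watertight.

## From mask to network

`skeletonizeNetwork()` thins the mask to a one-voxel curve skeleton by
topology-preserving deletion of simple points in six directional
sub-iterations per pass (foreground 26-connectivity and background
6-connectivity are both preserved; curve endpoints are kept, and the
directional scheme erodes tube ends by only about one radius before their
centerline tips become protected). Skeleton voxels of degree ≠ 2 are
clustered into junction nodes; degree-2 chains become edges with length =
polyline arc length and radius = mean corrected distance transform along
the chain. Terminal spurs shorter than twice the local radius are pruned
(thinning artifacts on thick vessels), degree-2 runs are merged
(length-weighted mean radius, which preserves Poiseuille resistance under
mild taper better than an arithmetic mean), and known opening positions
are bound to degree-1 nodes by globally greedy nearest-pair assignment.

`trimNetwork()` keeps the *k* most prominent outlets — prominence being the
outlet cross-sectional area πr², the only outlet attribute the study design
tabulates, with lexicographic label tie-breaks — then iteratively deletes
the dangling chains, so that the kept inlet-to-outlet paths have identical
geometry in the complex and trimmed models. `attachAneurysm()` splits the
parent edge and hangs a lumped compliant sac (volume, compliance) on a
short neck edge; the 3-D sac shape is out of scope, so sac "WSS" is the
neck-edge Poiseuille shear reported explicitly as `wss_proxy`.

## The reduced-order solver

`solveUnsteady()` stands in for a 3-D finite-volume simulation. Vessels are
Poiseuille resistors (8μL/πr⁴) on the graph; blood is Newtonian and
incompressible with μ = 4 mPa·s and ρ = 1055 kg/m³; flow is laminar and
time-resolved at Δt = 1 ms over three cardiac cycles with the last cycle
evaluated. The three inlets inject their prescribed waveforms; every outlet
receives its Murray's-law fraction (exponent n = 2, so fractions equal area
fractions) of the **total** instantaneous inflow; interior flows — in
particular around the communicating loops — follow from the nodal pressure
solve (sparse Cholesky of the conductance Laplacian, factorized once since
the matrix is time-invariant; only the right-hand side changes). Murray
fractions are global by default because with three inlets and a looped ring
a per-branch assignment is not well defined; a `perBranch` mode is provided
for comparison. Aneurysm sacs satisfy \(C\,dP_s/dt = Q_{neck}\) by implicit
Euler, solved simultaneously with the pressures (the sac adds a
symmetric-positive term, so one factorization still suffices); sac defaults
(compliance 10⁻¹² m³/Pa, neck length 1 mm) are declared free parameters of
the surrogate — with them the sac time constant is ≪ one cycle, which is
why the third cycle is periodic to well under 1 %. Vessels carry no
inertance or compliance: the purely resistive model preserves the
split-driven flow-redistribution mechanism the study isolates, which is
the point of the comparison.

Velocity *profiles* are reconstructed analytically: `womersleyProfile()`
Fourier-decomposes an edge's flow series, maps the steady part to the
parabolic profile and harmonic k to the annular-Bessel profile at Womersley
number \(\alpha_k = r\sqrt{k\omega\rho/\mu}\) (complex J₀/J₁ by power
series, accurate for the α ≲ 15 of cerebral arteries). Radial samples sit
on Gauss–Legendre nodes, so the stored quadrature weights integrate the
profile back to the flow to ~10⁻¹³ relative.

## Metrics and the comparison

* `tawss()`: time average of |τ| over the period.
* `osi()`: the standard oscillatory shear index
  \(\tfrac12(1 - |\int \tau\,dt| / \int |\tau|\,dt)\); the source design
  names but does not define OSI, and in the reduced model τ is the signed
  axial shear.
* `nir()`: the positive part of the neck flow in ml/s plus its mean
  (flow *into* the sac; the declared equivalent of positive normal-velocity
  flux through the neck plane).
* `vNorm()`: \(V_{Norm} = V A_{plane} / Q_{plane}\); the velocity used is
  the plane-normal component, the only one defined in the reduced model.
* `centerlineVelocity()`: time-averaged cross-section mean \(\bar Q/\pi
  r^2\) at equidistant arc-length stations along inlet-rooted paths, with
  stations distal to branch-carrying junctions flagged. A 0-D model cannot
  reproduce a literal 3-D point sample; the cross-section mean is the
  default and the Womersley centerline peak is available.
* `compareModels()`: paired deltas with the single declared sign
  convention δX = X(complex) − X(trimmed), per-path difference curves and
  their maximum absolute value.

All period integrals use the trapezoidal rule on the uniform stored grid
(for periodic uniform sampling this equals the mean, which also makes the
metrics exactly invariant to circular phase shifts).

## What the tests do and do not show

The test suite scores every stage against independent oracles: analytic
cylinder/sphere geometry for rasterization and surfacing, a brute-force
Hessian eigen-decomposition for the vesselness filter, an exhaustive
fixed-point iteration for region growing, a dense base-R linear solve for
the network flows, and quadrature identities for the Womersley profiles.
Problem sizes are kept modest by design (grids of ~3 M voxels for the
recovery tests, 60-outlet graphs for the flow tests, 10⁴-sample series for
the metric oracles); all scores are insensitive to these sizes.

The trimming-overestimation claim is reproduced in two forms. On a single
trunk with side outlets, the trimmed model's time-averaged centerline
velocity strictly exceeds the complex model's at every station distal to a
removed offtake — the clean mechanism. On the full 60- vs 10-outlet CoW
template, about three quarters of distal stations show the effect. The
shortfall from 100 % is structural, not numerical: with prescribed total
inflow the outlet fractions sum to one in both models, so trimming cannot
raise (or preserve) every branch's share — some branch must lose share and
its proximal trunk then carries *more* flow in the complex model. Which
branches reverse, and over how many stations, depends on the outlet-area
distribution; reproducing any specific subject's distribution is a
non-goal, and the same proximal reversals appear in the source study's own
basilar-artery centerlines. Passing the trunk-template check while showing
mixed signs on the looped template is therefore exactly the behavior the
study design describes.

Because phantoms are smooth capsules with piecewise-constant radii and
Gaussian noise, passing tests demonstrate correctness of the algorithms,
not performance on clinical angiograms (no flow-related enhancement
inhomogeneity, no motion artifacts, no vessel-wall irregularity).

## Reproducibility

Every generator is a pure function of its arguments including the seed
(RNG state is saved and restored); the solver is deterministic; and
`runStudy()` writes a resolved configuration, a per-stage log and an MD5
manifest, so a re-run with the same configuration reproduces all numeric
outputs bit for bit. The package's functions are the interface;
`runStudy()` is the single entry point that executes the four-case design
(complex/trimmed × physiological/pathological) and emits the two paired
comparison reports.

```{r example, eval = FALSE}
res <- runStudy(studyConfig(seed = 1), outDir = "cow_study")
res$reports$physiological
```
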