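---
title: "Methods: voxel-based micro-FE analysis of cortical windows and bioactive-glass grafts"
author: "osteofe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-based micro-FE analysis of cortical windows and bioactive-glass grafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical and mechanical problem

One-stage surgical treatment of osteomyelitis opens a rectangular *cortical
window* in the infected bone, debrides the infected tissue, and fills the
resulting cavity with a graft — frequently S53P4 bioactive-glass (BAG)
granules, alone or mixed with milled allograft bone morsels. The window and
the debridement weaken a load-bearing bone; the graft may restore part of the
lost stiffness and carry part of the load. `osteofe` implements the in-silico
side of this question as a voxel-based micro-finite-element (µFE) pipeline:

1. **Defect geometry** — how much bending stiffness and estimated failure
   moment a long-bone diaphysis loses as a function of window width and
   length;
2. **Graft material identification** — homogenized elastic properties of
   BAG/morsel beds identified from confined-compression aggregate moduli;
3. **Load sharing** — how axial load at the distal tibia is divided between
   cortical/trabecular bone, BAG granules, bone morsels and the granule
   interface layer once a windowed bone is grafted.

Because the original specimen scans (sheep radii µCT, mixture µCT, human
HR-pQCT) are not deposited, the package ships a first-class synthetic-phantom
generator; every stage of the pipeline runs end-to-end on phantoms, and all
quantitative checks are against closed forms, brute-force oracles, and
self-consistency — not against the specimen-specific numbers.

## The µFE model

Calibrated volumes (`image3d`, intensities in mgHA/cm³, isotropic voxels)
are segmented by fixed thresholds (`seg_thresholds`): a single lower
threshold of 485 mgHA/cm³ for the diaphysis models, 387 mgHA/cm³ for the
distal tibia, and a 515/838 mgHA/cm³ band for mixtures, where bone(-morsel)
occupies [515, 838) and BAG everything at or above 838. Thresholds are
half-open with the boundary voxel assigned to the upper phase — the
convention is ours, chosen to be deterministic and documented, since a
boundary rule is rarely stated alongside published thresholds.

Each non-void voxel becomes one 8-node trilinear hexahedron (2×2×2 Gauss
quadrature) of edge length equal to the voxel size; shared nodes are merged,
and elements outside the largest *face-connected* component are removed and
reported (`phasemap_to_model`). Face connectivity (6-neighborhood) is used
because corner-connected elements meet only along an edge or point and
produce near-singular stiffness contributions. Materials are isotropic
linear elastic per phase: 20 GPa for diaphyseal cortical bone, and for the
grafted tibia model 6826 MPa (tibia bone), 2.5 GPa (bone morsels), 35 GPa
(BAG), 25 MPa (interface), all at Poisson ratio 0.3.

### Boundary conditions

*Pure bending* is realized under displacement control: every node of each
end plane receives the rigid-rotation displacement field of ±θ/2 about the
bending axis through that plane's section centroid, all three components
prescribed. The published protocol prescribes "0.01 rad at both ends", which
is ambiguous between per-end and total; we fix θ_total = 2 × 0.01 rad and
note that every reported outcome is a ratio (maintained fraction, reduction)
in which the convention cancels. The rotation sense is chosen so that a
marked side of the section — the window side — is compressed.

*High-friction compression* fully fixes the bottom plane and prescribes an
axial displacement (default 1% of specimen height) on a laterally fixed top
plane. *Confined compression* additionally suppresses the wall-normal
displacement of every lateral surface node, detected per boundary face from
the voxel occupancy; for a homogeneous block this reproduces the
uniaxial-strain (aggregate) modulus E(1−ν)/((1+ν)(1−2ν)) to solver
precision, which the test suite asserts at 0.5%.

### Solver

The linear system is solved matrix-free (element-by-element) with
Jacobi-preconditioned conjugate gradients in C++; elements sharing a Poisson
ratio share one unit-modulus 24×24 stiffness matrix scaled per element by
its Young's modulus (the hexahedral stiffness is exactly linear in E and in
h). Dirichlet values are imposed exactly and the free equations are solved
to a relative residual of 1e-6 (configurable); stiffness ratios reported at
three significant figures need about 1e-4, so 1e-6 leaves two orders of
margin. All arithmetic is double precision — R has no single-precision
storage, and at desk-scale problem sizes the memory saving would be
irrelevant. Bending solves are warm-started from the Euler–Bernoulli
pure-bending displacement field (`beam_bending_guess`), which roughly halves
the iteration count without affecting the converged solution (the tests
solve with and without the guess and compare).

Element strain is evaluated once per element at the centroid, matching the
per-element failure criterion; the per-element strain energy used for the
energy balance is the exact quadratic form ½uᵀKu, so external work equals
total strain energy to solver precision (asserted at 0.5%). The
energy-equivalent strain is √(2U/E) with U the centroid strain-energy
density — the standard scalar strain measure used with this criterion,
which names but does not define it in most applications.

### Failure criterion

The Pistoia criterion declares failure when more than 2% of the bone
elements exceed 0.7% energy-equivalent strain, evaluated with a prescribed
criterion modulus of 6829 MPa. Linearity is exploited: with ε₉₈ the 98th
linear-interpolated percentile (type-7 quantile; all elements have equal
volume, so count and volume fractions coincide) of the energy-equivalent
strain at the applied load, the failure moment is the applied moment scaled
by 0.007/ε₉₈. A brute-force load-ramp oracle (bisection on the load
multiplier with explicit element counting) agrees to 0.1% on a 10⁴-element
bar, and a bar with a depth-linear strain field matches the closed form
M·0.007/(0.98·ε_max) up to element-count discretization. For
displacement-controlled single-phase models the strain field is independent
of the assigned modulus while the moment scales with it, so the applied
moment is rescaled from the model modulus to the criterion modulus rather
than re-solving. The criterion modulus (6829 MPa) and the tibia bone modulus
(6826 MPa) are close but distinct published values; both are kept as given,
with no reconciliation attempted.

## Synthetic phantoms

`make_bone_phantom` rasterizes circular or elliptical cortical shells; the
distal-tibia shape adds a trabecular core generated as a Gaussian random
field (FFT-smoothed white noise, correlation length 0.8 mm) thresholded at
the quantile that realizes the requested core fill fraction — one parameter
controls a BV/TV-like density, and the realized fill is exact to the
quantile. The defaults are a 9 mm outer radius, 3 mm cortex, 60 mm long
diaphysis tube (a sheep-radius-scale idealization) and a 13 × 10.5 mm
elliptical distal-tibia segment, 1.6 mm cortex, 10.2 mm high, 15% trabecular
fill.

`make_mixture_phantom` packs spheres — BAG granules drawn uniformly from
2–3.15 mm, morsels from 3–5 mm — into a cylindrical container (default
12 mm diameter × 12 mm height) by random sequential adsorption, choosing
each sphere's phase to track the requested BAG share of solid volume.
Strict RSA saturates near 38% solid fraction, well below an impacted bed,
so two proxies for impaction are layered on: candidate positions are drawn
in batches and the lowest feasible position wins (gravity settling), and
spheres may interpenetrate by up to 20% of their contact distance. With the
default target solid fraction of 0.45 the realized voxel solid fraction
lands at 0.40–0.45 and the realized BAG share within ±5 points. The
packing is seed-reproducible; voxelization gives earlier spheres priority
in overlaps.

What the phantoms deliberately do **not** emulate: angular granule shapes
(spheres suffice to exercise segmentation, interface morphology and
homogenization), impaction mechanics, partial-volume blur, and scanner
noise beyond a linear radial droop plus Gaussian noise. Consequently,
passing tests demonstrate the correctness of the pipeline's operations and
the qualitative defect/graft mechanics, not specimen-level accuracy on
real scans.

## Image processing

Beam hardening is modeled forward as a multiplicative linear radial droop,
`I·(1 − droop·r/r_max)`, and corrected by regressing the intensity of a
reference phase (provisionally segmented BAG) on the in-plane radius and
dividing every voxel by the fitted relative profile anchored at the axis.
Whether the published correction was additive or multiplicative is not
stated; the multiplicative form is chosen because it preserves the zero
background and the axis intensity. The correction strength is estimated
from the image itself, so it automatically scales with BAG content, and a
sample with no BAG (the 0 vol% group) receives no correction.

The granule *interface layer* — a soft continuum proxy for contact and
sliding at granule boundaries that a continuum mesh cannot otherwise
represent — is built by eroding the BAG mask by one voxel and dilating the
result by two, with a 3×3×3 cube structuring element (the 6-connected cross
is available as an alternative in principle, but the cube matches the
isotropic one-voxel/two-voxel phrasing). The shell between the dilated and
eroded masks overrules bone and BAG labels but never creates material in
void space; granules thin enough to vanish under erosion are preserved as
BAG with a warning, since converting them wholesale to interface would
delete stiff material on an undocumented rule. The implementation (shifted
array logic) is tested against an independent triple-loop voxel oracle on
random grids.

## Virtual surgery

`projected_width` measures the silhouette width of the bone over a slice
range; `create_cortical_window` cuts a flat-floored rectangular box of a
given width fraction and length, entered from a chosen side. The depth rule
follows the published schematic: windows up to 50% of the projected width
reach through the local cortical thickness, wider windows down to the
short-axis radius (the centerline); the 50% switch point is exposed because
the source phrasing ("smaller"/"wider") is not numeric. For the tibia
study the window is cut with the short-axis-radius rule so that trabecular
bone under the cortex is removed too, mirroring surgical reaming. The
published table of absolute defect sizes has internally inconsistent width
units; only the width:length:area product relation is treated as reliable
and is what the surgery report reproduces (area = realized width × length).

Graft implantation rescales a mixture phase map to the bone's voxel size by
nearest-neighbor label sampling (per-phase volume fractions are preserved
within 2 points; upscaling enlarges grains and interface but not the
homogenized modulus) and copies its labels into the recorded defect void,
clipped to the defect box. The graft source is the *interior core block* of
the packed bed (`mixture_core_region`), because the container's wall and
plate layers contain only sphere tangencies and would leave the graft
mechanically disconnected from the load planes — the physical samples were
scanned through the interior of an impacted plug. Sources smaller than the
defect are tiled with mirrored continuation, with a warning.

## Outcome analyses

Bending stiffness is the reaction moment about the bending axis divided by
the total relative end rotation, averaged over the two end planes (which
differ only by the solver residual); axial stiffness is force over
displacement. Maintained fraction and reduction (1 − defect/intact) are
computed strictly within-subject; the API refuses cross-subject pairs.
Load sharing attributes to each phase the axial internal-force
contributions of its elements to a constrained plane's nodes, normalized by
the plane total, so shares sum to one by construction.

`fit_phase_modulus` identifies one phase's modulus from measured aggregate
moduli. A model made entirely of the free phase scales linearly and is
solved in one step. Otherwise the aggregate modulus is monotone in the free
modulus, and the fit drives the signed mean (or median, config-exposed)
relative error across samples to zero by a safeguarded secant search on the
log-modulus, expanding the bracket geometrically from the initial guess
only as needed; at the self-consistent optimum this coincides with
minimizing the mean relative error, and it avoids the near-singular solves
that a blind wide-bracket minimizer forces at extreme moduli. Inner solves
are warm-started from the previous solution; convergence is declared at a
relative step below 1e-3, and non-monotone or non-bracketing responses are
errors, not silent results.

## Problem sizes and reproducibility

The default study conditions are desk-scale: the diaphysis tube meshes at
0.75 mm voxels (about 20k elements, eight bending solves for the
defect-geometry study), the tibia phantom at 0.5 mm, mixtures at 0.3 mm
(about 20k elements per confined-compression solve), and the beam-theory
refinement sequence runs 1.0/0.5/0.25 mm (8.6k/69k/541k elements). These
sizes were chosen once as the smallest phantoms that keep every geometric
feature resolved (three voxels across the cortex, four across the smallest
granule) while the full suite runs in minutes; the acceptance checks use
exactly these conditions. All randomness (trabecular field, packing, noise)
flows from explicit integer seeds carried in the specification records, and
identical configurations produce byte-identical study outputs.

## Known limitations

* Phantom-level realism only: no angular particles, no partial-volume
  effects, no scanner noise model beyond linear droop + Gaussian noise.
* Linear elasticity with small strains; no contact, damage or geometric
  nonlinearity — the interface layer is the only concession to granule
  contact mechanics, and its modulus is only meaningful immediately
  post-implantation (BAG degradation and bone bonding change it over time).
* The failure criterion is applied to bending as published, but it was
  validated for distal-radius compression elsewhere; failure estimates for
  grafted compression models are intentionally not produced.
* The high-friction column does not admit the confined closed form: with
  free lateral surfaces its stiffness lies between E·A/L and the confined
  bound, approaching E·A/L with slenderness; the tests assert exactly this
  bracket.
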