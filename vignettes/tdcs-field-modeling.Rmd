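---
title: "Modeling tDCS electric fields on synthetic head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tDCS electric fields on synthetic head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Transcranial direct current stimulation (tDCS) passes a weak direct current
(here 2 mA) between scalp electrodes. How much of that current reaches the
cortex — and where — depends strongly on electrode *position*, *size* and
*inter-electrode distance*. `tdcsim` provides a self-contained pipeline to
study those effects: it generates populations of synthetic multi-compartment
head phantoms, places 10–10 EEG coordinates, constructs conventional and
surround electrode montages, solves the quasi-static conduction equation

$$\nabla\cdot(\sigma\nabla\varphi) = 0,\qquad
E = -\nabla\varphi,$$

with Dirichlet conditions on the electrode contact surfaces and homogeneous
Neumann (zero normal current) conditions on the free scalp, and scores every
solve with three outcome measures. A within-subject statistics layer
(repeated-measures ANOVA with Greenhouse–Geisser correction, Tukey post-hoc
tests, intraclass correlations) compares montages across the phantom
population.

The central scientific comparison is between conventional montages that put
one pad *on* the target (bilateral M1: C3–C4; M1–SO: C3–Fp2), the 4×1
high-definition ring, and *surround* montages that bracket the target: the
left–right pad surround (C1–C5) and the anterior–posterior pad surround
(CP3–FC3), including size-matched (1×1 to 7×5 cm at equal edge-to-edge
distance) and distance-matched (+2 to +8 cm at equal size) families, and the
optimized 1×1 cm surround placed 2 cm closer than the CP3–FC3 baseline.

## Phantoms

A phantom is five nested ellipsoidal shells — skin, skull, cerebrospinal
fluid (CSF), grey matter, and a white-matter core — voxelized on a regular
grid (RAS mm coordinates, 0-based indices, voxel centers at
`origin + (index + 0.5) * h`). The default single phantom is spherical with
boundary radii 92/86/80/78/70 mm so that the analytic multi-shell series
solution applies exactly. Conductivities default to the standard literature
values: skin 0.465, skull 0.01, CSF 1.654, grey matter 0.275, white matter
0.126 S/m.

```{r}
library(tdcsim)
ph <- build_phantom(phantom_spec())
eeg <- locate_1010(ph)
```

An optional smooth low-order radial perturbation (a seeded combination of
quadratic/cubic surface harmonics, normalized to a mm amplitude) is added
*identically* to every shell boundary. Because all boundaries shift together,
inter-shell gaps are preserved exactly and the tissue nesting invariant holds
by construction; the only failure mode — the innermost boundary collapsing
through the center — is rejected as a geometry error.

**Population.** `sample_population()` draws independent subjects with uniform
variation in outer radius (84–90 mm), skin (5–7 mm), skull (4–9 mm), CSF
(1.5–3.5 mm) and grey-matter (7–11 mm) thickness, and perturbation amplitude
(0–2 mm). This emulates the between-subject variation that matters most for
conduction: overall head size, skull thickness, and scalp-to-cortex distance
(10.5–19.5 mm across the ranges). The population shares fixed anthropomorphic
axis ratios (`head_axis_ratios()`: left–right 0.94, anterior–posterior 1.15,
inferior–superior 1.22 of the outer radius), giving head breadths of
158–169 mm and lengths of 193–207 mm. The ratios were chosen once so that the
10–10 inter-electrode scalp distances of the study montages land in the
ranges reported for adult heads (e.g. C3–C4 pad gap ≈ 5.4 cm, CP3–FC3 pad gap
≈ 1.5 cm, 1×1 cm pads at CP3–FC3 ≈ 5.5 cm apart); perfectly spherical heads
compress the anterior–posterior arcs enough that the CP3–FC3 pads nearly
touch, which no real head exhibits.

What the phantoms deliberately do **not** contain: gyral folding, the
interhemispheric fissure, eyes, meninges sub-layers, or anisotropic
conductivity. Consequences for interpreting results are discussed under
*Limitations*.

## 10–10 coordinates

`locate_1010()` implements the proportional nested-arc construction on the
phantom scalp: the nasion–inion midline arc is subdivided in 10% steps (Cz at
50%), the preauricular arc through Cz carries the central row (C3 at 30% of
the full arc from the left preauricular point), the 10% circumferential ring
carries Fp1/Fp2 (5% of the ring circumference lateral to Fpz) and the
temporal anchors FT7/8, TP7/8, and the FC/CP rows are placed on the scalp
curves through FT7–FCz–FT8 and TP7–CPz–TP8 at the standard proportional
subdivisions. Arcs whose plane passes through the phantom center are sampled
exactly by radial rays; the ring and row curves use a vectorized bisection
along in-plane rays. On unperturbed spheres the construction reduces to
closed-form angles, which the tests use as oracles (e.g. the Cz–C3 arc is 20%
of the full ear-to-ear arc).

## Montages

Electrodes are ideal-conductor surface patches — the geodesic projection of
the nominal rectangle or disc onto the scalp, defined in geodesic polar
coordinates about the electrode center. There is no sponge, gel or electrode
conductivity: the montage prescribes equipotential contact surfaces, matching
the Dirichlet/Neumann formulation above. Rectangle orientation is a fixed
convention of this package (practice varies and montage descriptions rarely
state it): bilateral-M1 and M1–SO pads have their long axis left–right;
surround pads have the long axis perpendicular to the surround direction.

Two conventions deserve comment:

* **Edge-to-edge distance** is measured along the scalp geodesic through the
  two electrode centers, between the footprint boundaries — a tape measure
  between the facing edges. A minimum over all boundary point pairs would
  instead be dominated by pad corners, which bow toward each other on a
  curved scalp; that definition cannot simultaneously satisfy the
  matched-distance design of the size family and the exact +2 cm stepping of
  the distance family, whereas the facing-edge measure satisfies both (and
  coincides with the minimum for discs and in the planar limit).
* **Distance offsets** (`offset_along_ap()`) move each electrode by half the
  requested change *along the connecting scalp geodesic* (arc length), rather
  than shifting Cartesian coordinates and re-projecting to the nearest skin
  point, which under-delivers the offset on a curved scalp; arc-length
  stepping makes `+2 cm` mean exactly 2 cm of scalp separation.

The Round 2 size family keeps the edge-to-edge distance equal to the 1×1 cm
baseline at CP3–FC3 by recentring the larger pads symmetrically about the
CP3–FC3 arc midpoint. The optimized configuration places 1×1 cm pads with an
edge-to-edge distance exactly 2 cm *smaller* than that baseline (the
6.12 cm → 4.12 cm design arithmetic).

## Solver

The conduction equation is discretized with a conforming finite-volume scheme
on the voxel grid: one unknown per tissue voxel and face conductances from
the harmonic mean of the adjacent voxel conductivities (`g = σ_face · h` in
SI units). Two refinements reduce the thin-shell staircase bias of plain
center-label sampling: faces in the neighborhood of a tissue interface get
their conductance from a small resistor network sampled on the *analytic*
geometry (3×3 parallel strands across the face area, each strand the exact
series resistance along the segment between the voxel centers), and the
electrode terminals couple to their contact voxels through half-cell
conductances on the exposed outer faces, so the electrode sits on the scalp
surface rather than half a voxel deep (+1 V anode group, 0 V cathode group —
all cathodes share one terminal, so the 4×1 current split is free). The
system is a symmetric M-matrix; interior rows sum to zero, which makes the
discrete current exactly conserved — the flux through any separating surface
equals the injected current to solver precision.

The linear solve is a conjugate-gradient iteration with a no-fill incomplete
Cholesky (DIC) preconditioner; because the 7-point stencil's lower neighbors
never share earlier neighbors, the factorization reduces to a diagonal
recurrence, with a modified (MIC, weight 0.99) diagonal that lumps the
dropped fill and roughly halves the iteration count on these grids. The
default relative-residual tolerance is 1e-8; the solve is deterministic.
Current-controlled stimulation is realized by the unit-Dirichlet solve plus
post-hoc scaling (`scale_to_current()`), which is exact by linearity. E-field
vectors use central differences (one-sided at tissue boundaries); `e_mag` is
their Euclidean norm.

Default grid resolution is 2 mm for population runs and 1 mm for convergence
and oracle checks. At 2 mm one phantom solve involves roughly 4–6 × 10^5
unknowns and takes a few seconds on one CPU; the full acceptance population
(20 phantoms × 13 montages) runs in the order of a quarter hour. The original
study's tetrahedral mesh density is not transferable to a voxel solver;
resolution is a configuration parameter with an explicit oracle/convergence
requirement instead.

## The analytic oracle

For concentric spheres the potential has the classic Legendre expansion: in
shell $k$, each degree contributes $a_k (r/R_k)^l + b_k (R_{k+1}/r)^{l+1}$
(the per-shell normalization keeps the recursion overflow-free to order
several hundred). Coefficients propagate from the innermost shell outward
through continuity of $\varphi$ and $\sigma\,\partial\varphi/\partial r$, and
the outer Neumann condition fixes each degree against the electrode current
density: a point electrode injects $(2l+1)/(4\pi R^2)$ per degree, and a
uniform spherical-cap electrode multiplies each degree by
$(P_{l-1}(\cos\alpha) - P_{l+1}(\cos\alpha)) / ((2l+1)(1-\cos\alpha))$.
The series order defaults to 300 with a tail-based truncation warning. The
homogeneous sphere admits a closed form (a generating-function identity),
used to validate the series machinery independently (and the recursion is
cross-checked in the tests against a brute-force linear solve of the
interface conditions); the solver is compared against the heterogeneous
series over the CSF-and-inward region with both fields gauge-aligned by
mean-centering, at 1 mm and 2 mm resolution. The comparison converges at
first order in the voxel size and is dominated by thin-shell leakage of the
nearest-neighbor network at the 46-fold skull and 165-fold CSF/skull
conductivity contrasts: on a homogeneous sphere the error is ~1%, with the
full five-tissue model it is ~23% at 2 mm and ~10% at 1 mm. Within-population
montage *contrasts* — the quantities the study layer reports — share this
bias across montages; absolute field magnitudes at coarse resolution should
be read with it in mind.

The series also encodes the physics the study depends on: with the standard
conductivities the 0.01 S/m skull shunts current through the scalp, so the
brain-region field is several-fold smaller than in a homogeneous sphere at
the same drive — asserted as a property test.

## Outcome measures

* **ROI mean** — mean `|E|` over grey-matter voxels within a 10 mm-radius
  sphere centered on the first grey-matter voxel along the ray from the C3
  scalp point toward the head centroid. The ROI is located once per subject
  and reused for every montage.
* **99th-percentile mean** — mean `|E|` over the top 1% of the masked brain
  by volume (grey ∪ white matter by default; grey-only is a parameter), with
  the boundary element fractionally weighted.
* **Focality volume** — the volume (mm³) of masked tissue at or above
  `level_fraction` (default 0.5) of the robust peak, defined as the
  volume-weighted 99.9th-percentile of `|E|`. A focality phrase like "volume
  at or above the 50th-percentile E-field" cannot mean the volume-median
  (that is half the volume by definition); the half-of-robust-peak reading is
  the convention of the established E-field simulation toolchains. Both the
  level fraction and the peak percentile are configuration parameters.
* **Peak offset** — distance from the volume-weighted centroid of
  above-99.9th-percentile voxels to the scalp midpoint between the electrode
  centers projected onto the grey-matter surface (for 4×1, to the central
  electrode's projection, flagged as such).

Percentiles are volume-weighted with linear interpolation between order
statistics; on the uniform grids used here this equals the ordinary
continuous sample quantile, and ties are included by the `>=` threshold
comparison.

## Statistics

`rm_anova()` computes the one-way within-subject ANOVA from explicit sums of
squares and applies the Greenhouse–Geisser epsilon (computed from the
double-centered condition covariance) to both degrees of freedom — this is
what produces the fractional df convention of the repeated-measures
literature; Greenhouse–Geisser is the default (it is the correction standard
statistics packages apply by default) and Huynh–Feldt is available by
argument. `tukey_pairs()` runs all pairwise comparisons with the
studentized-range adjustment on the within-subject error term.
`icc_roi_vs_p99()` reports the two-way mixed-effects, single-measure,
*consistency* ICC — ICC(3,1) — between the on-target ROI mean and the
whole-brain 99th-percentile mean across subjects; the form is a
configuration choice, and consistency is the default because a fixed offset
between an on-target and a whole-brain measure should not count as
disagreement about *where* the maximum is.

## Study conditions and problem sizes

The packaged study conditions are: 2 mA per montage, 2 mm voxels, the
conductivities above, a 20-subject population for ordinal comparisons (the
acceptance tests) and the full 15-configuration catalog (5 + 4 + 5 + 1 over
four modeling rounds; the CP3–FC3 baseline belongs to Rounds 1 and 3, so 15
configurations cover 14 distinct geometries — 200 subjects × 15 = 3000 solves
in the full design). The bundled acceptance script runs an 8-subject
population so that the complete recomputation (design arithmetic, 2 mm oracle
comparison, 14-montage study, orderings, ICC) stays in the tens of minutes on
one CPU; population size is a parameter, and the orderings it checks are
stable well below n = 20.

## What passing tests do and do not show

The phantoms reproduce the *conduction* physics — skull shunting, scalp
current loss between close electrodes, the depth/separation trade-off — and
therefore the design-driven orderings: surround positioning beats
conventional placement on target; at matched separation smaller pads give
higher, more focal on-target fields; focality degrades monotonically with
separation while the on-target field has an interior optimum; the field peak
sits midway between surround electrodes. They do not contain cortical
folding, so effects that hinge on real anatomy are out of reach. One known
case: on smooth phantoms the left-right surround (C1–C5) is geometrically
closer than the anterior-posterior surround (CP3–FC3) — as it also is on real
heads — and focality tracks separation, so LRPS comes out slightly *more*
focal than APPS, whereas MRI-based models of real anatomy report the
reverse. A
prototype midsagittal CSF fissure slab reduced both montages' focality by
about 12% without reordering them, so it was not adopted into the phantom
model; the corresponding acceptance assertion documents the discrepancy
rather than papering over it. Relatedly, the phantom's CP3–FC3 surround gap
(≈1.7 cm) is smaller than on real heads (≈2.1 cm), which thins the surround
montage's on-target margin over M1–SO from ~33% to ~9%: the subjects with
the deepest cortex (largest scalp-to-cortex distance, thickest skull) can
individually invert that contrast even though the population means reproduce
it.

## Numerical choices

* Solver tolerance 1e-8 (relative residual), MIC weight 0.99, iteration cap
  configurable; breakdown of the diagonal recurrence falls back to the
  unmodified diagonal.
* Harmonic face averaging handles the 165-fold skull/CSF conductivity
  contrast without special-casing; faces to outside voxels carry zero
  conductance (the Neumann condition).
* Geodesic distances between scalp points are computed on the arc cut by the
  plane through the two points and the phantom center — exact for spheres,
  and accurate to well under a millimeter for the head-shaped phantoms used
  here (the scalp is star-shaped about its center). Footprint membership uses
  angle × mean-radius distances, exact on spheres.
* Tissue labeling is vectorized: a voxel's radius is compared against each
  perturbed shell boundary along its own direction; ties at a boundary go to
  the inner compartment (`<=`).
* Degenerate inputs error early and by name: non-positive dimensions,
  non-nesting ranges, montages without both polarities, empty masks,
  overlapping footprints, planes outside the grid.

## Limitations

Phantoms are smooth; absolute field magnitudes and focality volumes are not
comparable to MRI-derived models (the whole-brain mask alone differs by the
missing sulcal surface), and only within-population *orderings* and *paired
contrasts* are meaningful. Electrodes are ideal conductors without sponge or
gel layers. The 10–10 construction assumes the four ring anchors are nearly
coplanar, exact on spheres and approximate on ellipsoids. Anisotropy,
transient stimulation and electrode-skin impedance are out of scope.
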