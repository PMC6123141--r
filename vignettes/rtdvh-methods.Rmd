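---
title: "Methods: DVH computation, geometry and analytics in rtdvh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DVH computation, geometry and analytics in rtdvh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdvh)
```

`rtdvh` turns non-image DICOM-RT filesets (RT Plan, RT Structure Set,
RT Dose) into a queryable relational database of dose-volume histograms,
geometric metrics and radiobiological metrics. This vignette documents the
models and procedures, the parameters that matter, the numerical choices,
and what the synthetic phantoms do and do not demonstrate about clinical
data.

## Ingest conventions

Filesets are grouped by study instance UID; the package assumes one
composite plan per study (all boosts summed into one dose grid), so a
second plan arriving for an already-imported study is refused rather than
silently merged — data duplication in a QA database is worse than a manual
re-import. When several instances of one modality share a study, the
instance with the latest timestamp wins; we use the DICOM instance
creation date+time and fall back to the file's modification time, since no
DICOM attribute is universally present for this purpose. Ties break by
file name for determinism.

Three values cannot be extracted reliably from standard attributes and
follow clinical workarounds instead:

* **Treatment site** — a point of interest named `tx: <site>` (matching is
  case-insensitive and whitespace-tolerant) overrides the plan label.
* **Prescriptions from POI names** — plans from systems that omit
  prescription attributes can encode them in POI names; we accept the
  documented grammar `rx<group>: <name>:<fxs>x<fx_dose>:<percent>%`. The
  grammar is a package convention: any encoding must be agreed with the
  exporting side, and this one round-trips every field of the
  prescriptions table.
* **ITV typing** — structure names beginning with `ITV` are typed ITV
  regardless of the file's interpreted type, because several planning
  systems do not emit the ITV type at all.

## DVH computation

A structure's mask is the set of dose-grid voxels whose **centers** lie
inside the structure's planar polygon set, evaluated per slice with the
even-odd rule so that rings subtract (holes) and disjoint rings add
(islands). Contour slices attach to the nearest grid plane when the gap is
at most half the local plane spacing; slices falling between planes are
skipped rather than interpolated. There is no partial-volume weighting:
the masked volume therefore depends on the grid resolution and converges
to the true volume as the grid refines, which is exactly the behaviour a
user sees when exporting the same plan at different dose-grid settings.

The differential DVH uses a fixed bin width, default **0.01 Gy**
(configurable); bin `i` covers `[(i-1)w, iw)`. The cumulative curve is the
tail sum, so `cumulative[1]` is the structure volume. Alongside each bin's
volume we retain its **mass-weighted mean dose**. Histogram-derived
statistics (mean dose, gEUD) use that per-bin mean rather than the bin
center: with 0.01 Gy bins a bin-center convention offsets every statistic
by up to half a bin, whereas the mass-weighted dose reproduces voxel-level
values to machine precision at no cost.

Endpoints interpolate the cumulative curve linearly between bin edges.
`D_x` returns the largest dose whose cumulative volume still covers the
requested volume, ties on flat segments resolving toward the higher dose;
`D_xcc` requests beyond the structure volume are errors rather than
extrapolations. Relative outputs scale by the prescription dose (for D)
or the structure volume (for V).

### Degenerate inputs

Empty masks (structure outside the grid) rasterize to a warning and an
empty mask; computing a DVH from one is an error ("zero-volume ROI") so a
missing structure can never contribute a silent zero curve. Rings with
fewer than three points are dropped with a warning at parse time.

## Geometry

Planar boolean operations run on the Clipper library (`polyclip`); the
conventions are the package's own. Each slice's rings are canonicalized
under the even-odd rule into oriented rings (holes negative), after
repairing self-intersections by even-odd resimplification; rings that
remain degenerate are dropped with a warning. For DICOM contours —
nested or disjoint rings — even-odd folding is identical to the
"inside subtracts, outside adds" accumulation convention; partially
overlapping rings within one ROI are not standard-conformant input and are
resolved by the same parity rule.

The **combined PTV** is the per-slice union of every ROI whose type begins
with `PTV`, keyed on the merged z set. **Overlap volume** is
`Σ_z area(PTV_z ∩ ROI_z) · Δz` with the thickness taken from the ROI's own
slice spacing (forward gap; the last slice reuses the previous gap — the
choice of side is immaterial for uniform spacing, and uniform spacing is
the overwhelmingly common case). A single-slice ROI borrows the PTV's
median spacing with a warning. z keys snap to 10⁻³ mm so floating-point z
values from different files match reliably.

**Surface distances** are the brute-force multiset of 3-D Euclidean
distances between all boundary-vertex pairs, summarized as min / mean /
median / max in cm. Boundary points are the stored contour vertices, no
resampling: with the phantom generator's ≤ 1 mm vertex spacing the minimum
distance is resolved to about a vertex spacing. External/skin structures
are skipped by default (their vertex counts explode the pair count) and a
guard refuses more than 10⁷ pairs unless forced; both can be overridden
per ROI.

## Radiobiology

From the differential DVH with fractional volumes `v_i` and per-bin doses
`D_i`, the generalized equivalent uniform dose is the power mean
`EUD = (Σ_i v_i D_i^a)^(1/a)`, evaluated in log space so exponents up to
|a| ~ 10⁴ are stable. `a` is the volume-effect exponent: large positive
for serial organs (EUD approaches the maximum dose), near 1 for parallel
organs (mean dose), negative for targets (cold spots dominate). Response
probabilities use the midpoint-logistic form
`NTCP = 1 / (1 + (TD₅₀/EUD)^(4γ₅₀))` (TCP identically with TCD₅₀), which
is 0.5 exactly at the midpoint dose and has normalized slope γ₅₀ there.

No fraction-size (EQD) correction is applied before the power mean: the
correction requires an α/β ratio per structure and silently changing
doses is worse than documenting that DVHs are physical dose; a per-fraction
correction can be layered on the differential DVH by the user. The shipped
preset table (`inst/extdata/radbio_presets.tsv`) carries literature-style
defaults per organ and is explicitly editable — institutions should
substitute their own fitted values, which is why the loader takes any
conforming file.

## Database and query semantics

Five tables — DVHs, Plans, Prescriptions (Rxs), Beams, and the DICOM file
catalog — are linked by MRN + study instance UID. Imports are
all-or-nothing transactions stamped with one import timestamp; the DVH
curve is serialized as comma-separated cumulative volumes at the stored
bin width and contours as per-slice `z: x,y;…` text, keeping every column
engine-portable (the DDL in `inst/extdata/schema.sql` runs unchanged on a
server RDBMS). Selection filters OR values within a repeated category and
AND across categories; range filters are inclusive. Filters over
prescription or beam columns select whole studies via correlated EXISTS
subqueries, so a beam-level constraint never splits a study's DVH rows.

## Analytics

DVH bands resample every curve onto a common axis (zero to the sample's
largest maximum dose, shared bin width), padding past each curve's maximum
with zero, then take per-bin mean/median/quartiles; relative mode divides
each curve by its own volume first. The time-series moving average counts
its look-back window in **distinct simulation dates**, not calendar days,
so a burst of plans on one date does not flush the window; excluded points
(programmatic index lists, replacing interactive selection) leave the
moving average, band and sample mean but stay in the returned series. Two
group comparison uses the Welch t test (no equal-variance assumption to
justify), the Wilcoxon rank-sum test (exact for ≤ 8 untied observations
per group, normal approximation with tie/continuity correction otherwise)
and Shapiro–Wilk normality per group (undefined for constant groups,
reported NA). Correlation matrices use pairwise-complete deletion with a
3-case minimum per pair; regressions delete listwise and refuse exactly
collinear designs naming the dependent columns. P-values are raw — no
multiplicity correction is imposed, since the appropriate correction
depends on how many cells a user actually inspects.

## Synthetic phantoms and what they show

The generator produces spheres, boxes, cylinders, tubes (ring contours)
and two-island structures over uniform, linear-gradient and spherical
falloff dose models, contoured as dense planar rings (≤ 1 mm vertex
spacing) on the grid planes, and writes standards-conformant DICOM-RT
filesets (16-bit dose quantization with stored scaling; UIDs pinned by the
seed so regeneration is byte-stable). Every shape has a closed-form
volume; uniform and gradient models add closed-form dose summaries, and
concentric sphere pairs a closed-form surface gap.

Default study conditions used in the tests and the acceptance script:
2–2.5 mm grids of 24–40 voxels per axis (minutes-scale suites on one CPU;
the convergence study additionally uses a 58 mm cube at 1 mm),
prescriptions of 25–35 fractions totalling 50–70 Gy, and a standard
two-beam photon plan. The convergence fixture places the sphere center at
(0.3, −0.6, 0.45) mm: a structure never sits exactly on the dose-grid
lattice in patient data, and the degenerate lattice-aligned placement
makes voxel-center counting error oscillate rather than converge.

Passing phantoms demonstrates the computational chain — parsing,
rasterization, boolean geometry, histograms, persistence, statistics — to
analytic truth. They do not exercise inter-observer contouring variation,
non-axial orientations, heterogeneity artifacts in real dose grids, or
vendor-specific DICOM quirks beyond the encodings written here; validation
against a clinical planning system remains the user's commissioning step.

## Known limitations

Only axis-aligned (identity-orientation) dose grids are supported; CT/MR
image series, DICOM networking, dose resampling onto finer grids, signed
or Hausdorff surface distances, PRV expansion and LKB/Poisson
radiobiological alternatives are out of scope. The even-odd convention
resolves partially overlapping rings within one ROI by parity, which may
differ from a planning system's rendering of such (non-conformant)
input.
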