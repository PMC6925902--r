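---
title: "Keyed affine geomasking: model, design choices, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyed affine geomasking: model, design choices, and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomask)
```

## The problem

Health institutions hold point data — geocoded patient addresses, case
locations — that they cannot share, yet the analyses they need (hotspot
surfaces, clustering statistics) require exactly those coordinates. Geomasking
resolves the tension by displacing the points before sharing. Most masks
(random perturbation, aggregation) buy confidentiality by degrading spatial
structure, which changes the analytical results. An *affine* mask (isomask)
instead moves every point with the same rigid motion: pairwise distances, and
with them every distance-based statistic, are untouched. The collaborator
analyses the data in a fictitious geography and returns results that the data
guardian — and only the data guardian — can map back onto the real one.

## The mask

Given offset intervals $\{X_1, X_2\}$ and $\{Y_1, Y_2\}$ (metres) and a single
random number $r \in [0,1)$ drawn once per dataset, every point $(x, y)$ is
first translated

$$X = x + r\,(X_2 - X_1) + X_1, \qquad Y = y + r\,(Y_2 - Y_1) + Y_1,$$

then rotated clockwise about the coordinate origin by an angle $\theta$ drawn
uniformly from $\{90^\circ, 180^\circ, 270^\circ\}$. With $X_1, Y_1 \ge 0$ the
translation alone displaces every point by at least
$\sqrt{X_1^2 + Y_1^2}$ — the donut-style minimum-displacement guarantee — and
the rotation destroys the orientation cue a pure translation would leave.
The inverse applies the anticlockwise re-rotation and subtracts the same
offsets. The secret $(r, \theta)$, the intervals, and the masked points'
bounding rectangle are stored in a local key store under a user-chosen key;
masked outputs carry nothing but displaced coordinates and the untouched
attribute table.

Because the mask is a rigid motion, the average nearest-neighbour statistic
(observed and expected mean distance, their ratio, the z-score) and Ripley's
$K$/$L(d)$ are identical on masked and original data; kernel-density and
interpolation surfaces computed in the masked geography are cell-for-cell
permutations of the originals. The package's test-suite and
`scripts/acceptance.R` verify all of these equalities numerically rather than
asserting them.

## Design choices

**Quarter-turn angles only.** The angle is restricted to $\{90, 180, 270\}$
degrees. Three reasons. First, the rotation matrix entries are exactly
$-1, 0, 1$, so rotation is exact in floating point and the round trip is
lossless. Second, a quarter turn maps an axis-aligned rectangle onto an
axis-aligned rectangle of equal area, so statistics whose null model depends
on the bounding rectangle (the Clark–Evans expectation, the $K$ estimator's
area term) are *exactly* invariant, not merely approximately. Third, a raster
computed on masked points can be returned to the original orientation by an
exact array rotation — no resampling, no value change. Arbitrary angles would
break all three properties. The angle is drawn per masking run and stored in
the key record.

**Rotation pivot at the origin.** Rotating about $(0,0)$ needs no stored pivot
and composes cleanly with the stored translation; the inverse is fully
determined by $(r, \theta)$ and the intervals.

**One shared $r$.** A single random number scales both axis offsets. Two
independent draws would be marginally harder to guess but the stored record
grows, and the method's security rests on the key store either way.

**Minimum displacement by redraw.** The rotation can, for particular
geometries, move a point back near its original location even though the
translation respects its componentwise floor. `mask_points()` therefore
redraws $(r, \theta)$ (bounded at 100 attempts) until every displacement
clears the configured minimum, checked by explicit distance computation.

**Projected coordinates only.** Degrees are not metres; rotating
longitude/latitude pairs would silently distort the pattern. A geographic CRS
is rejected with an explicit message rather than warned about.

**Degenerate intervals are allowed but warned.** With $X_1 = X_2$ and
$Y_1 = Y_2$ the displacement is a fixed, guessable offset; the mask still
works (the formulas apply with $r$ irrelevant) but the package warns that
privacy is weaker.

## The key store

The store is a single local file the data guardian keeps: a versioned header
line followed by one JSON record per masking, append-only. Keys are unique and
never overwritten — losing or replacing a record makes the corresponding
masked data unrecoverable, so deletion requires an explicit `confirm = TRUE`.
Doubles are serialized with 17 significant digits, which round-trips IEEE
doubles exactly; the tests assert bit-identity of `r` after a save/load/reopen
cycle. A relational embedded database would offer nothing extra here: the
access pattern is append and key lookup, and a flat text file keeps the
guardian's secret inspectable and trivially backed up.

## Raster re-transformation

A collaborator returns a north-up, square-cell raster computed from the masked
points. Re-transformation proceeds in three steps:

1. **Values**: the cell matrix is rotated anticlockwise by $\theta$ — an exact
   permutation (90/270 swap the dimensions).
2. **Unadjusted corner**: the raster's corner coordinates are rotated
   anticlockwise about the origin and re-translated with the stored $r$; the
   rotated footprint's $(\min x, \max y)$ is the unadjusted top-left. For
   $\theta = 180^\circ$ this is precisely the masked raster's bottom-right
   corner rotated anticlockwise; taking the footprint's bounding box is the
   same construction stated so that it is also correct for 90 and 270, where
   the relevant corner is the top-right or bottom-left.
3. **Extent adjustment**: analysis tools rarely snap their raster exactly to
   the data, so the stored masked-point extent is compared with the raster's
   own extent side by side; the summed left+right and top+bottom differences
   $(x_{adj}, y_{adj})$ shift the corner:
   $X_{left} = X'''_{left} - x_{adj}$ and
   $Y_{top} = Y'''_{top} + y_{adj}$ if $y_{adj} < 0$, else
   $Y'''_{top} - y_{adj}$. The y rule subtracts the magnitude in both sign
   cases while the x rule subtracts the signed value; this asymmetry is kept
   exactly as the method defines it, and a unit test pins both branches with
   hand-computed values. When the raster is snapped to the masked-point
   extent both adjustments are zero and the placement is governed by step 2
   alone.

**When is the re-transformed surface cell-wise equal to the surface computed
on the originals?** Exactly when the two grids sample the plane at image
points of one another: the analysis extent must span the point bounding box in
a whole number of cells. Otherwise the conventional "cover the extent with
whole cells anchored top-left" rule puts the overhang on opposite sides in the
two geographies and the grids are shifted by that overhang. The verification
scenarios therefore pin the analysis window by including its four corners in
the point set (a study-window convention, like fixing the frame of a map
series) and choose a cell size that divides the window. The equality tests
then demand agreement to $10^{-9}$ relative — the residual is pure
floating-point rounding from the translation — and exact multiset equality of
cell values between the masked and re-transformed rasters.

## Verification statistics

The statistics are implemented from first principles because they *are* the
verification instrument; each is pinned to closed-form two-point cases and a
brute-force enumeration oracle in the tests.

- **Average nearest neighbour** (Clark–Evans): $omd$ is the mean Euclidean
  nearest-neighbour distance, $emd = 0.5/\sqrt{n/A}$,
  $z = (omd - emd)/(0.26136/\sqrt{n^2/A})$, two-sided normal p-value. The
  study area $A$ defaults to the minimum enclosing axis-aligned rectangle (the
  common desktop-GIS convention); a convex-hull area and a user-supplied
  value are available. Ratios below one indicate clustering.
- **Ripley's K**: $K(d) = A \cdot \#\{\text{ordered pairs with } d_{ij} \le
  d\} / (n(n-1))$, $L(d) = \sqrt{K/\pi}$, $\mathrm{Diff} = L(d) - d$, at
  evenly spaced bands $b \cdot d_{max}/n_{bands}$. No edge correction by
  default — the invariance argument needs none, since both patterns see the
  same bias — with the reduced-sample (border) correction available.
  $d_{max}$ defaults to a quarter of the shorter bounding-box side.
- **KDE**: quartic (biweight) kernel, $\frac{3}{\pi h^2}(1 - (d/h)^2)^2$ for
  $d \le h$, evaluated at cell centers; densities in points/m².
- **IDW**: Shepard weights $d^{-p}$ (default $p = 2$), exact hit returns the
  point's value; results are convex combinations of the data values.

The p-value under strong clustering underflows to zero at display precision;
it is reported as computed and printed as `p < 1e-15` when appropriate.

## Synthetic data

The generator emulates a clustered urban epidemic: a Thomas process over a
5 × 5 km window — parents Poisson with intensity $8 \times 10^{-7}$/m²
(about 20 cluster centres), Poisson(30) offspring each, isotropic Gaussian
scatter with 150 m standard deviation — plus uniform (CSR) controls and a
smooth-surface-plus-noise attribute generator for interpolation tests. Counts
follow a Poisson cluster process with boundary thinning; the tests check the
realized mean against the analytic expectation (with the retention integral
evaluated numerically) across 50 seeds.

What the synthetic patterns do *not* emulate: street-network alignment,
geocoding error, population-weighted placement, or duplicate addresses. The
masking equalities are exact algebraic properties and transfer to real data
unchanged; conclusions about *statistical power* of ANN or Ripley's K on real
epidemics do not follow from these fixtures.

Verification problem sizes: round trips at ~500 and ~5000 points, statistic
invariance over 20 patterns (≈500–900 points each) × 3 angles, surfaces on
50 × 50 grids (100 m cells) — sizes at which every quantity is computed
exactly and the whole suite runs in well under a minute.

## Numerical conventions

- Round-trip and isometry tolerance: $10^{-6}$ m on coordinates of magnitude
  up to ~$10^4$; observed residuals are ~$10^{-12}$ m (pure double rounding).
- Statistic invariance and surface equality: $10^{-9}$ relative.
- Quarter-turn rotations and array rotations are exact; the only inexact
  operations in the whole pipeline are the translation add/subtract and the
  statistics themselves.
- Ties in nearest-neighbour distances need no tie-break (only the distance
  enters); coincident points in IDW average their values on an exact hit.
- Empty point sets, zero-area windows, non-positive bandwidths or cell sizes,
  unknown keys, non-quarter angles, and geographic CRSs are rejected with
  specific errors rather than propagated.

## Limitations

- The mask is global and rigid: anyone who learns the true location of a
  single masked point can recover the entire dataset (rotation pivot and
  offsets follow from one correspondence plus the stored extent shape). This
  is inherent to structure-preserving masks; the defence is custody of the
  key store, not mathematics.
- Only point layers are masked; boundaries, street files or census layers
  must not be shared alongside, as they re-anchor the geography.
- Rasters must be north-up with square cells; anything else is rejected.
- The extent-adjustment rule is asymmetric in y by definition; when a
  collaborator's raster extent differs asymmetrically from the stored point
  extent the placement follows that rule verbatim, which may not centre the
  raster as a GIS would. Snapping the analysis extent to the masked points
  avoids the issue entirely.
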