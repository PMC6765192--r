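---
title: "Methods: quantifying larval zebrafish neurovascular-unit phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying larval zebrafish neurovascular-unit phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfnvu)
```

`zfnvu` quantifies behavioural, neuronal-activity and vascular endpoints of
larval zebrafish under a 2×2 treatment design (glucose vs mannitol,
with/without the NO donor SNP). This vignette is the package's account of
its methods: the models and formulas, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical choices that matter.

## 1. Behavioural endpoints

### Geometry and zones

All behavioural analysis happens in well-centred mm coordinates with y
increasing upward ([`px_to_mm()`] converts tracker pixel exports). A
[`well_geometry()`] is a circle (default radius 11 mm, one well of a
12-well plate) bisected by a diameter divider whose unit normal points
into the darkened half. A point's zone is the sign of its offset along
that normal; points exactly on the divider are labelled *light* — a
deterministic tie-break that touches only a measure-zero set of positions.

### Speed classes and time budgets

Instantaneous speed is Euclidean displacement over elapsed time per
consecutive frame pair. The tracker's printed class bands ("high > 6.4,
low 3.3–6.3, inactive < 3.3 mm/s") leave (6.3, 6.4) unassigned at display
precision; the package implements the exhaustive half-open bands
[0, 3.3), [3.3, 6.4), [6.4, ∞) mm/s, which preserve the printed thresholds
and order. Budgets are computed in 1-min bins: per bin, the percentage of
time in the light, and *within each zone* the percentage of zone time per
class — the normalisation that prevents light/dark preference differences
from masquerading as activity differences. Bin values are averaged with
equal weight (not duration-weighted, matching the "binned then averaged"
protocol); bins in which a larva never visited a zone are excluded from
that zone's class averages but count as 0% toward its time share. 15-min
blocks, when requested, average the same 1-min bin values within each
block.

### Path segmentation and the artefact filter

Trajectories are cut into maximal single-zone segments. Divider flicker
(a larva sitting on the boundary) produces spurious one-or-two-frame
segments; segments whose *point count* falls strictly below the 1st
percentile of the per-recording segment-length distribution are removed
before geometric feature extraction. Three documented defaults, each
overridable: length is sample count (the artefact is a frame-level
flicker, not a short excursion), the percentile is per recording (the
artefact rate is a per-recording property, and the filter must not depend
on cohort composition), and the comparison is strict (`<`), so
uniform-length inputs lose nothing. Filtering at a fixed realised
threshold is idempotent. Transitions are counted on the *unfiltered* label
sequence — they equal the number of unfiltered segments minus one — since
the filter exists only to stabilise the geometric features.

### Minimum enclosing ellipse, ε, MPDE, MPDC

Each kept segment's points get the unique smallest-area enclosing ellipse.
The solver maximises the log-determinant in the lifted D-optimal-design
formulation by Khachiyan-type iterative reweighting with away/drop steps,
on the convex hull of the segment (the fit depends only on hull points).
Numerical choices:

* points are centred and scaled before solving (the fit is
  affine-equivariant), and the shape matrix is rescaled after convergence
  so containment holds *exactly* — the area inflation from that rescale is
  bounded by the duality gap;
* convergence is a relative duality-gap tolerance of 1e-7 with an
  iteration cap of 1e5. When more than d(d+3)/2 = 5 points lie on the
  optimal boundary the optimal design weights are non-unique and the gap
  stalls while the ellipse itself is long converged; the solver therefore
  also stops when the objective gains less than 1e-7 over a 200-iteration
  window, which corresponds to an area suboptimality near 1e-4 — two
  orders below the tightest tolerance any consumer of the fit uses;
* degenerate inputs (fewer than 3 distinct points, or a collinear set,
  detected by a singular-value ratio below 1e-9) collapse to the segment
  between the two extreme points: a = half the largest pairwise distance,
  b = 0, eccentricity 1.

From the fit: ε = √(1 − (b/a)²) (0 for a circle, 1 in the collinear
limit) and MPDE, the mean distance of the segment's points to the ellipse
centre, measure spatial elongation/exploration; MPDC, the mean distance to
the *well* centre, measures thigmotaxis. Per-larva endpoints are
unweighted means of per-segment values per zone ("mean of per-segment
eccentricities" is the documented reading of the per-larva eccentricity
endpoint; a duration-weighted alternative would be defensible but is not
the default). Zones a larva never entered yield `NA`, never zero.

## 2. Synthetic behaviour generator

The generator is a correlated random walk with latent structure chosen to
exercise exactly the statistics the analysis assumes:

* **Locomotor state** follows a three-state continuous-time Markov chain
  (inactive/low/high) sampled at the frame interval via the matrix
  exponential of the rate matrix. Default mean dwells are ~4/2/1 s; state
  speeds (1.0, 4.8, 9.0 mm/s) sit inside the three class bands so budget
  recovery is unambiguous. No speed distributions of real larvae are
  public — this three-state construction is an assumption, and its
  empirical occupancy is tested against the chain's eigen-stationary law.
* **Heading** accumulates wrapped-normal turns with concentration κ
  (default 4) plus a wall-attraction steering term `w·sin(φ_out − θ)·dt`
  toward the outward radial direction (default gain 0.8 s⁻¹) that produces
  thigmotaxis; walls reflect specularly with a radial fold.
* **Light/dark preference** comes from a divider-crossing rule: crossings
  into the preferred side always pass; crossings out are accepted with
  probability `((1−p)/p)/crossing_bias` (capped at 1), a flux-balance
  heuristic that puts the long-run light fraction near the target `p` at
  `crossing_bias = 1`, exactly in the preferred side at `Inf`. The
  realised long-run value is validated against a 10× longer single-run
  simulation, not a closed form.
* **Frame rate**: the tracker's rate is not public; the generator default
  is dt = 0.2 s (5 Hz), an explicit parameter everywhere.
* **Treatment presets** encode only effect *directions* (glucose: lower
  light preference, higher activity and crossing rate, stronger wall
  attraction; SNP co-treatments equal control, modelling the full rescue).
  The magnitudes are arbitrary package defaults — the package makes no
  claim to reproduce the study's effect sizes, and acceptance is parameter
  recovery, not value matching.

What the generator does **not** emulate: beat-and-glide swim kinematics,
acclimatisation drift over the hour, tracking dropouts, and any mechanism
of the SNP rescue. Passing tests therefore demonstrate that the *analysis*
recovers known structure of this class, not that real larvae behave like
the model.

Cohorts derive per-larva seeds deterministically (`seed + index`); every
generator restores the caller's RNG state, so all outputs are pure
functions of (params, seed).

## 3. Calcium transients

ΔF/F₀ uses a low-percentile baseline (default the 20th), either global or
rolling. The rolling estimate is a strided windowed percentile (computed
every half window, linearly interpolated) — an O(n) approximation to the
exact rolling percentile that tracks drift slow relative to the window
(default 30 s); a drifting but event-free trace is recovered to well
within 1% under that assumption.

Detection operates on the locally detrended series (ΔF/F₀ minus its
running median over 10 s — long against a transient, short against
residual drift), lightly smoothed (0.5-s running mean) so noise bumps on a
decay tail do not masquerade as maxima. The noise sd is the scaled MAD of
that series, making detection invariant to affine rescaling of the raw
fluorescence. Local maxima must exceed `4.5 × noise sd` (with an absolute
floor of 0.02 ΔF/F₀ so numerically tiny residuals on noise-free traces are
never events) *and* rise by at least that much above the surrounding
signal (a prominence gate that rejects bumps riding a tail); peaks closer
than 2 s merge, keeping the larger, and peak times are refined to the
unsmoothed argmax just before the smoothed peak. The threshold multiplier
is a package choice set where both of the suite's operating requirements
hold — a per-trace false-positive probability at the percent level on pure
noise *and* ≥ 95% recall at 5× noise sd. Frequency is 60·count/duration;
when an underlying event *rate* is wanted, the standard non-paralysable
dead-time correction `r/(1 − r·τ)` with τ the merge window accounts for
unresolvable close pairs.

## 4. Image quantification

Stacks are channel-named voxel arrays with physical voxel size
(default 0.6 × 0.6 × 1.0 µm, the acquisition geometry). The vessel chain
is: per-pixel maximum-intensity projection over z → Gaussian pre-smoothing
(σ = 1.5 px; stabilises the mask boundary so the skeleton does not wander)
→ threshold (Otsu by default, fixed by configuration; the original
analysis constants are not public, so every run logs its realised
threshold) → hole filling and removal of components under 50 px →
Zhang–Suen thinning with staircase pruning (a degree-2 skeleton pixel
whose two neighbours are mutually adjacent is a redundant corner) →
length as the sum over adjacent skeleton-pixel pairs (1 or √2 pixel
units), with triangle reduction (a lateral pair closed into a triangle by
a diagonal neighbour is not counted) and tip extension halfway to the mask
boundary (thinning retracts a tip by about the tube radius while the end
cap overshoots by the same amount). On generated ground truth this reads a
101-px line at 0.6 µm/px as exactly 60 µm, a 100-µm straight tube to
within 1%, and a 45°-rotated tube within 8% of its axis-aligned twin —
the residual being irreducible digital-skeleton noise.

Channel intensity per vascular length is the masked signal sum divided by
skeleton length (the klf2a:GFP and DAF-FM endpoints); it is exactly
invariant to signal outside the mask. Fixed-tissue-volume endpoints (GFAP,
TRPV4, GS) are plain ROI means over an explicit, configured box — no
automatic tectum detection is attempted. Mural nuclei are counted by
thresholding the nuclear channel in the ROI, labelling 3-D components at
26-connectivity (breadth-first on a padded volume) and discarding
components under 4 µm³. Simple thresholding cannot split nuclei whose
centres are closer than ~4σ of the blob width; the generator's default
minimum separation (6 µm = 4σ) respects that operating range, and counts
are gain-invariant when the threshold is Otsu-derived.

The generator writes stacks whose intensities are integer counts, so TIFF
round trips are voxel-identical; metadata travels in a JSON sidecar.
Vessel-length and expression endpoints are exercised on nuclei-free stacks
(the vessel-reporter line carries no nuclear label), nuclei counting on
stacks with nuclei — mirroring the different transgenic lines used per
assay.

## 5. Group statistics

Per endpoint: Shapiro–Wilk per design cell (reported and warned on, never
acted on — no automatic nonparametric fallback; the gate is informational
only), then a two-way ANOVA on osmolyte × SNP with
interaction using type-II sums of squares — on the balanced or
near-balanced 2×2 cells of this design types I/II/III coincide or nearly
so, and II is the conventional default when the SS type is unstated.
Pairwise comparisons default to the four contrasts the study design draws
(mannitol vs glucose, the two rescue contrasts, mannitol vs rescued
glucose); the family is configurable, including the fully crossed six.
Sidak adjustment is `p_adj = 1 − (1 − p)^m` over the configured family —
the identity at m = 1, monotone in both arguments. Stars follow the
figure-legend convention (\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001,
0.0001).

The type-I calibration of the interaction test is checked by simulation
with per-larva endpoint values drawn directly from the null (normal
deviates at n = 12/cell) — the property under test concerns the testing
pipeline, and cohort-scale trajectory simulation is exercised separately
in the parameter-recovery and end-to-end checks.

## 6. Problem sizes and runtime choices

The test suite runs the behavioural generator at the study's recording
length (3600 s at 5 Hz): 200 larvae for light-preference recovery against
a 36,000-s single-run oracle (compared through a 99% t-interval whose
dominant error is the oracle's 10-block SEM), 40 larvae per group for the
treatment-direction tests, and 12 per cell for the end-to-end run.
Calcium checks use 300-s traces at 10 Hz (40–200 replicates); imaging
checks use stacks near 160 × 120 × 40 voxels; the ANOVA null calibration
uses 1000 simulated endpoint tables. These sizes keep every Monte-Carlo
comparison inside its sampling error at a few minutes of CPU.

## 7. Known limitations

* The percentile artefact filter and the transition count are defined
  before/after filtering by documented convention; the original scripts'
  exact choices are not public.
* Vessel length is measured on the 2-D projection skeleton, as the
  normalisation endpoint is defined on projections; out-of-plane tortuosity
  is invisible to it.
* ROI discovery (neuronal somata, the tectum outline) is out of scope —
  masks and boxes are inputs.
* The behaviour generator's effect magnitudes are arbitrary; only effect
  directions are meaningful, and nothing here validates the biological
  model of the rescue.
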