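---
title: "Cell sociology from multiplex IHC: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell sociology from multiplex IHC: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the problem left them open.

## The measurement model

### Spectral unmixing

Brightfield multiband images of chromogen-stained tissue follow
Beer–Lambert behaviour: after conversion to optical density,
`OD(pixel, λ) = log10(blank(λ) / I(pixel, λ))`, the spectrum at each pixel
is modelled as a non-negative linear combination of the stain absorbance
spectra plus noise,

```
OD = C · S + E,   C ≥ 0.
```

Three assumptions define the fit: the spectra are constant across the
image; concentrations are non-negative; and per-pixel concentrations are
*not* required to sum to one (no additivity). Dropping additivity avoids
needing spectra for glass and unstained tissue. With `S` fixed the problem
separates into one small non-negative least-squares solve per pixel,
which `mcr_als_unmix()` performs directly (deterministic, one pass); the
`refine_spectra = TRUE` mode alternates concentration and spectra updates
under non-negativity — useful when the supplied spectra are only
approximate, at the cost of the usual bilinear-model indeterminacies.

Numerical choices:

* Spectra are row-normalized to unit maximum before solving; the physical
  scale then lives entirely in the concentrations. This removes the
  scale indeterminacy of the bilinear model.
* Raw intensities below 1 count are clamped to 1 before the log; the
  clamp count is recorded on the result and reported as a warning. An
  OD that saturates this floor (very dense stain against a low blank) is
  no longer linear in concentration.
* The per-pixel solve uses the unconstrained solution when it is already
  feasible and falls back to an active-set NNLS only where negativity
  appears — identical results, large speedup on mostly-clean pixels.
* In refine mode, a stain with zero mass everywhere keeps its input
  spectrum (its spectrum is unidentifiable from that image); convergence
  is declared when the relative residual change drops below `tol`
  (default 1e-8) or the fit is exact to within 1e-10 of the data norm.
* A rank-deficient spectra matrix is rejected up front, naming the most
  collinear stain pair.
* An extra artifact spectrum (e.g. for dark debris) can simply be passed
  as a fifth row of the spectra matrix; nothing downstream assumes four
  stains.

### Nuclei segmentation

Nuclei are segmented from the hematoxylin concentration map by iterative
Otsu thresholding with size rules: a first global threshold, removal of
objects below `min_size` (50 px at 0.33 µm/px, ≈ 5.4 µm²), re-thresholding
of objects above `split_size` (1000 px) at the Otsu level computed from
the object's own pixels (necessarily higher than the global level, which
is how "increasing thresholds" is realized without a magic constant),
with fragments of at least `fragment_size` (150 px) becoming new objects
and smaller fragments staying with their parent. After every iteration
each object is examined with a Euclidean distance transform and watershed;
multiple basins split the object. Objects still above `split_size` are
reprocessed, up to 3 iterations in total.

Fixed conventions, chosen where the procedure is otherwise underspecified:

* Components are 8-connected throughout.
* The Otsu histogram uses 256 bins over the sample's min–max range, which
  makes every threshold scale-invariant (the whole segmentation is
  invariant to multiplying the map by any k > 0). When the
  between-class-variance criterion is maximized by a plateau (the usual
  case for well-separated modes, where any cut through the empty gap is
  optimal), the *middle* of the plateau is returned. The left edge would
  sit immediately above the dimmest foreground pixel and makes relative
  cutoffs (boundary refinement, below) degenerate.
* The watershed uses an h-maxima-style suppression of `h_px = 2` px
  (EBImage's `tolerance`): regional maxima of the distance map closer
  than 2 px in height are merged, which prevents boundary roughness from
  oversplitting round nuclei.
* Watershed regions below `min_size` are absorbed into the largest
  sibling region rather than becoming nuclei.
* The oversize test is applied to post-watershed objects.
* The published edge-relocation boundary refinement used by the original
  platform is *not* reimplemented; `refine_boundaries()` is a stated
  substitute: boundary pixels dimmer than half their nucleus's own Otsu
  level are trimmed, with removals reverted when they would empty or
  disconnect a nucleus (label count and topology are preserved by
  construction).

### Phenotyping

Integrated intensity per stain is the sum of the concentration map over
the nucleus mask; for the membranous markers (CD3, CD8, CD79a) the mask is
first dilated by a 2-px disc, since membrane staining falls just outside
the nuclear boundary. Both the ring radius and the set of ring stains are
configurable; the dilated mask may overlap a neighboring nucleus, which is
accepted (it is exactly the situation the conflict resolution handles).

Positivity is one threshold per stain per slide. The package standardizes
on "higher concentration = more positive"; legacy thresholds drawn on
inverted 0–255 intensity scales (positive *below* the threshold) can be
imported with `scale_direction = "below"`. Interactive visual
thresholding is out of scope; `auto_thresholds()` offers a hands-off Otsu
default on the per-slide integrated-intensity histogram.

The three binary calls define 2³ = 8 groups. T-lineage (CD3) and
B-lineage (CD79a) markers on one nucleus are incompatible: most such cells
are two overlapping cells the segmentation could not separate. The
automated stand-in for visual review is geometric: when the
intensity-weighted CD3 and CD79a centroids within the cell lie at least
`min_offset_px = 2` px apart, the cell is split — the original keeps its
position and becomes the T cell (retaining its CD8 status), and a new
cell is added at the CD79a-weighted centroid as the B cell, marked
`origin = "split_added"` with a `parent_id`. Conflicts that fail the
offset test are marked `EXCLUDED`. The rare CD3−CD8+ (± CD79a) cells are
assigned to `UNSTAINED` rather than dropped, which preserves the tissue
architecture for the tessellation.

## The sociology model

### Neighbor graph

Cell neighbors are cells whose Voronoi polygons, clipped to the ROI
polygon, share a boundary segment of positive length. The implementation
clips each generator's half-plane intersection directly (nearest
candidates first, with a provable early exit), in C++; the test suite
checks it edge-for-edge against an independent brute-force oracle that
intersects the half-plane constraints as 1-D intervals along each pair's
bisector.

Conventions where the definition needs sharpening:

* **ROI boundary**: polygons are clipped to the ROI; cells whose polygon
  touches the boundary remain valid nodes. This avoids the spurious
  hull-spanning adjacencies of an unbounded tessellation without
  introducing a distance cutoff, which the neighborhood definition
  deliberately avoids.
* **Cocircular degeneracies**: four points on a circle meet at a point;
  point contacts are not neighbors (shared length must exceed 1e-9 px).
* **Duplicate centroids** are jittered by 1e-6 px with a warning; fewer
  than 3 non-collinear cells is an error.
* **EXCLUDED cells** stay in the tessellation — they shape the geometry —
  but are removed from both numerator and denominator of every frequency
  and from densities.

### Frequencies, densities, permutation null

For focal cell *c*, `f(c, N)` is the fraction of its non-EXCLUDED
neighbors with phenotype *N*; per ROI and ordered pair (F, N), the mean
and SD over all F-cells with at least one eligible neighbor. Focal cells
with zero eligible neighbors are skipped, not counted as zeros (counting
them as zeros would conflate isolation with avoidance). `f(F, N)` and
`f(N, F)` are both reported; they differ in general. Densities divide
phenotype counts by the ROI polygon area converted with the pixel spacing
(default 0.33 µm/px).

The permutation test holds all positions and the graph fixed and permutes
the labels of non-EXCLUDED cells (sampling without replacement — every
replicate preserves the exact per-phenotype counts; EXCLUDED cells keep
their labels). The default is 500 replicates; z uses the sample (n−1)
SD, and a degenerate null (SD = 0) is flagged rather than divided by.
Permutation is per ROI, matching the fixed-positions-within-an-imaged-area
framing. |z| > 3 is the non-randomness flag; under the null the z-scores
are empirically centred with |z| > 3 in well under 2% of runs (see the
calibration test).

### Cohort comparison and the benefit score

Group comparisons are two-sided Wilcoxon rank-sum tests on ROI-level
values pooled by outcome group (exact for small untied samples, normal
approximation with tie correction otherwise).

The ROI-level benefit score formalizes "does sociology add to density?"
as follows: per metric, each outcome group g gets the interval
`[mean_g − sd_g, mean_g + sd_g]` of its ROI-level values; an ROI value is
*informative* when it falls in exactly one group's interval (that group
is its call). Per ROI: +1 when density is uninformative and the sociology
call matches the patient's true outcome; −1 when sociology calls the
wrong group; 0 otherwise. Patient verdicts follow the sign of the summed
score. This exactly-one-interval formalization was chosen because it
reproduces the +1/0/−1 trichotomy with no extra parameters; the source
description of the heuristic mixes "within the range of the means" and
"outside the range of the standard deviations" and is not implementable
verbatim. By default the group intervals exclude the patient being scored
(leave-one-patient-out), so no patient classifies itself; this is a
deliberate strengthening and can be switched off
(`leave_one_out = FALSE`). Note the score is invariant under consistently
renaming both outcome groups (a pure relabelling); flipping a single
patient's recorded outcome negates that patient's contributions.

## Synthetic tissue: what it does and does not emulate

`generate_tissue()` places cells on a hexagonal lattice with Gaussian
positional jitter (SD = 15% of the spacing, default spacing 30 px ≈ 10 µm)
clipped to the ROI — hexagonal packing approximates an epithelial sheet
and guarantees non-degenerate Voronoi cells. Phenotype counts are drawn
multinomially from the requested proportions (default 85% unstained tumor,
6% + 6% T subsets, 3% B), and the spatial regimes span the null-to-
structured continuum: `uniform` (random labels), `clustered`
(Neyman–Scott-like occupation of sites around random parents, ~15 cells
per parent), `segregated` (contiguous blocks), and `infiltrated`, where a
`mixing_fraction` of each immune type is scattered uniformly through the
tumor sheet and the rest is clustered. `render_cube()` is the exact
forward model of the unmixing stage (Gaussian nuclear and marker blobs,
`blank · 10^−(C·S)` plus optional OD-domain Gaussian noise), with
synthetic Gaussian-shaped absorbance spectra standing in for measured
chromogen spectra.

`generate_cohort()` injects a group difference *only* through the
infiltration mixing fraction (defaults 0.15 vs 0.85), with cell counts and
proportions shared between groups — expected densities are matched while
tumor–immune neighbor frequencies differ, which is precisely the contrast
the sociology metrics exist to detect.

What the generators do not emulate: irregular nuclear shapes and sizes,
stromal architecture, staining gradients and batch effects, chromatic
aberration, fixed-pattern camera noise, and cell-density gradients within
an ROI. Passing tests therefore demonstrate the correctness of the
computations and the qualitative behaviour of the statistics, not
performance on real slides — real-data thresholds, in particular, still
need per-slide review.

## Validation problem sizes

The shipped tests exercise: oracle equivalence of the neighbor graph on
twenty 100–200-point instances; null calibration over 50 independent
500-cell fixtures at 500 permutations each; unmixing recovery on
noiseless and 1%-noise cubes (10 draws); segmentation of a 30-nucleus
fixture and a touching-disk pair; and 200 replicate in-silico cohorts of
11 vs 8 patients × 5 ROIs × 150 cells, in which the sociology metric's
rank-sum p-value beats the matched-density metric's in well over 90% of
replicates. These sizes were chosen as the smallest that make the
statistical assertions stable; all scale linearly if enlarged.

## Known limitations

* The Voronoi construction is 2-D; thick sections with overlapping cell
  layers violate its premise (the conflict-splitting step is a partial
  mitigation).
* Neighbor frequency is a first-order statistic; second- and third-order
  neighborhoods are out of scope.
* The boundary refinement is a stated substitute for the original
  edge-relocation algorithm, not a reimplementation of it.
* Automatic Otsu thresholds assume a bimodal integrated-intensity
  histogram per marker; weakly expressed markers need manual thresholds.
* The permutation null fixes the composition margin; it tests arrangement,
  not abundance.
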