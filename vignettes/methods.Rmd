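---
title: "Atlas-based quantification of small-animal brain PET: methods and design"
author: "petquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based quantification of small-animal brain PET: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Dynamic small-animal PET of the rodent brain delivers 4-D images in which
anatomy is barely visible: a metabolic tracer such as FDG lights up the
whole brain roughly uniformly, while a target-selective tracer binds a
focal molecular target and leaves the rest of the brain dim. To report
uptake per anatomical structure (cortex, thalamus, cerebellum, ...), the
PET data must be carried into the coordinate frame of a high-resolution
MRI atlas. petquant implements that chain semi-automatically: after manual
image import and basic study configuration, everything from preprocessing
to group statistics runs without interaction.

The pipeline is: preprocess each dynamic volume; segment the brain volume
of interest (VOI) in each control animal by contour matching against the
resized atlas; pick the best-aligned control as reference and build an
averaged PET template; align every animal to the template (within-subject
rigidly, across subjects deformably); co-register the template to the MRI
atlas in two affine steps; resample the dynamic data into atlas space;
quantify per sub-region with fractional membership; and run automated
group statistics with plots.

# Preprocessing

Five slices at each axial end of the field of view are discarded (poor
sensitivity at the edge of the axial FOV), and isolated nonzero voxels are
removed with a 26-neighbourhood rule: a foreground voxel of the
frame-summed binary image is kept only if at least five of its 26
neighbours are foreground. The filter runs as a single pass on the summed
mask and the removals are applied to all frames. The per-frame variant
would remove more voxels in early, count-poor frames; the summed-mask
variant is the stabler choice and keeps the dynamic data consistent across
frames, which is why we adopted it.

Frame summation produces the high-count image used for *alignment only*.
Within each experimental group, summed images are rescaled by
`max_j(mean_j) / mean_i` so their mean intensities match the largest one;
this compensates differences in injected activity during registration.
The mean is taken over all voxels (including zeros) by default; a
nonzero-only mode is available (`groupIntensityFactors(meanOver =
"nonzero_only")`). Quantification always goes back to the original,
unscaled dynamic frames — both the summation and the group factor exist
only to stabilise registration.

# Atlas resampling with fractional membership

The MRI/atlas grid is 20-30x finer than the PET grid. A single isotropic
scale factor `1 / round(pet_inplane / mri)` resizes the MRI volumes to PET
resolution: 776 um PET against 39 um MRI gives 1/20, against 25 um gives
1/31. The PET z-spacing (796 um) differs slightly from in-plane; we derive
the single factor from the in-plane value, which is what reproduces the
conventional factors for these atlas/scanner pairs. A per-axis mode exists
for strongly anisotropic data.

Hard labels cannot be interpolated, so each sub-region's indicator volume
is resized *independently* with trilinear interpolation; the interpolated
values are the per-voxel occupancy fractions of that region on the PET
grid. Because interpolation is linear, the fractions automatically sum to
the resized whole-brain indicator (partition of unity), which the test
suite asserts to 1e-6. The binary brain support is the set of voxels with
total fraction above 0.5, and fractions at or below 1e-3 are zeroed to
bound memory; both cutoffs are exposed as arguments.

# VOI segmentation by rotational contour matching

Both procedures start by zeroing the caudal third of the axial extent
(the animal is centred with the brain in the rostral two thirds) and
adapting an intensity threshold, starting from the Otsu level, by
bisection on the intensity range until the largest connected component is
within 20% of the resized atlas voxel count (at most 50 iterations; if
nothing comes within 50% the segmentation fails with an error). The
description this concretises says only "approximately the size of the
resized atlas"; the 20% band and the bisection are our choices and are
configurable. We read the size comparison as voxel counts: a literal
connected-component count would compare 1 against 1 for any threshold.

The thresholded object is matched against the atlas support with a
boundary-F1 (BF) score: precision is the fraction of candidate boundary
voxels within 1 voxel (Euclidean) of the atlas boundary, recall the
converse, and the score their harmonic mean. The tolerance default of one
voxel is our choice; no tolerance is standard. The atlas mask is rotated
through a per-axis grid of -20 to 20 degrees in 2-degree steps
(nearest-neighbour resampling about the volume centre), centroid-aligned
to the candidate, and the best-scoring placement wins; ties go to the
smallest total absolute angle, then lexicographic (x, y, z) order. The
default search is coordinate descent over the axes in z, x, y order (63
evaluations); an exhaustive 21^3 mode exists
(`rotationSearch(mode = "exhaustive")`). Note a geometric resolution
limit: at one-voxel BF tolerance, a rotation of 2 degrees moves even a
26-voxel-long semi-axis by less than one voxel, so angles within one grid
step of the truth can tie — recovery is therefore guaranteed only to one
2-degree step, and only for elongated masks.

For metabolic tracers the VOI is the thresholded candidate under the
best-placed atlas contour (intersection with the placed mask dilated by
one voxel — the final masking step is shown but not defined in the
original workflow; the one-voxel dilation absorbs contour discretisation).

For target-selective tracers the bright object is the head, not the
brain. The thresholded object is reduced morphologically: cavity fill,
opening with a 3x3x3 element, marker-based splitting of touching
components (markers from the eroded object, grown by multi-source BFS — a
marker-based watershed equivalent), and retention of components
overlapping the central axial band. The interior (eroded) voxels of the
reduced object seed the contour match: the atlas mask is anchored at each
component centroid in turn and the rotation search runs per seed. This
whole reduction sequence is deliberately isolated in one internal function
(`morphologicalReduction`) because the original description leaves it
under-specified; substituting a different reduction requires touching
nothing else.

# Template construction

Control VOIs are compared by principal-axis orientation: the inertia
eigenvectors of the VOI mask, with the longest axis assigned to z, middle
to x, shortest to y (the brain is ellipsoidal and the animal lies along
z). The control with the smallest angle sum is the reference; it is
centred on its VOI centroid by an integer-voxel shift. Every other
control is deformably registered to the centred reference and the
template is the voxel-wise mean. Our deformable backend is a rigid
pre-alignment followed by dense demons refinement with Gaussian field
regularisation (sigma 1.5 voxels); convergence is declared when the
correlation coefficient between warped and fixed changes by less than
1e-8, with a 1000-iteration cap — cap and tolerance follow the reference
settings for template construction and remain arguments. Any backend that
optimises a correlation-coefficient similarity over a smooth transform
satisfies the same contract; the demons displacement field is our
implementation of it, chosen because no deformable registration library is
part of this package's dependency set and the field-based scheme is
compact and fully testable.

For a target-selective template the VOI is segmented from the *inverted*
template: crop to the content bounding cuboid, exclude voxels above half
the maximum (the bright target), contrast-stretch the rest to [0, 1] and
invert, so healthy tissue becomes bright. The gradient-magnitude shell of
the inverted volume, thresholded at the Otsu level capped at half the
maximum gradient, is used as a blocking set, and a seed at the grid
centre grows by iterated one-voxel dilation without crossing it. Two
numerical details: on near-piecewise-constant volumes the gradient
histogram concentrates on a few interface magnitudes and plain Otsu can
cut away part of the shell (hence the half-maximum cap); and the blocking
shell is dilated by one 6-connected step to close diagonal gaps, with the
grown mask dilated back correspondingly. If the central seed lands on a
boundary or excluded voxel it relocates to the nearest valid voxel. We
use the thresholded gradient shell directly as the blocking set; a
thinned (skeletonised) variant would admit the same growth but with
thinner walls, and the thick shell is the conservative choice.

# Registration and transform reuse

All registrations run on min-max normalised copies; resampling is always
applied to the original data. Rigid (6 parameters) and affine (12:
rotation, translation, log-scale, shear) transforms are estimated by
Nelder-Mead over the chosen metric (mean squares for mono-modal pairs,
negative correlation, or negative mutual information from a 64x64 joint
histogram for cross-modality), initialised by intensity-centroid
alignment and restarted once from the optimum. Iteration caps and
tolerances default to the reference settings per context (within-subject
rigid: 2000 and 1e-21; template co-registration affine steps: 500/2000 and
1e-15); tolerances below machine precision are clamped inside the
optimiser. Mean squares is the mono-modal default; the metric is an
argument everywhere.

Within a subject, disease states are rigidly registered to the control
state. Because paws, glands and other structures can derail a rigid
alignment of the brain alone, the registration runs on auxiliary images:
for metabolic tracers, the image masked to everything above the adaptive
threshold (brain plus Harderian glands — high, stable FDG uptake linked
to the head); for target-selective tracers, the intensity-inverted VOI
combined with the rostral half of the head at half intensity. Across
subjects, controls are deformably registered to the template and each
subject's other states *reuse* the control's chain bit-for-bit — no
re-registration — which the tests assert as an identity on voxel arrays.

The optional second-template path covers studies where disease alters
uptake so strongly that deformable registration to a healthy template
would be misled: a second template is built from the designated
experimental group, its members align to it rigidly (never deformably),
and the second template is rigidly registered onto the primary one; an
audit log records the registration kind per member.

Template-to-MRI co-registration is two affine steps: gradient-magnitude
images first (rough alignment), then the template VOI volume onto the
resized MRI brain support with mutual information. Central-difference
gradient magnitude is our operator choice. Transform chains are applied
with a single trilinear interpolation pass: output coordinates are folded
through every step (affine matrices exactly; deformable displacement
fields interpolated), then the source image is sampled once — so a chain
of k transforms costs one interpolation, not k.

Similarity reports (Pearson, Spearman, joint entropy and mutual
information in bits from a 64-bin joint histogram, over the full image or
a VOI) are computed before and after every registration and written to a
CSV; visual verification of alignments remains advisable and the exported
NIfTI QC volumes support it.

# Quantification

Three semi-quantitative parameters per region, animal, state and time
interval, computed on the original dynamic frames summed over each
requested interval (intervals are half-open in minutes and must tile
whole frames; a misaligned interval raises an error listing the valid
boundaries):

* normalized activity `A_N = region activity / injected activity`;
* `SUV = region concentration / (injected activity / body weight)` in
  g/mL, with region concentration = fraction-weighted activity divided by
  fraction-weighted volume;
* uptake ratio `UR = region activity / reference activity`, where the
  reference is the whole VOI or a designated reference region. The
  cerebellum is the usual reference when surgery or disease touches large
  parts of the brain. UR is computed on activities, following the
  "measured radioactivity" wording of the underlying formulas; a
  concentration-based (SUVR-like) variant is available
  (`concentrationBasedUR = TRUE`) because regions differ in volume and
  the garbled source formula admits either reading.

Region activity uses fractional membership: activity is the sum of
fraction times concentration times voxel volume, so partial-volume voxels
contribute proportionally and region activities sum exactly to the
whole-VOI activity. Voxel values driven below zero by interpolation are
clamped to zero before aggregation. A_N and SUV scale linearly with a
global intensity rescaling while UR is invariant; the alignment-only
group normalisation factor therefore never touches any reported value.

# Group statistics

The test plan follows the sample-size rule: nonparametric below 30 per
group, parametric from 30. Paired designs use the signed-rank test (two
groups) or the Friedman omnibus with signed-rank post hoc (more); unpaired
designs the rank-sum test or Kruskal-Wallis. The source workflow names
the rank-sum test as the Friedman post hoc in one place and uses the
signed-rank test in its worked three-state comparison; for a paired
design the signed-rank test is the coherent choice and is our default,
with the rank-sum variant available. The parametric branch (t tests,
one-way and repeated-measures ANOVA) completes the rule; the source
never names its parametric tests, so these are the standard analogues.

The rank tests implement mid-ranks and exact small-sample paths: the
signed-rank null is enumerated over all 2^n sign assignments up to n = 15,
the rank-sum null over all label assignments up to combined n = 20
(without ties), and the Friedman permutation null by dynamic-programming
convolution over per-subject rank permutations up to 8 subjects and 4
groups. Larger samples use the usual chi-square and tie-corrected normal
approximations with continuity correction. Two-sided p-values throughout;
the source reports only significance stars, so sidedness is our
convention. No multiple-testing correction is applied across regions by
default (matching the source workflow); Holm adjustment is available
(`adjust = "holm"`). Normality diagnostics (Shapiro-Wilk, Anderson-Darling,
QQ points) accompany every cell; boxplots with individual animal points
and QQ plots are written as PNG (and SVG where a cairo device exists).

# The phantom generator

All validation runs on synthetic rodent-head data with known ground
truth. The brain is an ellipsoid (default semi-axes 13 x 10 x 16 PET
voxels on a 64 x 64 x 80 grid at 776 x 776 x 796 um) partitioned into
five axial slabs — olfactory, cortex, thalamus, hippocampus, cerebellum —
whose volumes have closed forms (ellipsoid slab integrals), so the
voxelised atlas can be checked analytically. The MRI/atlas grid is an
integer factor finer (default 3x, so the printed 1/20 and 1/31 factors are
exercised separately through the scale-factor arithmetic). Metabolic
cohorts get per-region uptake near 5 kBq/mL plus a pair of anterior
Harderian-like hotspots outside the brain; target-selective cohorts get a
dim brain (1 kBq/mL), a bright focal lesion (10 kBq/mL) and surrounding
head tissue at 3 kBq/mL. Each animal receives a known rigid perturbation
(up to 6 degrees and 2.5 voxels by default), a monotone time-activity
scaling across frames, and Gaussian noise with variance proportional to
intensity (a Poisson surrogate; default sigma gives about 5% voxelwise CV
at tissue level — heteroscedastic like count noise, cheap to generate).
Each animal draws from its own seeded RNG stream, so cohorts are bitwise
reproducible.

What the phantom does *not* emulate: scanner physics (scatter, randoms,
point-spread blur), anatomical realism beyond ellipsoid sectors,
inter-animal anatomical variability beyond rigid perturbation, and
motion. Passing tests therefore demonstrate correctness of the
algorithms under controlled geometry and noise, not clinical-grade
performance on scanner data.

For statistical calibration experiments that need hundreds of cohorts,
`simulateQuantCohort()` generates quantification tables directly from the
ground-truth uptake model (per-animal lognormal random effect,
multiplicative measurement noise) without the imaging stages; the type-I
calibration of the Friedman branch runs on 200 such null cohorts.

# Problem sizes and numerical choices

The test-suite and the acceptance script run at deliberately desk-scale
sizes chosen once as the package's validation conditions: registration
recovery on 48^3 two-bump volumes, segmentation on the default
64 x 64 x 80 phantom, rotation-search recovery on a 64^3 ellipsoid with
semi-axes (26, 12, 20) voxels (elongated enough to resolve one grid
step), and the end-to-end pipeline on a 48 x 48 x 60 grid with three
animals, two states and three frames, with the demons cap lowered to 40
iterations (the blobs converge long before the production default of
1000). Degenerate inputs raise errors rather than guesses: spheres have
no principal orientation, constant images no Otsu threshold or
correlation, empty masks no centroid; all-zero difference vectors give
the degenerate signed-rank p of 1 with a flag.

# Known limitations

* The demons deformable backend assumes mono-modal, roughly
  intensity-matched inputs (it follows the rigid pre-alignment and the
  group intensity normalisation); it is not suited to cross-modality
  deformable registration, which the pipeline never needs.
* Rotation-search resolution is bounded by the BF tolerance geometry (one
  2-degree step at one-voxel tolerance, see above).
* Hemisphere splitting uses the bounding-box midplane of the region, not
  a curved anatomical midline.
* No decay correction, kinetic modelling or blood-glucose correction:
  inputs are assumed scanner-calibrated activity concentrations and the
  three parameters are deliberately semi-quantitative.
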