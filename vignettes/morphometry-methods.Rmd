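---
title: "Automated mouse-brain morphometry: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated mouse-brain morphometry: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multimorph)
```

`multimorph` implements a fully automated morphometric phenotyping pipeline
for ex vivo mouse-brain micro-MRI: several brains are scanned together in a
single field of view, separated into individual images, oriented into
standard RAS space, intensity-standardised, tissue-segmented, spatially
normalised into a common group space, and analysed voxel-wise for local
volume (TBM) and tissue-density (VBM) differences between genotype groups,
with regional volume tables on the side. This vignette explains the models
behind each stage, the tunable parameters and their defaults, what the
synthetic phantoms do and do not emulate, and the design decisions taken
where several reasonable options existed.

## Multiple-subject extraction

Several fixed brains (in-skull) are packed in a low-signal holder inside a
syringe filled with proton-free embedding fluid, so the acquired volume
contains N bright subjects on a dark background, plus small hyperintense
agarose identification markers. Thresholding alone is unreliable: weak
thresholds keep extraneous material, strong ones cut low-signal tissue and
carve concavities. The pipeline therefore:

1. standardises intensities (trained on the image itself, landmarks within
   the whole volume) and smooths with a 3D Gaussian kernel, FWHM 0.2 mm;
2. fits a two-component 1D Gaussian mixture (background vs subject) to the
   intensity sample by EM, and takes the per-voxel Bayes posterior of the
   bright component;
3. thresholds the posterior at 0.5 — the Bayes decision boundary; the
   threshold is a free parameter (`threshold`) because the source procedure
   does not state one;
4. labels 6-connected components, discards components below 1% of the
   expected subject volume (noise speckle), and fits a rasterised 3D convex
   hull around each remaining object, which restores internal concavities
   (collapsed ventricles, fissures, vessels);
5. keeps the N objects whose hull volumes are closest to the expected
   volume (a training-mask mean in practice), breaking ties toward the
   larger volume and then the smaller world x centroid, and crops each with
   a configurable margin, updating the affine so world coordinates are
   untouched.

The mixture EM runs to a relative log-likelihood change below 1e-8 (cap 500
iterations), initialised by k-means seeded on the intensity quantiles with a
fixed seed, so results are reproducible. The convex hull is computed by an
incremental (quickhull-style) algorithm over candidate boundary voxels and
rasterised by testing voxel centres against the facet half-spaces,
column-by-column, which is exactly verifiable against brute-force point
enumeration.

## Orientation to standard space

Brains may sit in any pose. Two anatomical regularities drive the
correction: the antero-posterior axis is the longest (AP > RL, IS), and the
brain is approximately mirror-symmetric about its mid-sagittal plane.

1. **Principal axes.** The intensity-weighted inertia tensor (second central
   moments in world mm about the intensity centroid, intensities below a
   background level carrying no weight) is diagonalised; the eigenvector
   with the smallest eigenvalue is the AP axis and is rotated onto +y; the
   largest-eigenvalue axis (the shortest extent, IS) goes to +z. Signs are
   fixed to give a proper rotation — no reflection is ever applied to a
   subject. A ratio below 1.05 between the two smallest eigenvalues flags
   degeneracy (a near-spherical object cannot be oriented this way).
2. **Roll search.** 14 candidate rolls about y, uniformly spaced over
   [0°, 360°), are scored by the Pearson correlation r between the image
   and its reflection in the plane x = (intensity centroid x). Because the
   r landscape can peak between the coarse rolls, the top three basins are
   refined by a bounded 1-D search; ties go to the smallest angle.
3. **Halfway refinement.** The image is rigidly registered to its own
   reflection, giving a transform A; resampling through the log-Euclidean
   half of A (principal matrix square root) symmetrises the pose. Under
   this package's pull-back convention the symmetrising half is the inverse
   square root; both signs are evaluated and the refinement is skipped if
   neither improves r.
4. **Disambiguation.** Principal axes leave four 180°-related candidates
   (RAS, LAI, LPS, RPI — all proper rotations). Each is rigidly registered
   to a correctly oriented reference and the candidate with the highest r
   wins; if all four scores agree within 0.01 the object has no usable
   AP/IS asymmetry and an error is raised.

All stage transforms are composed and the subject is resampled **once**
(cubic interpolation; nearest for masks/labels), onto the reference grid.
The stages run on a half-resolution working copy when the grid is large
(minimum dimension > 64): transforms live in world coordinates, so the
working resolution only affects the precision of intermediate decisions,
and a final registration polish (initialised at the composed transform)
restores sub-voxel accuracy. The built-in rigid/affine registration is a
Powell-style direction-set search over normalised mutual information
(32-bin joint histogram) or Pearson correlation, multi-resolution, with
intensity-centroid pre-alignment; it replaces the external registration
tool a production deployment would use, and is accurate to well under a
degree on phantoms at these scales.

## Intensity standardisation

Group-wise averaging is intensity-driven, so images must agree about what
"grey matter bright" means. The pipeline uses the classic piecewise-linear
landmark scheme: 11 histogram landmarks at percentiles
{1, 10, 20, ..., 90, 99} are computed within a mask (the dilated brain mask
when available, otherwise a rough foreground mask — background and
out-of-field fill must not dominate the percentiles), each profile is
mapped affinely so (pc1, pc99) land on (0, 1), the per-landmark mean across
the cohort defines the standard scale, and every image is mapped
piecewise-linearly between its own landmarks and the standard ones, with
linear extrapolation beyond pc1/pc99 (clamping would destroy rank order in
the tails). The map is monotone, affine-invariant, and idempotent on the
standard scale to numerical precision.

## Tissue segmentation

Five classes are modelled: GM, WM, external CSF, ventricular CSF and
background, each with a single Gaussian intensity model.

* **Rim modelling.** The brain mask is dilated by 10 voxels and a
  prior-free (flat-prior) EM classifies the rim into BG/WM/GM/eCSF by
  intensity rank. This keeps skull, meninges and other extra-cranial
  material out of the brain classes and prevents the classic
  cortical-surface artifact where partial-volume GM is labelled WM.
* **Subject-specific priors.** Registered atlas label maps vote per voxel;
  a tissue-class table maps structure labels to classes (ventricular
  structures to vCSF, mixed structures contributing 50% GM / 50% WM; the
  pituitary is excluded). Atlas databases are doubled by mid-sagittal
  mirroring with left/right name swapping. The eCSF prior comes from the
  rim posteriors; BG fills the remainder.
* **Ventricle refit.** Ex vivo ventricles largely collapse, so the atlas
  vCSF prior mostly covers tissue. A 3-class prior-free EM inside the vCSF
  support reassigns it among GM/WM/vCSF; classes are identified by
  intensity rank (CSF darkest). If the fitted means stay within a few
  within-class standard deviations of each other the support is judged
  homogeneous fluid and the prior is kept (EM would otherwise split pure
  noise into pseudo-classes). Supports under 30 voxels are skipped.
* **EM-MRF.** The main stage is EM with a mean-field Potts Markov random
  field over the 6-neighbourhood (coupling 0.25) and per-iteration prior
  relaxation: from iteration 2, prior <- 0.75 prior + 0.25 G(posterior)
  with a Gaussian kernel of SD 0.5 mm, avoiding overt atlas bias. Defaults:
  convergence at relative log-likelihood change < 1e-5, cap 30 iterations,
  variance floored at 1e-6 of the data variance (phantoms can have
  noiseless regions). With coupling and relaxation at 0 the scheme reduces
  exactly to prior-weighted Gaussian-mixture EM, which the tests exploit
  as an independent oracle.

Volumes follow from the posteriors: class volume = voxel volume times the
summed class probability; TIV = GM + WM + eCSF + vCSF; BV = GM + WM. A
phantom-based gradient calibration factor can be applied to volume tables
on either the volumetric or the linear (cubed) scale.

## Group-wise registration and morphometry

The cohort is normalised into common coordinates by iteratively registering
every subject to the current average and re-averaging, with a schedule of
1 symmetric rigid, 9 symmetric affine (12 DOF) and 15 nonrigid rounds by
default; the initial target is drawn from the cohort by a seeded RNG. The
built-in nonrigid backend is a coarse cubic B-spline free-form deformation
(control-point spacing 5 voxels, bending-energy weight 0.005) optimised by
L-BFGS on intensity SSD with an analytic gradient — appropriate for
intensity-standardised images at phantom scale; the `register()` contract
is the seam where a production registration tool slots in. The average is
parcellated by a simplified locally-ranked label fusion: atlases are ranked
per voxel by local normalised cross-correlation in a Gaussian window
(default sigma 0.6 mm) and the top k (default 5) vote, weighted by
similarity, ties to the lowest label id. This is a deliberate
simplification of STAPLE-style fusion estimators, which are out of scope.

Per-subject deformations yield Jacobian-determinant maps by central finite
differences of x + u(x) in world mm (one-sided at boundaries). Regional
volumes are the voxel volume times the sum of J over each parcellation
region. Whether the affine determinant is composed into J (so overall size
differences appear in regional volumes) is a configuration switch,
defaulting to composed, which is what reproducing absolute regional volume
tables requires. For TBM the response is ln J smoothed with FWHM 0.16 mm
(4 voxels at 0.04 mm); for VBM tissue maps are propagated to the average
space (unmodulated), renormalised and smoothed the same way.

## Statistics

At every voxel inside the brain mask an ordinary least-squares GLM is
fitted:

Y = b1 P(mut) + b2 P(WT) + b3 Age + b4 Cohort + b5 TIV + e

with TIV omitted for VBM. Age and TIV are mean-centred (interpretable group
coefficients; contrast t values unchanged). The genotype contrast
(1, -1, 0, ...) gives a two-tailed t with n - rank(X) degrees of freedom;
signed maps follow the usual convention (positive: mutant larger).
Significance is controlled by Benjamini-Hochberg FDR at q = 0.05 — note
that BH *licenses* up to a fraction q of false discoveries, so even a
perfectly localised effect is expected to come with a few scattered
significant voxels outside the true region. Tissue and regional volume
tables are tested with Welch t-tests (the groups' variances differ
noticeably in practice), absolute and TIV-normalised, Bonferroni-corrected
across measures. No cluster-extent or random-field correction is applied:
inference is voxel-wise FDR only.

## The phantoms

Every stage is testable without external data through synthetic brains with
complete ground truth: a grey-matter shell around a white-matter core, two
dorsal ventricles sized to a requested volume fraction (default 2%), an
anterior bulb and an antero-posterior taper (AP asymmetry), a flattened
ventral side (IS asymmetry, like a brain resting flat), an external CSF gap
and a skull shell, mirror-symmetric about the mid-sagittal plane, with the
AP semi-axis strictly longest. Images add Gaussian noise scaled to a
requested SNR (default 15, matching a multi-subject acquisition; Rician
noise is an option, but high-SNR magnitude MRI is near-Gaussian and the
segmentation model is Gaussian), and optionally a smooth multiplicative
bias field (sum of low-order random polynomials; default off, since bias
correction is delegated to an external tool through a hook that only fixes
the 5-voxel dilated correction mask). The default single-brain grid is
96 x 128 x 96 at 0.04 mm isotropic — a miniature brain, adequate for
orientation and segmentation testing. Multi-subject scenes instead use
realistically sized brains (about 3.3x the miniature, ~500 mm cubed of
brain+skull) at 0.18 mm voxels: hull accuracy is governed by the ratio of
the smoothing skirt (a fixed width in mm) to the object's volume-to-surface
ratio, so subject separation must be exercised at realistic object scale.
The holder is modelled as barely-visible plastic walls (MR-dark), and the
identification markers as short bright agarose rods.

Group analyses are driven by a cohort generator that produces analytic
Jacobian maps on a shared 64 cubed grid: mutants receive a uniform
volumetric expansion inside a spherical region with a thin cosine ramp just
inside its boundary (so the true effect support is exactly the region), and
every subject receives a smooth log-normal Jacobian noise field (log SD
0.05, correlation length 0.12 mm) emulating registration imprecision, plus
per-subject ages, cohorts and TIVs (WT-like mean 469.5, SD 15.3 mm cubed;
an optional global mutant TIV excess exercises the TIV covariate). Using
analytic deformations decouples the statistics from the registration
backend and gives exact ground truth for power and null behaviour.

What the phantoms do **not** emulate: real neuroanatomy and its
between-subject variability, fixation shrinkage, susceptibility and
gradient distortions, intensity non-uniformity at realistic amplitude,
partial-volume mixing along curved boundaries, and the failure modes of
production nonrigid registration on real cortex. Green phantom suites
demonstrate that the algorithms are implemented correctly and behave as
designed under controlled conditions — not that the pipeline will reach the
same accuracy on real acquisitions.

## Numerical choices and known limitations

* Interpolation: cubic (Catmull-Rom) for images, trilinear inside
  optimisation loops, nearest for masks and labels; out-of-field value 0.
* Smoothing uses mirror padding (conserves the local mean near edges far
  better than zero padding); kernels are sampled Gaussians truncated at
  5 sigma; for sigma > 3 voxels a three-pass box filter gives an O(n)
  approximation (used by the 0.5 mm prior relaxation, where approximation
  error is immaterial).
* Dilation/erosion use the exact Euclidean distance transform, so the
  structuring element is a true discrete ball.
* Percentiles use linear interpolation between order statistics
  (type 7).
* The noise region for SNR/CNR is defined as background at least 10 voxels
  from every object (the source protocol does not state its noise ROI).
* Problem sizes in the test-suite: unit tests run miniature phantoms
  (32-64 voxels per axis); the acceptance-style suites run the full
  default phantom for orientation (100 random poses) and segmentation,
  20 multi-subject scenes for extraction, and 50 null cohorts plus a
  power cohort for the statistics, sizes chosen so the full suite runs in
  tens of minutes on a single core.
* A bright skull shell is kept out of GM/WM by the rim model but tends to
  be absorbed into the eCSF class, inflating eCSF/TIV on skull-bearing
  phantoms; with realistically dark bone this does not arise.
* The built-in FFD backend regularises with squared second differences of
  the control lattice (a discrete bending-energy approximation) and relies
  on intensity gradients: displacement inside large homogeneous regions is
  determined only by the regulariser (the aperture problem), which is why
  regional-volume recovery is assessed on intensity-bounded regions.
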