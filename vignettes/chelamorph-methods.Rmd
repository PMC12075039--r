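---
title: "Methods: claw shape, sensillation and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claw shape, sensillation and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`chelamorph` analyses heterochely (major- vs minor-claw divergence) and
sexual dimorphism in decapod chelae from two kinds of digitised data:
2-D landmark configurations of the propodus and micrometre coordinates
of sensillar articulation sockets.  This vignette records the models,
the numerical choices, and what the synthetic-data generator does and
does not emulate.

## Superimposition

Shapes are compared after generalised Procrustes analysis.  Each
configuration is centred, scaled to unit centroid size, and rotated by
the closed-form least-squares proper rotation onto the running
consensus; the consensus is the coordinate-wise mean, re-normalised
for the next rotation target.  Iteration stops when the consensus RMS
change falls below 1e-10 (cap 200 iterations; the `converged` flag is
returned either way).  Three choices deserve note:

* **No reflection during alignment.**  Minor claws are digitised in
  their anatomical (mirrored) orientation; `reflect_y()` is applied
  explicitly before joint analysis, so the rotation solver never needs
  an improper rotation.  In the rank-degenerate case the sign
  ambiguity of the SVD is broken toward the identity rotation.
* **Unit-size aligned shapes.**  All shape statistics operate on
  unit-centroid-size coordinates; size is analysed separately via
  centroid size.  No per-configuration scale re-optimisation is done
  after normalisation, so every aligned slice keeps centroid size 1
  exactly (this is the invariant the tests check).
* **Deterministic gauge.**  A GPA solution is unique only up to a
  global rotation.  The final solution is rotated so the consensus'
  principal axis lies along x (sign fixed by the largest-|x| landmark),
  making output independent of input order.
* **Missing landmarks.**  Scans with any missing landmark are excluded
  before alignment, with their ids reported — no imputation, the
  conservative choice for incomplete configurations.

The full Procrustes distance between two shapes is computed on unit
preshapes with the optimal non-negative scale, giving
`d = sin(rho) <= 1`, symmetric and zero exactly for
similarity-equivalent shapes.

## Group inference

CVA operates on principal-component scores of the aligned coordinates:
aligned 2-D shapes of k landmarks span at most `2k - 4` dimensions, so
components with eigenvalues below 1e-12 of the largest are dropped, and
at most `N - g` are kept so the pooled within-group covariance is
invertible (an error names the retained dimensionality if it is still
singular).  Mahalanobis distances use the pooled within-group
covariance; Pillai's trace is `tr(H (H + E)^{-1})`; Goodall's F is the
ratio of between- to within-group full-Procrustes variation with
degrees of freedom `(g - 1) m` and `(N - g) m`, `m = 2k - 4`.

Permutation p-values use the `(b + 1) / (n_perm + 1)` convention
(never zero), default 10,000 permutations, with a Monte-Carlo standard
error reported.  When a `crab_id` column is present and the tested
factor is constant within crabs, whole crabs exchange labels — the
exchangeability unit respects the two-scans-per-animal structure.  A
factor that varies within crabs (claw type) permutes at scan level.

The Procrustes ANOVA decomposes the aligned coordinates sequentially
(claw type, sex, individual), testing fixed effects against the
individual mean square and the individual against the
digitising-replicate residual; requesting the individual stratum
without replicated digitisations is an error.  Degrees of freedom
follow the Goodall convention (effect df × m).  Workflows built on
repeated (e.g. triple) digitisation differ in how they count error df;
this package reports its own convention with the df alongside every F
so any discrepancy with other software is inspectable.

## Sensillar sites and densities

Articulation points within one setal diameter (default threshold
20 µm, strict inequality) of one another belong to one site;
single-linkage connected components implement this, so chains merge.
Component size maps to type: S1 (1), S2 (2), S3 (3), S4 (>= 4; exact
socket counts inside clusters are not resolvable from 2-D micrographs
and are treated as an unordered class).  The output is deterministic
under input permutation (members sorted by coordinate, sites by
centroid).

Two investment measures are computed per scan: absolute density
(sites / chelar area, mm^-2) and the area-weighted density — each
type's count multiplied by its mean site area divided by the mean S1
area, summed, divided by chelar area — a coverage measure.  The
denominator defaults to the total chelar area (including the
dactylus), with propodus-only available for consistency with the
landmark analysis.  Mean site areas are taken from annotations when
present, otherwise from a buffered convex hull of the member points
(default articulation radius 10 µm); they are pooled per claw type
across the dataset by default (stabilising weights for scans with few
sites of a type) with a per-scan option; no single measurement rule
is standard, so both modes exist and the pooled one is the default.

## Frequency maps

Each complete scan is registered to a 5162 × 2947 px reference frame
by a least-squares similarity transform from its landmarks to the
frame-registered consensus (minor claws reflected first, together with
their consensus target).  The registration method is an assumption:
micrograph-alignment workflows rarely document their geometry, and
similarity is the minimal choice consistent with standardising
alignment and size; affine registration was considered and left out
because the input is digitised coordinates, where shear has no
plausible source.  One marker is rasterised per grouped
site (radius 0 for conservation checks, 6 px for visible dot maps at
full resolution); per-scan binary rasters are summed into frequency
maps, tinted composites (S1 magenta, S2 cyan, S3 lime, S4 gold) and a
sequential dark-to-bright heat rendering.  Outputs are plain-text
PGM/PPM so they are byte-stable and portable; a downscale factor
(default 8 in the pipeline) keeps desk-scale memory modest.

## Mixed models

Outcomes (log chelar area, log absolute and weighted density, type
proportions) are modelled with crab-level random intercepts, REML
estimation via lme4, and marginal per-term F tests with Satterthwaite
denominator df computed in this package: the variance-parameter
covariance is twice the inverse finite-difference Hessian of the REML
deviance in (theta, sigma), and each contrast's df is
`2 (L'VL)^2 / Var(L'VL)` by the delta method.  Factors use sum-to-zero
contrasts so tests are marginal (type III); the balanced-design df
closed forms are recovered in the tests.  Chelar area is modelled
against log mass; densities and proportions against untransformed
mass, the conventional choices for these outcome families.  Proportions are
modelled on the raw scale with identity link (as the source analysis
implies); a logit option can be had by transforming the column first.
Natural logs throughout; zero densities are dropped from log-scale
models with a logged count (no zero-handling rule is stated in the
source).  Model reduction starts from all two-way interactions and
removes the largest-p non-protected interaction above alpha, one per
refit — deterministic, conventional backward elimination — with
`sex:claw_type` protected as the key hypothesis term.  A
collection-site covariate can be added by the user but is off by
default.

## The synthetic world

`sim_params()` defaults state the emulated design; they are fixed,
not tuned:

| parameter | default | rationale |
|---|---|---|
| crabs | 34 F / 42 M | the emulated sample size |
| mass | truncated normal 0.508 ± 0.257 g on [0.015, 1.088] | stated moments and range |
| MNC scan retention | 56/76 | minor-claw moults are fragile |
| missing landmarks | 0.5% per landmark | emulates 76→70 / 56→54 scan exclusions |
| area allometry | log area = 1.63 + 0.67·log mass (+claw, +sex×claw) | isometric-ish slope (2/3), MJC ≈ 3.2 mm² at 0.5 g |
| density | 16 sites/mm² at 0.5 g, mass slope −0.5 | declining density with size, realistic counts (30–60 sites/claw) |
| density variance | crab 0.031, residual 0.0446 (log scale) | back-solved from the reported crab-level variance and ICC 0.41 |
| female-MJC multiplier | 1.2 | a modest real effect; tests inject 1.0 (null) and 1.5 (recovery) explicitly |
| type mixes | MJC 0.66/0.20/0.04/0.10, MNC 0.45/0.25/0.12/0.18 | S1-dominant major claw, richer S3/S4 on the minor claw |
| site areas | 120/220/330/520 µm², CV 15% | strictly increasing S1→S4 |
| spatial fields | kernel mixtures anchored at landmarks | S1 proximal, S2 marginal, S3 distal joint, S4 tips |

Site members are jittered within ~7 µm of their site centre so the
20 µm grouping rule recovers the generated structure; counts are
Poisson with mean density × area (the simplest count-noise model
consistent with density analyses).  Site placement uses a padded
convex hull of the template landmarks as the claw surface.

What the generator does **not** emulate: digitising bias, correlated
landmark error, non-Gaussian shape variation, spatial interaction
between sites (inhibition/clustering beyond the intensity fields), and
measurement error in chelar areas.  A green test therefore establishes
that the *pipeline* recovers what it is supposed to recover from data
with the stated first- and second-order structure — not that the
biological conclusions of any particular study are correct.

Type-I calibration (sex-by-claw LMEM term and the CVA permutation
test within 3.5–6.5% over 400 null seeds) and parameter recovery (the
1.5× female-major-claw density multiplier within 10%, power > 80% at
40 crabs/sex over 200 seeds) run at full size in the acceptance test
file; module-level simulation examples run scaled down (15–25 seeds,
widened bands) to keep the routine suite fast.

## Known limitations

* No sliding semilandmarks, 3-D alignment, or partial Procrustes.
* The CVA permutation engine recomputes the statistic on fixed
  principal-component scores; the projection itself is label-free, so
  this is exact, but axes are not re-estimated per permutation.
* Satterthwaite df rely on finite-difference derivatives of the REML
  criterion; at variance boundaries (group variance → 0) the Hessian
  is pseudo-inverted and df become approximate.
* Raster registration assumes similarity geometry; real montage
  distortions (local warping) are out of scope because the input is
  coordinates, not pixels.
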