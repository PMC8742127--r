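---
title: "Methods: simulating and calibrating SP-DRI capillary diameter measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and calibrating SP-DRI capillary diameter measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Shifted position-diffuse reflectance imaging (SP-DRI) estimates the diameter
of skin capillary loops from diffusely reflected light. Two reflectance
images are acquired with the light source shifted by a small lateral offset;
after translating one image so that the source positions coincide, the
pixel-wise ratio cancels the common illumination field and leaves the
relative shift of subsurface absorbing structures — the capillaries — as a
localized modulation. A cross-section through the smoothed ratio image shows
one maximum-then-minimum excursion per capillary; the area K_norm enclosed
by that excursion grows linearly with the capillary diameter, so each tissue
(one set of optical properties) is summarized by the line

K_norm = beta0 + beta1 * diameter,

and an observed K_norm converts to an absolute diameter through the
inversion diameter = (K_norm − beta0) / beta1. The calibration parameters
beta0 and beta1, however, depend on the tissue's optical properties, which
differ across individuals. This package implements the full in-silico study
of that dependence: photon-transport simulation of the imaging process under
randomly perturbed optical properties, extraction of K_norm, reduction to
(beta0, beta1), machine-learning attribution of their variation to specific
optical properties, analytic calibration surfaces, and the resulting
calibration-free diameter-prediction error.

# Tissue model

`buildTissueVolume()` voxelizes a seven-layer skin stack (stratum corneum,
epidermis, papillary dermis, upper blood net dermis, reticular dermis, deep
blood net dermis, subcutaneous tissue; the last layer is trimmed to the
volume depth) with blood-filled structures: six capillary loops, each
modeled as two vertical cylindrical limbs spanning depths 150–300 um, and a
superficial vascular plexus of two horizontal legs (30 um diameter, axis at
300 um) to which the loops connect. The full-scale volume is
950 x 950 x 2000 voxels at 1 um. A voxel belongs to a vessel when its center
lies inside the cylinder; voxel i spans [i, i+1) um so a 30 um vessel is
exactly 30 voxels wide. Labeling is idempotent and order-independent for
disjoint vessels; loops whose limbs would intersect another loop are a
geometry error, while loop–plexus contact is anatomy, not an error (plexus
labels are applied last).

The capillary diameter (4–14 um in 2 um steps across simulation runs) is the
quantity the method ultimately measures.

## Optical properties

Each of the eight media (seven layers plus blood) carries an absorption
coefficient mu_a (mm^-1), scattering coefficient mu_s (mm^-1), scattering
anisotropy g, and refractive index n; analyses use the reduced scattering
mu_s' = mu_s (1 − g). The illumination wavelength is 424 nm, an
oxyhaemoglobin absorption peak, which is what makes the capillaries visible:
blood absorbs some two orders of magnitude more strongly than the
surrounding dermis there.

No authoritative per-layer table at 424 nm ships with the package. The
defaults in `defaultMediaProperties()` are literature-style placeholders,
chosen once with two constraints: short-wavelength skin optics (scattering
and absorption well above red/NIR values; blood mu_a = 300 mm^-1 at
15 g/dl), and reduced scattering of the two outermost layers (3.6 and
5.4 mm^-1) inside the range over which the reference calibration surfaces
below actually vary. Every algorithm takes the media table as data; nothing
is hard-coded.

## Inter-individual variation

`samplePropertySet()` perturbs every optical-property element independently
with a Gaussian of standard deviation 30% of the base value for mu_a and
mu_s and 3% for g and n; each element receives its own deviation. Draws
violating physical bounds (negative coefficients, |g| >= 1, n < 1) are
rejection-resampled, which preserves the Gaussian shape away from the
bounds rather than piling mass at them (clipping would). The 24-predictor
reduction (mu_a, mu_s', n per medium, medium-major order) is the feature
vector used downstream. The study design draws 236 such property sets and
simulates 6 diameters x 2 source positions each: 2832 runs
(`enumerateRuns(experimentPlan())`).

# Photon transport engine

`simulatePhotons()` is a voxel Monte-Carlo engine written in C++:

* **Launch.** Packets start on the −z face, uniform over the 20 um fiber
  core, directions uniform in solid angle within the emission cone
  (NA 0.35). The air–tissue interface is a stochastic Fresnel event:
  reflected packets exit specularly (and reach the detector at normal
  incidence), transmitted packets refract by Snell's law.
* **Propagation.** Free paths are sampled from the local scattering
  coefficient (dimensionless optical depth consumed segment-wise across
  voxels), deflection angles from the Henyey–Greenstein phase function with
  the local g. Voxel faces where n changes trigger unpolarized Fresnel
  reflection or Snell refraction, including total internal reflection.
  Absorption never terminates a packet: the weight decays continuously as
  exp(−mu_a l) per segment while per-medium pathlengths are accumulated.
* **Termination.** Packets below 1% of the launch weight play russian
  roulette: survival probability 1/m with weight multiplied by m (m = 10, a
  standard choice; only the 1% threshold is prescribed). The detection face
  applies Fresnel refraction into the external medium (n = 1 by default,
  configurable) and accepts packets within the detector cone
  (asin(NA/n_ext), NA 0.25 at full scale), evaluated on the refracted
  direction. Lateral and deep faces are open — escaping packets are tallied,
  not reflected — emulating laterally and in-depth semi-infinite tissue; a
  `sideBoundary = "mirror"` option exists but costs about 4x runtime for a
  marginal gain at desk scale.
* **Rendering.** Because per-medium pathlengths L_m are stored, diffuse
  reflectance images are produced in post-processing: each packet
  contributes rouletteFactor * exp(−sum mu_a,m L_m) at its exit pixel, and
  arbitrary absorption maps can be re-applied to one detected photon set
  without re-running the transport (`renderReflectance()`).

Identical seeds give bit-identical photon streams. Each packet owns a
counter-based RNG substream (splitmix64 over disjoint Weyl-offset
counters), so two runs with the same seed are photon-wise paired: a
geometry change perturbs only the packets whose paths meet changed voxels,
which is what makes common random numbers effective (below). Degenerate inputs behave sensibly: zero scattering and matched indices
give purely ballistic transmission; a zero-diameter fiber is a point source;
with mu_a = 0 the tallies conserve the launched weight exactly because
roulette never triggers.

The engine's correctness is tested against closed forms (normal-incidence
Fresnel reflectance of an n = 1.4 half-space; Beer-law rendering equal to
the in-flight weight to 1e-9) and against an independent, analytically
traced (voxel-free) R implementation of the same physics on a homogeneous
box.

# The SP-DRI signal chain

`computeSPDRI()` registers the image pair by the source shift
((0, 110) px at full scale), divides pixel by pixel, and smooths with a 2-D
Gaussian kernel (sigma 10 px at full scale). `extractProfile()` takes the
cross-section at x = 570 px (the reference column; configurable — a figure
caption in the source literature also mentions 610 px) and applies a
Savitzky–Golay filter (order 5, frame 151 px), after linear interpolation
over masked gaps. `computeKnorm()` locates, per capillary position, the
local maximum preceding and the local minimum following it within a search
window (half the inter-capillary spacing per side; nearest extremum wins)
and integrates the area between the curve and the horizontal level of the
minimum from the maximum to the minimum by the trapezoid rule.

Choices worth stating explicitly:

* **K_norm integrand.** The quantity is defined in prior literature as the
  area enclosed by the curve between the maximum and the subsequent minimum.
  We fix the enclosing chord as the horizontal line through the minimum.
  This makes K_norm invariant under adding a constant, exactly linear in
  the modulation amplitude, and equal to h*w/2 for a triangular bump of
  height h and half-width w — the closed forms the implementation is tested
  against.
* **Extremum detection.** Plateaus (exact ties, which arise in synthetic
  fixtures) are collapsed to their midpoint; a plateau reaching the profile
  boundary counts as the adjacent extremum type, true boundary points never
  do. A capillary entry is flagged missing — not an error — when either
  extremum is absent, when the enclosed area is non-positive, or when the
  max-to-min window touches unmeasured (masked) pixels.
* **Scaling.** For volumes smaller than full scale, the smoothing sigma and
  filter frame scale with the lateral extent (ratios 10/950 and 151/950,
  frame forced odd), keeping the processing comparable.
* **Sparse images.** The reference processing order (divide, then smooth)
  assumes every pixel holds many packets. At desk photon budgets most
  pixels hold zero or a few, and a per-pixel ratio is undefined or wildly
  biased. `computeSPDRI(method = "presmooth")` therefore smooths both
  registered images with the same Gaussian before dividing — identical in
  the high-count limit, well defined when sparse — and masks pixels whose
  smoothed support falls below a relative floor (`minSupport`, default
  1e-3 of the image maximum). The pipeline uses this variant; the
  reference order remains the default of the low-level function and is what
  the identity/reciprocity properties are tested on.

# Desk-scale preset

The full-scale study (10^10 packets per run, 2832 runs) is far beyond a
desktop. The desk preset (`deskGeometry()`, `studyConfig("desk")`) is the
package's scaled-down stand-in: 240 x 240 x 500 voxels, one plexus leg, two
capillary loops, 10^6 packets per run. Lateral coordinates scale by 240/950
and depths by 500/2000, with three deliberate departures, all sized a priori
from photon statistics rather than scaled blindly:

* The 30 um plexus and the 4–14 um capillaries keep their physical size
  (they are the measurand), so the cross-section column keeps its
  *absolute* 20 um offset from the loop axis — just outside the plexus
  stripe, as 570 px is to 550 px at full scale. Scaling that offset would
  park the section on top of the plexus shadow.
* The source sits 44 px from the loop axis instead of the scaled 81 px: the
  diffuse halo at 10^6 packets supports a measurable ratio only within
  roughly 60 um of the source. The source *shift* between the two positions
  keeps its scaled value (28 px), preserving the SP-DRI registration
  geometry.
* The desk detector integrates over all exit angles (NA = n_ext) rather
  than the 0.25 fiber NA, trading angular selectivity for about 6x more
  detected packets. The full-scale preset keeps NA 0.25.

Even so, a desk run carries on the order of tens of detected packets per
smoothing kernel at the cross-section, i.e. roughly 10–20% profile noise
against a capillary modulation of comparable scale. Two consequences:

* **Common random numbers.** The full-scale study draws an independent
  uniform seed per run, and the paper-scale plan keeps that contract. At
  desk budgets, independent seeds leave adjacent-diameter K_norm
  differences noise-dominated; the desk plan therefore reuses one seed per
  (property set, source position) across the diameter series
  (`experimentPlan(commonRandomNumbers = )`), so that the shared photon
  noise cancels in diameter-to-diameter comparisons — the standard
  variance-reduction design for paired Monte-Carlo comparisons.
* Desk-scale K_norm series remain noisy in absolute terms; the end-to-end
  check asks for a monotone trend, not precise values.

# Surrogate study generator

Monte-Carlo runs are too slow to drive the calibration and evaluation
machinery in tests, so `generateCalibrationDataset()` emulates the
*statistical* structure the downstream analysis assumes: per simulated
individual, a sampled property set; beta1 and beta0 computed from reference
calibration surfaces of the two outermost layers' reduced scattering (see
below) plus Gaussian noise; and one K_norm per diameter from the linear law
plus noise. What it deliberately does not emulate: spatial photon noise,
masking/missingness mechanisms, and any dependence of the betas on
predictors other than the two reduced-scattering values. Tests passing on
surrogate data therefore validate the calibration/evaluation machinery, not
the physics; the physics is validated by the engine tests and the
end-to-end desk run.

The reference surfaces have the form z = a1 exp(−b1 x1) + a2 exp(−b2 x2) + c
with coefficients (1.251, 0.3319, 1.046, 0.6513, 0.1389) for beta1 and
(−3.803, 0.4382, −2.356, 0.6406, −0.4093) for beta0, where x1 and x2 are
mu_s' of stratum corneum and epidermis in mm^-1. The beta-noise defaults
(0.116 and 0.249) were derived once: the empirical SD of the noise-free
surface response over 5000 sampled property sets at the default base media,
scaled by sqrt(1/R^2 − 1) with target fit qualities 0.8454 (beta1) and
0.9117 (beta0). They are tunable inputs, not claims about real tissue.

# Calibration analysis

* `fitKnormRegression()`: ordinary least squares of K_norm on diameter,
  skipping and counting missing entries; at least two points are required.
* `rankPredictors()`: a bagged regression-tree ensemble with all predictors
  available at every split (randomForest with mtry = 24); importance is the
  raw mean increase in out-of-bag squared error under per-predictor
  permutation. A constant response yields all-zero importances with a
  warning rather than an error.
* `tuneAndTrain()`: 5-fold cross-validated grid search over the aggregation
  method (bagging, or least-squares gradient boosting via xgboost), the
  boosting learning rate {0.05, 0.1, 0.35, 0.5} and minimum leaf size
  {1, 3, 5}; the winner is retrained on all data with 500 learning cycles.
  The grid brackets the reference optima (boosting at rate ~0.35 with leaf
  1 for beta1; bagging with leaf 3 for beta0) while staying deterministic
  given a seed; we do not replicate any Bayesian optimizer trajectory.
* `probeModelSurface()`: 200 equidistant query values per predictor inside
  the central 20–80% band of the observed min–max range (read as a range
  band, not quantiles; configurable), to keep range-edge outliers out of
  the surface fit.
* `fitAnalyticSurface()`: nonlinear least squares of the two-exponential
  form without interaction term (an interaction was tried in the source
  study and discarded). Multistart initialization: decay rates from
  {0.1, 0.5, 1} per axis; for each start the amplitudes and constant, which
  enter linearly, are solved exactly by least squares. Decay rates are
  bounded below at zero (decaying form); near-constant responses
  short-circuit to a1 = a2 = 0, c = mean(z). The best converged start by
  residual sum of squares wins; total non-convergence is an error carrying
  the best residual. On noise-free 20 x 20 grids of either reference
  surface the fit recovers all five coefficients to a relative 1e-3.

# Diameter prediction and its error

`runEvaluation()` repeats 30 times: split the property sets 80/20, train
beta0/beta1 ensembles on the training rows (hyperparameters are selected
once on the full data, as in the study design, not per repeat), and convert
each test row's six K_norm values to diameters through the inversion, with
betas supplied by (a) the ensemble directly, (b) an analytic surface fitted
to the probed ensemble response, or (c) fixed values from the ideal
unperturbed run. Predictions with non-positive predicted slope are excluded
and counted (`nInvalid`) — the inversion is undefined there.

`summarizeRecords()` reports mean, median, sample SD and CV = 100 SD/|mean|
per method and true diameter. Whether to pool predictions across repeats or
average per-repeat summaries is ambiguous in the source description
("averaged afterwards"); the default averages per-repeat summaries, and
`pool = TRUE` switches. The overall CV per method is the mean across
diameters. Two structural expectations — analytic CV decreasing with
diameter (a fixed absolute beta error against a growing signal) and the
fixed-value method being worst under property variation — are asserted on
surrogate data as trends; the printed full-scale error statistics themselves
depend on the 10^10-photon runs and are out of reach at desk scale.

# Reproducibility and orchestration

All randomness flows from explicit seeds. Per-run seeds derive from a
master seed by a counter-based integer hash into (0, 2^31), both limits
excluded, matching the stated seed contract of the study; the derivation is
exact in doubles and platform-stable. `runPipeline()` writes one JSON
manifest per simulation run (run id, seed, configuration fingerprint via a
32-bit FNV-1a hash of the serialized configuration); with `resume = TRUE`
completed runs are skipped and a manifest from a different configuration
aborts unless forced. Outputs are plain CSV (K_norm tables, betas,
summaries), YAML (configurations) and TIFF (label stacks, reflectance and
ratio images).

Problem sizes used in the shipped tests: engine oracles at 1e4–2e5 packets;
the end-to-end desk study at 1 property set x 6 diameters x 2 positions x
1e6 packets; surrogate suites at the full 236-row study size; predictor-
importance repetitions with 300-tree ensembles.

# Known limitations

* The absolute optical-property table at 424 nm is a placeholder; absolute
  reflectance levels and the absolute scale of K_norm are therefore not
  comparable to any specific measurement, only the method's structure is.
* Capillary loops are straight cylinder pairs; no curved loop apex, no
  appendages, no wavelength-dependent geometry.
* The desk preset trades angular selectivity and source–section distance
  for photon statistics, as described above; full-scale behavior
  (10^10 packets) is represented structurally, not numerically.
* Polarization, fluorescence and time-resolved detection are out of scope.
* The ensemble-probing analytic fit inherits any ensemble overfitting on
  small training sets; the direct-surface option exists for exactness
  checks.
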