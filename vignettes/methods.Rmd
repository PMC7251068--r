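---
title: "Modelling tau spread on brain connectomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tau spread on brain connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauspread)
```

## The scientific problem

Neurofibrillary tau tangles appear in a stereotyped anatomical order:
first in the entorhinal cortex, then the hippocampus and adjacent limbic
cortex, then association isocortex, and last in primary sensory areas —
the classical six-stage autopsy progression. One mechanistic explanation
is that pathological tau (or a pathological state that induces it)
propagates from neuron to neuron along axonal connections, seeding each
newly reached region in a cascade. `tauspread` implements the
computational machinery to test that hypothesis with regional tau-PET
data: a measurement model that converts SUVR values into tau-positive
probabilities, a network-diffusion model of spread over a connectome, and
the downstream statistics (epicenter search, connectome null models,
amyloid-residual coupling, hemispheric asymmetry, staging summaries,
cohort matching).

Because subject-level tau-PET datasets and template connectomes are
access-restricted, the package ships a first-class synthetic-data module
with known ground truth, so every stage of the pipeline can be validated
end to end.

## The spreading model

Let $\hat C$ be the row-normalized connectome (rows scaled to sum to 1
where nonzero), and $X_i(t) \in [0,1]$ the tau-positive probability of
region $i$. The epidemic spreading dynamics are

$$\frac{dX_i}{dt} \;=\; \beta\,(1 - X_i)\sum_j \hat C_{ij} X_j \;-\;
\delta\, X_i ,$$

with a seed $X = x_0$ on the epicenter region(s) at $t = 0$ and zero
elsewhere. Production is proportional to the connectivity-weighted burden
of a region's neighbours and to its remaining capacity $(1-X_i)$;
clearance is first order. The three subject-level parameters are the
production rate $\beta$ (1/year), the clearance rate $\delta$ (1/year),
and the effective duration $t_\mathrm{eff}$ (years, standing in for time
since onset). They control overall burden and velocity — the *regional
patterning* is controlled entirely by the connectome, which is what the
model fit evaluates. A balance $\beta \approx \delta$ produces little to
no spread; an excess of production drives the cascade outward.

Row normalization makes the neighbour term a weighted average in
$[0,1]$, so states provably remain in the unit interval (the vector field
points inward at both boundaries). Integration is explicit Euler with
post-step clamping; the default step is $dt = 0.01$ years and a guard
aborts if any single step moves a state by more than 0.5. Tests verify
agreement with an adaptive Runge–Kutta oracle (`deSolve::ode`) to
$10^{-3}$ on small systems and with the closed form
$x_0 e^{-\delta t}$ under zero coupling to $10^{-6}$.

### Fitting

Parameters are fit per subject by exhaustive grid search minimizing the
sum of squared errors between simulated and observed regional
probabilities. The default grid takes 20 log-spaced values in
$[0.01, 3]$ per year (plus 0) for both rates, durations
$5, 10, \dots, 50$ years, and a fixed seed amplitude $x_0 = 0.1$
(`esm_grid()`); a coarser grid (`esm_grid_coarse()`) is provided for
ensemble work such as null-model refits and epicenter searches, where
hundreds of fits are needed. Because candidate predictions do not depend
on the subject, `esm_fit()` integrates each parameter set once and
compares all subjects against the prediction matrix with a single
cross-product — fitting a 50-subject cohort takes well under a second at
the coarse grid.

Fit quality is the squared Pearson correlation ($r^2$) between predicted
and observed regional vectors: per subject (*individual* $r^2$) and
between the subject-mean vectors (*global* $r^2$). Squared correlation is
used deliberately — it measures pattern agreement, not calibration — and
perfect anticorrelation therefore also scores 1; that property is
documented and tested rather than hidden. A flat observed vector makes
the statistic undefined: such subjects are flagged, counted as 0 in the
fit object's own summary, and excluded (with a logged count) by
`summarize_fit()`.

## From SUVR to tau-positive probability

Tau-PET signal mixes target binding with off-target background. Per
region, one- and two-component Gaussian mixtures are fit across the
population by EM (`fit_region_mixture()`) and compared by AIC with
parameter counts 2 and 5; a strictly smaller two-component AIC declares
the region bimodal. The tau-positive probability of a subject is the
posterior probability of the upper (abnormal) component, evaluated
out-of-sample by repeated five-fold cross-validation
(`mixture_probability_transform()`): per repeat, subjects are shuffled
into folds, the mixture is refit on the training folds (warm-started
from the full-sample solution plus fresh restarts), the held-out fold is
scored, and scores are averaged over repeats (default 10). Bimodality is
decided on the full-sample fit.

Numerical choices: EM uses 10 restarts (a k-means split first, then
random two-point initializations), a variance floor of $10^{-6}$, and a
relative log-likelihood tolerance of $10^{-6}$ with at most 1000
iterations; zero-variance input and all-restart failure are explicit
errors. The fitted likelihood is checked in the tests against an
independent implementation (`mclust`).

Two properties of this procedure deserve honesty:

* **AIC is liberal for mixtures.** With a thorough EM, a pure Gaussian
  sample of $n = 500$ is called bimodal in roughly a fifth of draws
  (the two-component likelihood gain exceeds the AIC penalty of 3
  log-units that often). Weakly optimized fitters appear more
  "specific" only because they miss the two-component optimum. The
  package implements the thorough fitter and documents the measured
  operating characteristic; unimodal regions under the `full78` /
  `cortical66` region sets are transformed with a forced two-component
  fit and flagged, and only the `bimodal_only` region set drops them.
* **The upper-component mean is only estimable where abnormal subjects
  exist.** At $n = 500$, a 5% accuracy claim for the upper mean needs
  on the order of 55 abnormal draws (3-sigma argument with an effective
  component SD near 0.2), i.e. an abnormal prevalence of about 0.1.
  Validation therefore asserts the 5% recovery for regions at or above
  that prevalence.

Alternatives (`alternative_transform()`): per-region min-max scaling
(SUVR essentially as-is), and a reference-region bootstrap ECDF — the
null distribution of the maximum over 40,000 bootstrap resamples of the
trimmed (5th–95th percentile) reference values, applied as an empirical
CDF. Confound handling (`regress_confounds()`) precedes transformation:
either per-region OLS residualization on age, sex and mean
choroid-plexus signal (residuals re-centred on the regional grand mean
so mixture fitting stays on the SUVR scale; sex coded 0/1), or w-scores
against an amyloid-negative cognitively normal reference group.

## Connectome preparation and null models

`average_connectomes()` averages subject matrices into a template;
`threshold_and_scale()` keeps the strongest fraction of connections
(default 10%, ranked over the upper triangle with stable tie-breaking)
and rescales survivors into $(0, 1]$ by dividing by the maximum — the
scaling is chosen so the operation is idempotent, which pure min-max is
not (it would zero the weakest survivor each application).
`distance_similarity()` builds the extracellular-spread baseline:
pairwise centroid distances divided by the largest distance and
inverted, so coincident regions score 1 and the most distant pair 0.

Significance of a fit is assessed against degree- and
strength-preserving connectome null models (`generate_nulls()`):
Maslov–Sneppen rewiring of the binarized topology (10 swaps per edge,
via igraph) followed by re-assignment of the original weight multiset,
placing the largest remaining weight on the edge with the largest
product of residual expected strengths. Degree preservation is exact by
construction; strength preservation is approximate and logged (measured
correlations ≥ 0.99 on the synthetic template). The one-sided p-value
is the exceedance count over the number of nulls, floored at
$1/n_\mathrm{null}$ — with the conventional 100 nulls the smallest
attainable p is 0.01.

## The synthetic-data module

The generator is not a test fixture but the package's stand-in for the
restricted study data; its defaults are the study conditions every
validation runs under, chosen once during design:

* **Atlas** (`build_region_table()`): the Mindboggle-compliant DKT label
  set — 31 cortical labels per hemisphere plus bilateral hippocampus and
  amygdala (66 regions, 33 homotopic pairs), plus six deep subcortical
  structures per hemisphere for the 78-region set. Each cortical-set
  region carries an approximate six-stage ROI assignment (stage 1
  entorhinal, stage 2 hippocampus, remaining regions distributed 3–6 by
  the conventional scheme); the mapping is a single editable table in
  the source and is documented as approximate.
* **Geometry**: centroids are synthetic and mirrored across hemispheres.
  The longitudinal coordinate follows the staging axis (26 mm between
  stage bands, with primary cortex pushed 14 mm further out), with
  seeded jitter (SD 5/8/12 mm). This mimics the real geometric fact
  that tangle stage tracks distance from the medial temporal lobe, and
  the band separations are set so that between-stage differences in
  terminal probability exceed sampling noise at the validation cohort
  sizes. Only relative distances are meaningful.
* **Connectome** (`simulate_connectome()`): distance-kernel edge
  propensity (length scale 10 mm) times mirrored log-normal edge noise
  (SD 0.5 log-units), homotopic edges floored at 0.35 (a separate floor
  for limbic pairs), within-hemisphere medial-temporal circuit edges
  floored at 0.15 (entorhinal–hippocampus; half that for the remaining
  limbic pairs), thresholded to 10% density with the maximum spanning
  tree always retained so the graph stays connected. Two template
  regimes matter: the default (strong homotopic coupling everywhere)
  resembles a functional template, and under mirror symmetry its
  homotopic edges act as local self-reinforcement that sharpens the
  staging gradient; setting `limbic_homotopic_strength` near zero gives
  a tractography-like template whose sparse medial-temporal
  interhemispheric connectivity is what makes epicenter hemisphere
  identifiable — mirroring the empirical observation that hemisphere
  effects are resolvable on structural but not functional connectomes.
* **Cohort** (`simulate_cohort()`, `cohort_spec()`): 312 subjects by
  default with the demographic marginals of the combined discovery
  cohorts (162 CN / 89 MCI / 61 AD; age 71.7 (7.1); 53.1% women;
  education 14.6 (3.8); 51.7% APOE4; amyloid positivity 42.6 / 64.0 /
  100% by diagnosis). Clearance is log-normal
  ($\log\delta \sim N(\log 0.2, 0.2)$) and production is clearance
  times a log-normal ratio ($N(\log 2.4, 0.2)$, multiplied by 1 / 1.3 /
  1.6 for CN / MCI / AD); durations are uniform on 8–18 years. This
  correlated parameterization keeps subjects mid-course — neither
  saturated nor empty — which is what makes parameters and epicenters
  identifiable at all; independent rate draws produce many flat
  patterns that carry no information. Terminal probabilities come from
  the spreading model itself; amyloid-positive subjects receive an
  additive tau boost (default +0.15, clamped at 1) in nine bilateral
  amyloid-prone association regions, planting the signal the
  amyloid-residual analysis is designed to detect; truncated Gaussian
  observation noise (SD 0.05) is added.
* **Emission** (`suvr_emission()`): per cell, upper-component membership
  is Bernoulli in the tau probability and SUVR is drawn from
  $N(1.0, 0.10)$ or $N(1.6, 0.15)$ (small seeded per-region jitter on
  both means), then linear age / sex / choroid-plexus effects are
  added. The upper SD of 0.15 keeps the modes clearly overlapping while
  leaving the 5%-recovery validation honest margin at realistic
  prevalences.

What the generator does *not* emulate: realistic demographic covariance
beyond the stated marginals, voxel-level data, longitudinal trajectories,
directional (asymmetric-flow) spread, region-specific vulnerability
beyond the amyloid boost, and measurement artifacts other than additive
Gaussian noise and linear confounds. Passing tests therefore demonstrate
that the pipeline recovers what it is designed to recover under its own
generative assumptions — a necessary check, not evidence about real
tau-PET data.

## Validation design choices worth knowing

* **Recovery benchmarks switch the amyloid boost off.** The boost is a
  deliberate violation of pure connectivity spread; with it on, the
  systematic distortion in 18 regions dwarfs the tiny global-$r^2$ gap
  between the planted epicenter pair and its neighbours, and recovery
  is not a test of the estimator any more. Conversely the
  amyloid-residual analyses run with the boost on (power) and off
  (type-I error).
* **Type-I calibration of the residual–amyloid correlation uses an
  exchangeable null.** With the anatomically fixed bilateral
  amyloid-prone set, homotopic pairing halves the effective degrees of
  freedom and both maps carry persistent spatial structure, so the
  parametric p is inflated even with the coupling off — that scenario
  is simply not a draw from the test's null hypothesis. The calibration
  harness instead samples the amyloid-prone set uniformly over
  individual regions per simulation, under which the measured
  false-positive rate is ~2% at $\alpha = 0.05$.
* **Lateralization validation tolerates unclassifiable subjects.**
  Subjects with essentially zero burden, and subjects whose spread has
  saturated, carry no epicenter information in principle; left-seeded
  cohorts are therefore validated as: left-limbic is the modal class,
  contralateral misclassifications are (near-)absent, and the
  laterality index (mean left minus right across cortical regions) is
  significantly positive — not as a literal 100% classification rate.
* **Problem sizes.** Validation runs use 20 cohorts of 50 subjects for
  recovery, 500-subject cohorts for mixture recovery and staging, 20–100
  nulls per significance run, 50 runs for null calibration, and 200
  simulations for the statistical-calibration checks, with the coarse
  parameter grid for ensemble refits. These sizes give the binomial
  margins the assertions need while keeping a full validation run in
  the tens of minutes.

## Statistical conventions

Welch's two-sided t-test for the amyloid class comparison; Pearson
correlation with its parametric p; OLS for all GLMs;
Benjamini–Hochberg FDR across regions at q < 0.05 (via `p.adjust`);
greedy nearest-neighbour matching without replacement on jointly
z-scored features under Euclidean distance, processed in reference
order. The epicenter-class "other" label covers any best-fitting
epicenter outside the limbic list (entorhinal, hippocampus, amygdala,
parahippocampal), either hemisphere. Per-region asymmetry GLMs model
tau on epicenter hemisphere among limbic-classified subjects, adjusting
for disease status, age and sex, with the homotopic pairing recorded in
the atlas table.

## Known limitations

The spreading equation is this package's own binding definition of the
epidemic spreading model; published implementations of the same model
family differ in functional form, onset parameterization and seed
amplitude, and numerical disagreement with them is expected. The grid
search trades resolution for robustness: rates are recovered up to grid
spacing, and the production/clearance *ratio* is considerably better
identified than either rate alone (duration trades off against both).
Mixture-based bimodality calls inherit AIC's liberality (above).
Epicenter discrimination between spatially adjacent candidate pairs is
fundamentally limited by how similar their spread patterns are; the
synthetic connectome is built so that distinct pairs are identifiable
at the validation cohort size, and that should not be over-read as a
claim about every real connectome.
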