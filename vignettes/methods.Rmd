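---
title: "Mechanics-informed posturography: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics-informed posturography: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swayshift)
```

# The problem

Parkinson's disease impairs postural control in ways that standard clinical
scales often miss. A force plate measures the ground reaction force and
moment vector at high rate during quiet standing and gait initiation, and
the centre of pressure (COP) derived from them summarises how a subject
regulates balance. `swayshift` implements a complete assessment chain on
such recordings: COP derivation and filtering, extraction of
mechanics-informed features, forward feature selection with nested
cross-validation, a from-scratch t-SNE embedding with k-means clustering
and validity indices, and effect quantification with Cohen's d, classical
tests, and exact Shapley attribution. Because clinical force-plate
recordings are rarely shareable, the package also contains a seeded
synthetic cohort generator with known group structure; every statistical
property of the pipeline is tested against that generator or against
closed-form oracles.

# The synthetic cohort generator

## Standing sway model

Quiet-stance COP sway is modelled per axis as a mean-reverting
(Ornstein-Uhlenbeck) diffusion, discretised by Euler-Maruyama:

$$ c_{t+1} = c_t + \theta(\mu - c_t)\,\Delta t + \sigma\sqrt{\Delta t}\,\varepsilon_t $$

with mean-reversion rate $\theta$ (1/s), diffusion scale $\sigma$
(mm/$\sqrt{s}$) and equilibrium position $\mu$ (mm). The model was chosen
for its closed-form stationary moments — the stationary SD is
$\sigma/\sqrt{2\theta}$ — which make the generator itself testable: the
test suite simulates 300 s of sway and checks the sampled RMS against the
closed form within 10%. Paths are initialised at a stationary draw, so
there is no burn-in transient. This is a phenomenological model of the
COP *statistics*, not a biomechanical model of the body: it reproduces
amplitude, variability and smoothness of sway, but not the inverted-pendulum
dynamics, tremor spectra, or long-range correlation structure of real
recordings. Passing tests therefore certify the pipeline's behaviour under
controlled group contrasts, not clinical performance.

## Channel reconstruction

Channels are reconstructed from the latent COP so that downstream recovery
is exact by construction: $F_z$ is body weight with 0.5% multiplicative
sensor noise, and the moments satisfy the plate identity $M_x = y\,F_z$,
$M_y = -x\,F_z$ (COP in metres, moments about the plate surface). The
horizontal shear channels are mechanically coupled to the sway through
Newton's second law: the centre of mass is approximated by the 1 Hz
low-passed COP and $F_x = m\,\ddot{x}_{COM}$ plus 2 N sensor noise. This
coupling matters for the channel-SD analyses: on a real plate every channel's
variability reflects the subject's sway, and a generator with constant-SD
shear channels would make half of the channel-SD feature block pure sensor
noise — which column standardisation then amplifies to unit variance,
burying the group signal. The free moment $M_z$ is left as pure sensor
noise (0.5 N m), deliberately retaining one uninformative channel.

## Gait-initiation template

The gait-initiation trial holds the baseline COP for `cue_time` (default
3 s), then executes a single-step anticipatory postural adjustment (APA):
a half-cosine lateral excursion towards the swing limb of amplitude
`apa_ml_amplitude` (with a simultaneous posterior shift) over the loading
phase, followed by a half-cosine reversal towards the stance side during
unloading. Half-cosine segments are the simplest smooth shape with
unambiguous phase boundaries; the analytic boundary times (onset, lateral
extremum, baseline recrossing) are stored as ground truth in the trial
metadata, which is what the segmentation tests score against.

## Group presets and calibration

The `"study"` preset encodes the intended clinical contrasts: patients sway
with larger mediolateral amplitude ($\sigma_{ML}$ 8 vs 1) and larger
anterior-posterior drift ($\sigma_{AP}$ 5 vs 1.2), and produce a smaller
lateral APA (18 mm vs 30 mm, a 0.6 ratio). Magnitudes are calibrated to the
effect-size regime reported for cohorts of this kind — healthy-vs-patient
Cohen's $|d|$ in the huge range (about 4 and beyond) for the discriminating
sway features — rather than to population-typical contrasts, which are
smaller. Two inequalities fix the remaining free constants:

* between-subject variability (`subject_cv`, lognormal CV 0.2 on sway and
  APA parameters) must exceed the within-trial sampling variability of the
  features (about 13% CV for a 30 s trial at $\theta = 1$/s), otherwise the
  pre- and post-session points of one subject would not pair in the
  embedding, and
* the group log-contrast must exceed that subject variability by a wide
  margin, otherwise lognormal tails produce ambiguous subjects and the
  two-cluster diagnosis cannot be error-free.

Body mass (derived from sampled BMI and height) multiplies six of the eight
channel-SD features and acts as a realistic anthropometric confound; the
calibrated sway contrast dominates it, as it must for the channel-SD
diagnosis to work at all.

The intervention is modelled as a convex shift of each intervention-group
subject's parameters towards the healthy preset,
$p_{post} = (1-\lambda)p_{pre} + \lambda p_{healthy}$ with $\lambda = 0.6$,
leaving the control group's parameters untouched between sessions.

The `"signal_recovery"` preset supports planted-signal experiments: group
signal lives in the sway diffusion scales only (read through mediolateral
RMS and anterior-posterior path length), with gait and demographics matched
across groups. Because RMS and path length on one axis both scale with
$\sigma$, the same-axis aliases of the planted pair necessarily carry the
signal too; recovery experiments therefore exclude those aliases from their
candidate sets and plant the signal against genuinely uninformative
candidates (noise-channel SDs, demographics).

# Preprocessing

COP is derived as $x = (-M_y - F_x z_0)/F_z$, $y = (M_x - F_y z_0)/F_z$
(in mm; $z_0$ is the height of the plate surface over the moment reference,
0 by default), with samples below a 50 N vertical-load threshold masked
invalid. Standing trials are trimmed by 2 s at each end; gait trials keep
from 1 s before the cue onwards. Filtering is a zero-phase (forward-
backward) 4th-order Butterworth low-pass at 10 Hz — standard posturography
practice; cutoff, order, trims, threshold and $z_0$ are all arguments.
The filter wrapper demeans, pads by odd reflection, filters both ways and
restores the mean, so DC is preserved exactly and edge transients stay
below the stated tolerances; tests verify the passband (< 1% at
$f/f_c = 0.05$) and stopband (> 99% attenuation at $f/f_c = 5$) against the
squared analytic magnitude response.

# Features

From standing trials: per-axis and planar path length $\sum|\Delta c|$,
RMS and variance of the demeaned COP (demeaning makes
$\mathrm{var} = \mathrm{RMS}^2$ hold exactly and removes dependence on
stance position), mean sway velocity (path length over duration), and sway
area as the 95% prediction-ellipse area
$\pi\,\chi^2_{2,0.95}\sqrt{\det\Sigma}$. From gait-initiation trials, after
segmentation: net displacement magnitude and mean velocity per phase and
axis; the headline feature is the loading-phase mediolateral displacement
(the APA amplitude). Net displacement was preferred over path length within
phases because it reads directly as APA amplitude; path-based variants can
be built from the standing-feature functions if needed. A third block holds
the sample SD of every raw channel and both COP axes.

Gait segmentation: onset is the first post-cue time where the planar
deviation from the pre-cue baseline mean exceeds 3 baseline SDs sustained
for 50 ms; the loading phase ends at the mediolateral extremum in the
swing direction (the maximum of the oriented excursion before its first
baseline recrossing — robust to filter ripple); unloading ends at that
recrossing. The swing direction is auto-detected from the first substantial
excursion rather than the global extremum, because the reversal towards the
stance side is longer-lived than the APA peak. Monte-Carlo tests against
the generator's truth boundaries require 50 ms accuracy in at least 90% of
noisy trials.

Feature tables are assembled one row per subject-session with block
provenance retained, sex coded numerically (M = 0, F = 1), and are
z-scored jointly over all rows entering an analysis (pre and post sessions
together), since the embedding places them in a single space.

# Selection, validation, explanation

Forward feature selection greedily adds the candidate that maximises inner
cross-validated accuracy of a wrapper classifier — an L2-penalised logistic
regression (ridge strength 1, fitted by IRLS, which stays defined under the
perfect separation that n = 18 cohorts readily produce) or k-nearest
neighbours (k = 5). The inner criterion averages 8 repeated stratified
3-fold assignments: a single 3-fold split at n = 18 is fold-noise dominated
and repetition is the standard small-cohort remedy. Ties break by column
order and are logged. The default target size is 3. Note that the greedy
score trace is only guaranteed non-decreasing while genuinely useful
features remain: once a feature subset saturates the criterion, forcing
further additions can lower the cross-validated estimate.

`select_feature_vector()` runs both wrappers and merges their selections
(ranked by how many wrappers chose a feature, then by selection step),
mirroring reporting that attributes each selected feature to the model(s)
that chose it.

Nested cross-validation re-runs selection inside each outer
leave-one-subject-out fold, so sessions of one subject never straddle the
train/test split. Bootstrap CIs are percentile intervals over
case-resampled evaluations of a fitted model, and the permutation test uses
the add-one estimator $p = (1 + \#\{M_{perm} \ge M_{obs}\})/(B+1)$.
Calibration is verified empirically: type-I error within [0.03, 0.07] at
$\alpha = 0.05$ over 400 null replicates (B = 200), and 93–97% coverage of
a known population accuracy (an evaluation set of 400 points scored by a
rule trained on independent data, so the population accuracy has a closed
form under the Gaussian generative model).

McFadden's pseudo-$R^2$ is $1 - \ell_{model}/\ell_{null}$ from a
maximum-likelihood logistic fit; under quasi-separation the unpenalised
likelihood is unbounded and the value is computed from a lightly ridged fit
and flagged.

Exact Shapley attribution enumerates all $2^d$ coalitions ($d \le 12$) with
the interventional value function (absent features marginalised over a
background sample — the analysis table itself by default); additivity is
asserted at $10^{-9}$ and the implementation is tested against a
permutation-average oracle. One caveat worth knowing: for a model that is
linear in its inputs the interventional Shapley value reduces to
$\phi_i = w_i(x_i - \bar{z}_i)$ regardless of the coalition structure, so
attribution for redundant features hinges entirely on how the fit shares
weight between them.

# Embedding and clustering

The t-SNE implementation follows the standard construction: per-point
Gaussian bandwidths found by bisection so the conditional distribution's
perplexity (the exponential of its Shannon entropy) matches the target to
$10^{-3}$; conditionals symmetrised to the joint $P$; Student-t kernel in
the embedding space; gradient descent on $\mathrm{KL}(P\|Q)$ with momentum
0.5 switching to 0.8 at iteration 250, early exaggeration 4 for the first
100 of 1000 iterations, and adaptive per-coordinate gains. The learning
rate defaults to $\max(n/12, 10)$, sized for cohorts of tens of points. An
alternative joint-normalisation affinity (a single global normalisation of
per-point Gaussian kernels, then symmetrisation) is selectable via
`affinity = "joint"`; the conditional-symmetrised form is the default. The
KL trace is recorded against the un-exaggerated $P$, is clamped at zero
against roundoff, and the returned embedding is the best iterate.

K-means is Lloyd's algorithm from k-means++ initialisations, best of
`n_init = 10` restarts; emptied clusters are re-seeded from the farthest
point. The elbow curve reports best-of-restarts WCSS per k with an advisory
knee at the maximum discrete second difference — recipes use fixed k values
rather than automatic selection, since elbow reading is a judgment call.
Validity indices (mean silhouette with singletons scored 0,
Davies-Bouldin, Calinski-Harabasz) follow their textbook definitions and
are tested to $10^{-12}$ against double-loop oracles. "Unseen data"
validation is out-of-bag bootstrap: fit k-means in-bag, assign out-of-bag
points to nearest centroids, compute indices on the out-of-bag points,
percentile CIs over replicates. DBSCAN (defaults eps = 0.687,
min_samples = 2) is provided for robustness comparisons and runs on the
embedding, like k-means.

# Analysis recipes

`run_recipe()` wires the chain for four seeded, reproducible analyses:

| recipe | rows | features | perplexity | k |
|---|---|---|---|---|
| intervention | PD pre+post | selected triple | 2 | 3, 5 |
| convergence | all subjects | selected triple | 3 | 2, 3, 4 |
| diagnosis | pre + healthy | channel SDs | 3 | 2 |
| baseline | PD pre | selected triple | 1 | 2 |

The selected triple defaults to mediolateral standing RMS,
anterior-posterior standing path length, and loading-phase lateral gait
displacement; `selection = "ffs"` re-derives it by forward selection of
PD-vs-healthy membership on pre-intervention rows. Bundles carry the
feature table, embedding, per-k clusterings, indices (with optional
bootstrap CIs), per-cluster descriptives, pre-to-post transition tables,
Cohen's d contrasts (intervention pre vs post per group, healthy vs
post-intervention), Shapley summaries, and a manifest (seeds, parameters,
config hash, package version); `report()` renders a markdown summary.
Cohen's d uses the pooled-SD definition with first-minus-second sign
convention and extended magnitude labels (negligible < 0.2 < small < 0.5 <
medium < 0.8 < large < 1.2 < very large < 2 < huge on $|d|$). Classical
tests are Welch's t (which reproduces the reference cohort's printed BMI
p-values from its raw rows, the package's reason for adopting it),
equal-variance one-way ANOVA, and tie-corrected Kruskal-Wallis.

# Problem sizes in the test suite

The shipped tests and the acceptance script scale simulations to keep runs
brisk while leaving every contrast far above its decision threshold: trial
simulations inside Monte-Carlo suites run at 100–250 Hz sampling (the
generator's statistics are rate-robust for the band-limited signals
involved; a dedicated test checks feature agreement within 2% between
1000 Hz and 500 Hz), cohort properties use 12–25 seeded cohorts of
6 + 6 + 6 subjects, calibration suites use 400–500 replicates at B = 200,
and the long-run stationarity check uses a single 300 s trial. These sizes
are the package's own choices and are stated here so they can be scaled up
when more precision is wanted.

# Known limitations

* The sway model has no tremor peak, no postural drift beyond mean
  reversion, and no inter-axis coupling; group contrasts are calibrated to
  the huge-effect regime of the motivating application, which is larger
  than typical population contrasts.
* Perplexity values of 1–3 on 12–30 points make t-SNE layouts sensitive to
  the seed; recipes pin seeds and report the KL trace, but embedding
  coordinates are exploratory, not metric.
* Exact Shapley is limited to 12 features by enumeration; no sampling
  approximation is provided.
* The permutation and bootstrap machinery assumes exchangeable rows within
  the blocking structure it is given; it does not model serial dependence
  within trials (features are per-trial summaries, so this matters only if
  multiple trials per session were added).
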