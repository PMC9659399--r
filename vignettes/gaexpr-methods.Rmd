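---
title: "Models and methods behind gaexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gaexpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaexpr)
```

`gaexpr` simulates interactive-genetic-algorithm (GA) experiments in which
observers evolve facial expressions of emotion, and implements the
statistics defined on the evolved expressions. This vignette documents the
model, every tunable parameter with its default and rationale, the
numerical choices, and the limits of what the synthetic data can show.

## Expression space

An expression lives in a 149-dimensional blendshape rig; 46 *core units*
move independently and drive the rest through a nonnegative coupling map
(`core_map`). All weights are fractions of maximal activation in [0, 1].
The true rig coupling of any particular avatar is production data we do
not ship; the default map partitions the 149 rig dimensions into 46
contiguous blocks, each driven identically by its core unit, which
preserves the 46-independent / 149-rendered structure without inventing
facial anatomy. A measured rig loads through `read_core_map()`, and every
analysis accepts it.

Dissimilarity is cosine distance, `CD(a, b) = 1 − cos(a, b)`. On
nonnegative weights CD lies in [0, 1], is zero exactly for positively
collinear patterns, and ignores overall intensity — appropriate because
observers judge the *configuration* of a face, not its global strength.
All-zero vectors are rejected rather than silently mapped to 0 or NaN. By
default distances are computed on the 46 core units (the space the GA
actually searches); computing them on the expanded rig would count each
core unit once per coupled rig dimension, i.e. weight units by their
block sizes. PCA, in contrast, defaults to the rendered 149-dimensional
space, since the category-structure analyses describe the expressions as
displayed; a `representation` argument switches either choice.

## The evolution loop

One session is one initialization trial plus `n_generations = 10` evolved
trials of `population_size = 10` candidates — the final trial asks for a
single choice, the *preferred expression*. Initialization draws sparse
random faces: each unit active with probability 0.3, active magnitudes
Uniform(0, 1). Breeding is:

1. **Elitism** — the observer's flagged best match survives unchanged.
   Without it the best-match flag would not influence evolution at all;
   it also guarantees monotone convergence under a noiseless observer.
2. **Uniform crossover** — two parents drawn uniformly with replacement
   from the selected set; each offspring unit comes from either parent
   with probability 1/2. A single selection degenerates to mutate-clone.
3. **Gaussian mutation** — each unit perturbed with probability
   `mutation_prob = 1` by N(0, `mutation_sd` = 0.1), then clipped to
   [0, 1].

The mutation default deserves explanation. With sparse per-unit mutation
(e.g. probability 0.15) the spuriously active units inherited from
initialization decay too slowly within a 10-generation budget, leaving an
algorithmic noise floor — the mean pairwise CD among expressions evolved
toward the *same* target — of roughly 0.5, as large as realistic
between-individual differences. That regime contradicts the phenomenon the
toolkit exists to study: between-participant variability must be
measurable *above* algorithm noise. Perturbing every unit every breeding
(an evolution-strategy-style operator) exploits clipping at zero as a
ratchet that strips spurious units, and brings the floor to ≈ 0.25 CD
while leaving convergence speed intact. Both parameters stay exposed in
`ga_config()`.

## Observer models and synthetic cohorts

A simulated observer holds a latent target expression and scores each
candidate as `−CD(candidate, target) + N(0, decision_noise_sd)`. The
default selection rule is top-k with k = 3 of 10 (a distance-threshold
rule is available), and `decision_noise_sd = 0.05` — noticeable relative
to late-session score spreads, so selections stay imperfect the way human
choices are.

`generate_cohort()` emulates a study dataset: N participants × 4 emotions,
one preferred expression each. Each participant's latent target is the
emotion's *category mean* plus per-unit Gaussian jitter
(`between_subject_sd = 0.15`, clipped), and each cell runs a full GA
session under a seed derived from the cohort seed and the cell label, so
datasets are reproducible and order-insensitive. The shipped category
means are hand-authored prototypes whose top five active units carry the
action units the FACS literature associates with each emotion (happy:
AU 12, 13, 6, 7, 1; fear: 5, 1, 2, 20, 4; angry: 4, 10, 11, 9, 16; sad:
15, 11, 17, 20, 7), with deliberate overlap — fear/sad share AU20,
angry/sad share AU11 — so synthetic cohorts reproduce the qualitative
confusion structure of human data (happy most distinct, fear/sad most
confusable). They are a fixture file (`extdata/category_means.csv`), not
a claim about any real population.

## GA stochastic-noise thresholds and exceedance

`simulate_noise()` evolves `n_iter` independent sessions toward one fixed
target and takes the **mean** of the pairwise-CD distribution among the
finals as the noise threshold (a percentile option exists but is
non-default, "mean of the simulation" being the literal reading).
`ga_noise_thresholds()` uses the cohort's own per-emotion centroids as
targets — the "average" expressions — and reports per-emotion and pooled
exceedance: the fraction of observed between-participant CDs strictly
above their emotion's threshold.

The null observer is deterministic (`decision_noise_sd = 0`): the
threshold is meant to capture noise *of the algorithm*, not of the
selector. Note one subtlety we verified empirically: the centroid of many
evolved expressions is denser (more small nonzero units) than any
generating prototype, so for cohorts generated *without* between-subject
dispersion the centroid-targeted null is not an exactly matched process;
passing the true generating means via `targets=` restores the matched
construction (pooled exceedance ≈ 0.5). At the package defaults
(`between_subject_sd = 0.15`) pooled exceedance runs ≈ 95–99%: individual
differences dominate algorithm noise, the regime the method is built for.

## Convergence and the plateau rule

`convergence_profile()` tracks, per generation, the mean pairwise CD
among the candidates the observer selected. The plateau is the first
generation after which every later change of that dispersion stays below
5% *of the session's initialization-trial dispersion*. Normalising by the
series' scale rather than by its current value is deliberate: at the
converged floor the dispersion is small and its proportional wobble under
mutation noise never settles below any strict ratio criterion, which
would push every plateau to the last generation and make the statistic
vacuous. Flat-at-a-floor is precisely what "the variance of the selected
faces became constant" means. The final single-choice trial contributes a
dispersion of exactly 0 by construction; it is flagged and excluded from
the rule. Under the defaults the median plateau over 100 sessions lands
at trial 6–7, matching the rapid convergence the interactive procedure is
known for (`scripts/acceptance.R` recomputes this from scratch).

## Category statistics

- **PCA** (`run_pca`): centered, unscaled — all dimensions share the same
  unit, and correlation-mode scaling would inflate near-constant units; a
  `scale.` flag exists. Rank deficiency returns as many informative
  components as the data support, flagged.
- **Gaussian mixture** (`fit_gmm_confusion`): k = 4 full-covariance
  components on the first 10 PC scores, fit with `mclust` (model "VVV").
  On top of mclust's deterministic model-based hierarchical
  initialisation we run 9 further EM starts from hierarchical
  initialisations on random half subsets and keep the best
  log-likelihood; with ~100–300 points in 10 dimensions the default
  initialisation alone is often a poor local optimum. Singular
  covariances trigger a conjugate prior (regularization), flagged with a
  warning. Clusters map to emotions by the bijection maximising the total
  diagonal count over all 4! assignments — a majority vote can collapse
  two labels onto one cluster, and the confusable fear/sad pair makes
  that failure mode real.
- **Fingerprints** (`fingerprint`): per-unit mean and SD across
  participants; the SD convention is population SD (divide by n), since
  the summary describes the cohort itself rather than estimating a
  superpopulation; `sd_type = "sample"` switches. `mean_sd` × 100 is the
  "% of maximal activation" variability figure.
- **SVM** (`svm_category_cv`): linear kernel, cost 1, stratified 5-fold
  cross-validation (folds reduce, with a warning, when a class is
  smaller). Linear is the conservative default in a 46-dimensional space
  with tens of observations per class.

## Recognition analysis and the permutation null

`simulate_recognition()` has every perceiver label every stimulus; the
response model scores the four emotions by distance between the stimulus
and the perceiver's *own* preferred expressions and samples through a
softmax (`temperature = 0.1`; 0 = deterministic nearest-preferred, ∞ =
guessing). `bin_by_cd()` bins each perceiver's trials by the CD between
the stimulus and the perceiver's same-category preferred expression into
equal-count quantile bins (rank-based, stable tie-break by trial order),
collapsed across emotions, then pools across perceivers. Quantile bins
guarantee occupancy where fixed edges need not; a fixed-edge option
exists. Because bins depend on ranks only, any monotone transform of the
distances leaves the analysis unchanged.

The permutation test swaps *whole* 4-emotion preferred-expression sets
across perceivers (uniform random permutations of perceiver identity) and
recomputes the binned performance; responses stay fixed, so total trials
and overall accuracy are invariant and only the stimulus–perceiver match
is destroyed. P-values carry the add-one correction. The highest-CD bin
is tested one-sided in the lower tail — the effect of interest is a
performance *drop* for stimuli far from one's own preferred expression —
and the other bins two-sided, counting permuted values at least as far
from the null centre as the observed one (the `2·min(lower, upper)` form
is markedly conservative for discrete proportion statistics and fails
uniformity checks at realistic trial counts). Under an exchangeable null
the per-bin p-values are uniform once bins hold on the order of 10²
trials; at much smaller sizes the proportion statistic is too discrete
and p-values are conservative, which is a property of permutation tests
on coarse statistics, not of this implementation.

## Problem sizes and reproducibility

All defaults are desk-scale choices that keep the full stack fast while
staying in the regime the statistics need: cohorts of 24–84 participants
(96–336 expressions), 100 noise-simulation iterations, 1000 permutations
in the pipeline default (the study-scale figures — 500 iterations, 10,000
permutations — remain the CLI defaults for `noise-sim` and `permtest`).
Every stochastic stage derives its seed from a global seed plus a stable
stage label (FNV-1a hash), so adding a stage never perturbs another
stage's stream, and pipeline outputs embed the configuration hash and
seed.

## What the synthetic cohorts do not show

The observer model is target-plus-noise: it has no semantics, no
conceptual knowledge of emotions, no attention lapses, no learning across
trials, and its latent targets are Gaussian perturbations of four fixed
prototypes rather than the heavy-tailed, multimodal dispersion real
populations may exhibit. Passing tests therefore validate the *machinery*
— the evolution operators, the noise-floor logic, the clustering and
permutation inference — under known ground truth; they do not establish
how human preferred expressions are distributed, and quantities estimated
here (confusion rates, exceedance percentages, variability levels) should
be read as properties of the simulated conditions, not predictions for
any human dataset. Rendering, image-based analyses and external stimulus
databases are out of scope.
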