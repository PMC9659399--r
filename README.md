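# gaexpr

Genetic-algorithm evolution and analysis of facial-expression blendshape
vectors, with simulated observers in place of human participants.

## The problem

In interactive evolution experiments, a participant repeatedly picks, from
small sets of candidate avatar faces, the ones that best depict a target
emotion (happy, fear, angry, sad); a genetic algorithm breeds the next set
from those picks, and within about ten generations the process converges on
the participant's *preferred expression* — their idea of what that emotion
looks like on a face. Preferred expressions differ substantially between
people, and those differences in turn predict how well a person recognises
emotional expressions made by others.

`gaexpr` re-implements this whole measurement-and-analysis stack offline.
Human participants are replaced by parameterized *observer models* (a
latent target expression, a selection rule, decision noise), so every
statistic the approach defines can be computed, tested and calibrated on
synthetic cohorts with known ground truth. The package is aimed at
researchers in computational psychophysics who want to prototype, power, or
sanity-check GA-based expression-evolution studies before running them on
people.

## The expression space and its statistics

An expression is a vector of **blendshape weights**: 149 rig dimensions, of
which 46 **core units** can move independently; each weight is a fraction
of maximal activation in [0, 1] and maps onto FACS action units (AU12 = lip
corner puller, and so on). Dissimilarity between expressions *a* and *b* is
the **cosine distance**

    CD(a, b) = 1 − (a · b) / (‖a‖ ‖b‖)  ∈ [0, 1],

which compares activation patterns irrespective of overall intensity.

On top of the GA engine (10 candidates per generation, uniform crossover,
Gaussian mutation with clipping, elitism) the package implements:

- **GA stochastic-noise thresholds** — evolve many independent sessions
  toward one fixed target; the mean of the pairwise CDs among the resulting
  expressions is the variability attributable to the algorithm itself. The
  **exceedance fraction** is the share of observed between-participant CDs
  above that floor.
- **Category structure** — PCA of the cohort, a 4-component full-covariance
  Gaussian mixture on the first 10 PC scores, cluster-to-emotion matching
  by optimal bijection, and the resulting confusion matrix.
- **Fingerprints** — per-emotion mean and SD of each core unit across
  participants, ranked and labelled with FACS names and AU numbers.
- **SVM category prediction** — stratified cross-validated classification
  of the targeted emotion from the evolved weights alone.
- **CD-binned recognition analysis** — simulated forced-choice labelling of
  other participants' expressions, binned by the distance between each
  stimulus and the perceiver's own same-category preferred expression, with
  a permutation null that swaps whole preferred-expression sets across
  perceivers (the test for a genuinely *personal* contribution beyond the
  category's central tendency).

## Worked example

```r
library(gaexpr)

cohort <- generate_cohort(cohort_spec(n_participants = 24, seed = 1))
noise  <- ga_noise_thresholds(cohort, n_iter = 100, seed = 2)
noise$report
#> exceedance of between-participant CDs over GA noise thresholds:
#>  emotion n_pairs threshold exceedance
#>    happy     276    0.2406      98.9%
#>     fear     276    0.2449      97.5%
#>    angry     276    0.2408      96.7%
#>      sad     276    0.2460      95.7%
#> pooled: 97.2%
```

Nearly all between-participant differences exceed what the algorithm's own
randomness can produce: the synthetic individual differences are real
signal, not GA noise. Clustering recovers the category structure
imperfectly — by design, the shipped category prototypes overlap the way
human categories do (fear and sad share action units):

```r
pca <- run_pca(cohort, n_components = 10)
gmm <- fit_gmm_confusion(pca$scores, cohort$emotion, seed = 3)
gmm
#> Gaussian-mixture confusion matrix (rows = true emotion):
#>        assigned
#> true    happy  fear angry   sad
#>   happy 0.792 0.042 0.000 0.167
#>   fear  0.417 0.500 0.042 0.042
#>   angry 0.417 0.000 0.583 0.000
#>   sad   0.333 0.000 0.083 0.583
#> mean diagonal = 0.615

fingerprint(cohort, "happy")
#> happy fingerprint (n = 24): mean weight SD = 23.4% of full activation
#>   top activated units:
#>     AU12  lip corner puller            mean = 0.76
#>     AU13  sharp lip puller             mean = 0.69
#>     AU6   cheek raiser                 mean = 0.57
#>     ...
```

The recognition experiment shows the signature effect: accuracy collapses
in the bin of stimuli most dissimilar from the perceiver's own preferred
expression, and the permutation test confirms the drop is personal, not a
central-tendency artefact:

```r
perceivers <- generate_cohort(cohort_spec(n_participants = 8, seed = 4))
rec  <- simulate_recognition(cohort, perceivers, seed = 5)
perm <- permutation_test(rec, n_perm = 1000, seed = 6)
perm
#> permutation test of CD-binned recognition performance (1000 permutations):
#>  bin observed null_mean null_lo null_hi p_value     sided
#>    1   0.6198    0.4608  0.4113  0.5312  0.0010 two-sided
#>    2   0.3958    0.4159  0.3490  0.4792  0.5794 two-sided
#>    3   0.3958    0.4072  0.3490  0.4635  0.7453 two-sided
#>    4   0.2135    0.3412  0.2760  0.3958  0.0010     lower
```

A command-line front end covering every stage
(`simulate-session`, `generate-cohort`, `noise-sim`, `cluster`,
`fingerprints`, `recognition-sim`, `permtest`, `run-all`) is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "gaexpr.R", package = "gaexpr"))')" run-all --seed 1 --out results/
```

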