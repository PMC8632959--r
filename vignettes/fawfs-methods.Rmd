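---
title: "FAW-FS: hybrid filter–wrapper feature selection for EEG phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FAW-FS: hybrid filter–wrapper feature selection for EEG phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The method

`fawfs` implements a two-stage feature-selection procedure for labeled tabular
data, together with the EEG front end it was designed for and the clinical
outcome statistics used alongside it in depression-intervention studies.

## Filter stage

Each feature is scored twice against the binary class label:

* **ANOVA F-score.** With groups $i = 1,\dots,k$ of sizes $n_i$
  ($N = \sum n_i$), the total sum of squares about the grand mean decomposes
  into between-group and within-group parts, $TV = BGV + WGV$, with mean
  squares $MSG = BGV/(k-1)$ and $MSW = WGV/(N-k)$ and $F = MSG/MSW$. When a
  feature separates the classes perfectly ($WGV = 0$, $BGV > 0$) we assign
  $F = +\infty$ so it ranks first; a feature with identical group means scores
  0. `anova_decompose()` exposes the full decomposition, and a property suite
  checks the identity $TV = BGV + WGV$ and agreement with
  `stats::oneway.test(var.equal = TRUE)` on random draws.
* **Mutual information.** The discrete plug-in estimator
  $I(X;Y) = \sum p(x,y)\log_2 \frac{p(x,y)}{p(x)p(y)}$ (bits, $0\log 0 = 0$).
  Continuous features are discretized into `mi_bins` equal-width bins (default
  10) and reduced to the discrete case. Binning is crude but monotone-ordering
  is all the filter needs; no density estimator is implied by the definition,
  so we use the simplest consistent one.

The filter selects the **union** of the top-`k_anova` features by F and the
top-`k_mi` features by MI (`filter_union()`). Whether the source procedure
thresholds scores or takes fixed-size sets is not documented; we use top-$k$
sets because they give a deterministic, size-bounded union
($\max(k_a,k_m) \le |U| \le k_a+k_m$). Defaults are
$k = \lceil p/2 \rceil$ each; ties break by ascending feature index so runs
are reproducible.

## Wrapper stage

Within the union, a genetic algorithm over boolean feature masks
(`run_ga()`):

1. random initial population (each bit Bernoulli(½), empty masks repaired);
2. fitness evaluation (below), with a cache keyed by the mask bits;
3. tournament selection of size 3 (the selection operator is otherwise
   unspecified; tournaments are scale-free and elitism-friendly);
4. single-point crossover with probability `crossover_prob`;
5. per-bit mutation with probability `mutation_prob`;
6. **annealing-guided local search**: `local_search_iters` single-bit-flip
   proposals per individual, each accepted by the Metropolis rule on energies
   $e = 1 - \mathrm{Fit}$ — a better-or-equal candidate is always accepted, a
   worse one with probability $\exp(-E\,\Delta/T)$;
7. elitism (`elitism` best individuals survive unchanged), then geometric
   cooling $T_g = T_0\,\gamma^g$.

The search stops at the generation budget or after `patience` generations
without improvement.

**Fitness** is the rectified excess of cross-validated accuracy over a
baseline $D$:
$\mathrm{Fit} = f(x) - D$ if $f(x) > D$, else $0$, with $D$ defaulting to the
majority-class rate — a subset scores only if it beats the trivial classifier.
Two design choices deserve emphasis:

* **Acceptance-rule orientation.** The published form of the annealing rule
  is ambiguous about which of the two energies is the incumbent and uses a
  maximization-flavoured fitness next to a minimization-flavoured rule. We
  resolve it by minimizing $e = 1-\mathrm{Fit}$ and accepting ties, which
  makes "accept with probability 1" coincide with "the candidate is at least
  as accurate". The Monte-Carlo acceptance test pins the worse-move
  probability to $\exp(-E\Delta/T)$ within binomial error.
* **Repeated-CV fitness** (`fitness_repeats`, default 3). With a single
  fixed split the search can overfit fold noise: masks padded with
  uninformative features can score above the truly informative subset on one
  split while losing on fresh splits. Averaging a few independent stratified
  splits removes most of that bias at proportional cost. The fitness is still
  a mean cross-validated accuracy.
* **KNN as the default fitness classifier.** Nearest-neighbour accuracy
  degrades steadily as irrelevant dimensions are added, so it supplies a
  usable search gradient even when the classification problem itself is easy;
  linear or margin-based fits saturate near the Bayes rate on separable data
  and leave the fitness surface flat in the noise bits. Any of the five
  classifier families can be substituted.

### Default hyperparameters

| parameter | default | note |
|---|---|---|
| `population_size` | 30 | masks per generation |
| `n_generations` | 50 | hard budget |
| `local_search_iters` | 10 | bit-flip proposals per individual |
| `crossover_prob` | 0.8 | per mating pair |
| `mutation_prob` | 0.02 | per bit |
| `initial_temperature` | 1.0 | energy units of $1-\mathrm{Fit}$ |
| `cooling_rate` | 0.95 | geometric |
| `energy_scale` | 1.0 | multiplier $E$ |
| `elitism` | 1 | carried over unchanged |
| `fitness_repeats` | 3 | stratified 5-fold splits averaged |
| `patience` | 10 | stall generations before stopping |

The source procedure names these parameter kinds without values; the values
above are conventional GA practice, fixed once and recorded in every run's
provenance metadata.

## Evaluation protocol

`cross_validate()` implements the five-subset protocol: stratified fold
assignment (per-class round-robin after a seeded shuffle), training on four
subsets, validation on the fifth, rotated until every subset has served as
the verification set. Features are standardized on each training fold and the
training statistics applied to its validation fold, so no information leaks.
Classifier defaults: unpenalized logistic regression, `rpart` decision tree,
KNN with $k=5$, RBF-kernel SVM with $C=1$, random forest with 100 trees —
conventional settings, configurable per call.

# EEG front end

## Preprocessing

* **Down-sampling** (`eeg_downsample()`): integer decimation only (the
  1000 Hz → 250 Hz regime), preceded by a zero-phase 4th-order Butterworth
  low-pass at 80 % of the target Nyquist. Arbitrary resampling ratios are out
  of scope.
* **Band-pass** (`eeg_bandpass()`): 4th-order Butterworth, 0.5–50 Hz by
  default, applied forward–backward (`signal::filtfilt`) so the pass band is
  phase-neutral. No filter family or band edges are documented for the source
  chain; these are standard EEG practice and configurable.
* **EOG removal** (`remove_eog()`): the named ingredients are a Kalman filter
  and a wavelet transform, with no state model, wavelet family, or order of
  operations documented. Our chain is: (i) a per-channel local-level
  (random-walk) Kalman smoother — equivalent to a Whittaker smoother with
  $\lambda = \sigma^2_{obs}/\sigma^2_{proc}$ — tracks the slow high-amplitude
  blink trajectory, which is subtracted; (ii) the residual is decomposed with
  a periodic Daubechies-4 transform (level 5), the approximation-band
  coefficients are soft-thresholded at the universal threshold
  $\hat\sigma\sqrt{2\log n}$ ($\hat\sigma$ from the MAD of the finest detail
  band), and the surviving coefficient mass — the remaining artifact
  estimate — is reconstructed and subtracted. On artifact-free input both
  artifact estimates are essentially zero, so the recording passes through
  with a relative RMS change of a few percent. The default variance ratio
  $10^{-4}$ makes the smoother track components up to a few Hz at 250 Hz
  sampling — the blink band, below the alpha rhythms the features feed on.

## Features

`extract_features()` returns exactly 12 named features per channel-epoch.
The fixed size is part of the published design; its composition is not, so
the package defines a stable, documented set: power-spectrum entropy, binary
Shannon entropy of the median-binarized epoch, correlation dimension, K2
entropy, C0 complexity, total periodogram power, five relative band powers
(δ 0.5–4, θ 4–8, α 8–13, β 13–30, γ 30–45 Hz), and the spectral peak
frequency.

Numerical choices:

* **Correlation dimension** (Grassberger–Procaccia): the $r \to 0$ limit is
  replaced by the least-squares slope of $\ln C(r)$ vs $\ln r$ over 16
  log-spaced radii between the 5th and 50th percentile of pairwise distances;
  pairs closer than the Theiler window in time are excluded. The fast
  implementation is tested against a naive $O(n^2)$ pairwise oracle to 1e-9.
* **K2 entropy**: the published limit form has undefined increments; the only
  well-posed estimator consistent with its description is the correlation
  entropy $K_2 = \langle \ln(C_m(r)/C_{m+1}(r))\rangle_r / \tau$ from
  correlation integrals at consecutive embedding dimensions, which is what we
  implement.
* **Embedding defaults**: $m = 5$, $\tau$ = first zero-crossing of the
  autocorrelation (fallback 1), Theiler window $=\tau$.
* **C0 complexity**: DFT coefficients whose squared magnitude exceeds the
  mean squared magnitude are retained, the inverse transform gives the
  regular part $Y$, and $C_0 = \sum|X-Y|^2 / \sum|X|^2 \in [0,1]$. Under
  Gaussian white noise the periodogram ordinates are exponential, and the
  expected below-mean energy fraction is $1 - 2/e \approx 0.264$ — the test
  suite asserts around this derived null rather than a larger round number.
* **Binarization** for the Shannon feature: threshold at the epoch median
  (the mapping from EEG to a probability is otherwise unspecified).
* Degenerate inputs (constant or all-zero epochs) raise errors naming the
  feature rather than returning NaN.

# Synthetic data: what it emulates and what it does not

The three generators define the study conditions for every test:

* `simulate_classification()` — Gaussian features with a class-conditional
  mean shift of `effect_size` standard deviations applied to class 1 on
  `n_informative` planted columns; everything else is class-independent
  noise. Shapes mirror the public-dataset suite used for benchmarking
  (90–1040 samples, 7–60 features, 2 classes). Ground truth is returned as
  metadata, never embedded in the matrix.
* `simulate_eeg()` — sums of sinusoids plus Gaussian noise at 1000 Hz (or any
  rate), with blinks planted as raised-cosine pulses of 300 ms at 5× the
  clean-signal SD, placed without overlap; the clean reference and blink
  metadata are returned alongside. The artifact shape is our choice — the
  source material shows blink contamination but never characterizes it.
* `simulate_cohort()` — two equal groups, pre/post scores per instrument with
  a planted mean post-score reduction difference (`intervention_effect`);
  scores are clamped to each instrument's admissible range. Default baselines
  (SAS/SDS 62, HAMD 25, GQOLI-74 55) put simulated patients in the moderate
  band of each scale.

Passing tests on these fixtures show that the pipeline recovers *planted
linear mean-shift structure*, removes *stereotyped transient artifacts*, and
scores *Gaussian pre/post cohorts* correctly. Real EEG is nonstationary,
spatially correlated and artifact-rich in ways these generators do not
attempt (muscle, line noise, electrode drift), and real rating-scale data are
discrete and skewed — results here do not certify performance on clinical
recordings.

# Clinical statistics

Severity bands follow the instruments' conventions (SAS/SDS: <50 none, 50–59
mild, 60–69 moderate, ≥70 severe; HAMD: <8 none, 8–20 mild, 20–35
mild-to-moderate, >35 severe). The published HAMD bands overlap at their
edges; we use half-open intervals $[8,20]$, $(20,35]$, $(35,\infty)$ so every
score has exactly one band. The HAMD reduction rate
$100(\text{pre}-\text{post})/\text{pre}$ maps to cured (>75), markedly
effective (50–75], effective (25–50], ineffective (≤25); a rate of exactly
25 % is unassigned in the source wording and goes to ineffective so the bands
partition. Percentages are rounded **half-up** to two decimals, matching how
such tables are conventionally printed. Group comparisons use Welch's
unequal-variance t (the safer default when the pooling assumption is
undocumented) and the Pearson chi-square without continuity correction
(Yates optional). Composite rows — total effective = cured + markedly
effective + effective; total compliant = complete + basic — are derived, not
stored.

# Problem sizes and reproducibility

The test and acceptance workloads are sized for a single CPU: the planted
wrapper-recovery study uses 300 samples × 20 features with 5 informative
features at effect size 2.0, population 30 and a 40-generation budget;
denoising properties use ten 4-second fixtures at 250 Hz; the
acceptance-law harness uses 10 000 Metropolis trials; oracle comparisons for
the correlation integral use ≤ 500 embedded points. Every stochastic step —
generators, fold assignment, GA, annealing — is driven by explicit integer
seeds, and rerunning any pipeline with the same configuration reproduces its
CSV artifacts bit for bit (this is itself a test).

# Known limitations

* The wrapper's fitness is a biased estimate of generalization accuracy for
  the *selected* subset (selection bias is inherent to wrapper methods); the
  comparison table from `compare_selectors()` re-evaluates masks under fresh
  folds but a fully unbiased estimate would need nested cross-validation,
  which is out of scope.
* The binned MI estimator is biased upward at small $n$; it is used only for
  ranking.
* EOG removal assumes artifacts are slow (≲ a few Hz) and large relative to
  the background; it will not remove muscle or line-noise artifacts and is
  not a substitute for ICA on real multichannel recordings.
* EEG I/O is wide CSV only; binary acquisition formats are out of scope.
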