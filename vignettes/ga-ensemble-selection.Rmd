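---
title: "Selecting majority-vote ensembles by genetic search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting majority-vote ensembles by genetic search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaeoc)
```

## The model

A pool of k base classifiers is fixed and ordered. A candidate ensemble
is a k-bit mask; bit i selects pool member i. The ensemble's prediction
for a sample is the unweighted majority vote of its members' predictions,
with an exact tie (possible only for even member counts) resolved
uniformly at random. Ensemble quality is the Matthews correlation
coefficient (MCC) of the resulting confusion matrix; the fitness of a
mask is the mean MCC over the validation folds of a stratified 10-fold
cross-validation of the training data. A genetic algorithm (GA) searches
the 2^k − 1 masks for the fitness maximiser; the winner is retrained on
the full training set and scored on held-out data.

The central modelling assumption is that a mask's cross-validated vote
fitness ranks ensembles the same way their test performance would. The
pipeline never consults test labels before prediction, and base
classifiers are trained once per (classifier, fold) pair and cached, so
fitness evaluation reduces to vote counting over cached predictions —
which is what makes a population-based search over thousands of masks
affordable.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `n_folds` | 10 | validation folds; each fold's MCC enters the fitness mean |
| `population_size` | min(5k, 12·2^k) | 100 at k = 20; the cap only binds for tiny pools (k ≤ 5) |
| `crossover_rate` | 0.60 | probability a mating mixes parents bitwise; otherwise the fitter parent is cloned |
| `mutation_rate` | max(0.01, 1/population) | per-bit probability of *replacement* by a fresh uniform bit |
| `tournament_size` | 10 | parents are the fittest of 10 drawn without replacement |
| `elite_count` | 1 | individuals copied unchanged per generation |
| `max_generations` | 1000 | hard stop |
| `stagnation_limit` | 50 | stop after this many consecutive generations without improvement of the best fitness |
| `optimum_fitness` | 1.0 | stop when the best fitness reaches a perfect mean MCC |

Two settings deserve comment.

**Crossover-rate semantics.** "Uniform crossover at rate 0.60" admits two
readings: (a) with probability 0.6 the offspring inherits each bit from
either parent with probability ½, otherwise it is a clone of the fitter
parent; (b) every bit independently comes from parent 1 with probability
0.6, else from parent 2. Reading (a) matches the conventional meaning of
a crossover *rate* and is the default; reading (b) is available as
`per_gene_bias = TRUE` in `ga_config()` so both interpretations are
testable.

**Mutation is replacement, not flipping.** A mutated bit is redrawn
uniformly, so it keeps its value half the time; the expected number of
actual flips per chromosome is k·rate/2. Tests of the mutation operator
assert the replacement model (expected Hamming distance k/2 at rate 1).

## Numerical choices and degenerate inputs

* **MCC with a vanishing denominator factor is 0.** This makes a
  majority-class (one-class) predictor score 0, which is also the natural
  baseline value, and keeps every fold's score defined.
* **Exact vote ties** draw from an explicit, seeded tie stream, one draw
  per tied sample in sample order, so entire runs replay bit for bit
  despite the randomised tie rule. Whether ties are resolved per sample
  or per run is a genuine ambiguity; per-sample is implemented.
* **Fitness memoisation.** Fitness is memoised by bitmask for the whole
  run; a re-encountered mask costs nothing and returns the identical
  value (including its tie resolutions). The evaluation budget is
  therefore bounded by the number of *distinct* masks visited.
* **All-zero chromosomes** (an empty ensemble, for which the vote is
  undefined) are repaired at creation and after mutation by setting one
  uniformly chosen bit, rather than penalised. Every evaluated individual
  is thus a meaningful ensemble.
* **Stagnation** means the best fitness improved by less than 1e−12; the
  optimum test uses `>= optimum_fitness − 1e−12`. The elitist copy
  guarantees the best-fitness history is non-decreasing, which the tests
  assert on every run.
* **Tournament ties** resolve to the lowest population index, and the
  two parents of a mating may coincide, in which case crossover
  degenerates to cloning — harmless and simple.
* **Integer-exact MCC.** The numerator TP·TN − FP·FN is formed in
  integer-exact double arithmetic and only the denominator takes a
  floating square root, so large counts cannot lose precision.

## Class-distribution balancing

All minority samples are set aside; the majority class is shuffled with
a seeded stream and split into q = max(1, round(n_maj/n_min)) chunks,
remainder rows spread one per chunk; each chunk joins the full minority
class as one balanced replicate. Balanced input passes through untouched
as a single replicate. The chunks partition the majority class — no
sample is lost or duplicated — and every replicate's class ratio is
within one sample of 1:1. The rounding rule handles the non-integer
ratios of real tables (a 458:241 class split gives q = 2 chunks of 229).

When balancing produces several replicates, the full
fold/train/search/test cycle runs once *per replicate*, with
per-replicate and averaged reporting. Pooling replicates into a single
search was the alternative; per-replicate runs keep each search's
training distribution balanced, which is the point of the construction.

## Feature selection

**Entropy/MDL discretization.** Per feature, the boundary cut minimising
the class-entropy of the induced partition is accepted only when its
information gain exceeds the minimum-description-length threshold
`(log2(N−1) + log2(3^c − 2) − c·Ent(S) + c1·Ent(S1) + c2·Ent(S2)) / N`,
then each side is split recursively. Features with no accepted cut are
dropped. Only value *ranks* matter, so the output is invariant to
strictly monotone transforms (property-tested).

**(α,β)-k selection.** On the discretised codes, a feature set S is
feasible when every inter-class sample pair differs on at least α
features of S and every intra-class pair agrees on at least β. The
greedy solver adds the feature satisfying the most still-open pair
constraints (ties to the lowest index); the exhaustive solver enumerates
subsets by cardinality (refused above 20 features) and is provably
minimal. Infeasible (α, β) are reported with the violating pair and the
maximum feasible α — never silently relaxed. Defaults are α = 1, β = 0;
the values used in the original biomarker studies are not recorded here,
so they are deliberately exposed as configuration rather than guessed.

**Consolidation.** With several balanced replicates, per-replicate
selections are combined by set union or intersection. The
entropy-first variant applies MDL filtering per replicate, then
selection, then the union. The intersection variant stops after
intersecting (no second selection pass); the source procedure is loose
on this point and intersect-then-stop is the simpler reading.

## The base-classifier pool

The default pool holds 20 named learners spanning Bayes, linear, SVM,
kNN, rule and tree families, built directly on established R
implementations (e1071, rpart, randomForest, ranger, class, nnet, MASS,
stats). The names mirror a well-known data-mining suite's pool, but each
entry is an analogue, not a re-implementation — the search is
pool-agnostic and any list of `classifier_spec` objects can be plugged
in. Near-duplicate entries are kept as distinct bits to preserve the
20-bit search space. A learner that fails to train on a fold falls back
to predicting that fold's training majority and the failure is recorded;
the model store never aborts on one learner.

Folds are stratified (class proportions within one sample per fold).
Plain randomisation is the looser alternative, but on small balanced
replicates it can produce one-class validation folds, on which MCC is
degenerate.

## The synthetic generators, and what the tests do and do not show

`gen_imbalanced_gaussian()` emulates the class-imbalance *structure* of
the benchmark tables — two spherical Gaussian classes at controllable
separation and imbalance ratio — not their feature semantics.

`gen_mock_pool()` builds fixed per-fold predictions so ensemble fitness
is exactly computable and the optimum over all masks is certified by
exhaustive enumeration (k ≤ 16). Its default plants a realistic
structure: three accurate members (error 0.15) with mutually independent
errors among weaker members (error 0.30–0.45) that share a latent error
mask (weight 0.8) — a pool in which a diverse committee beats any
individual, which is the phenomenon the search exists to exploit.
Validation folds default to 70 samples, the fold scale of the ~700-sample
benchmark tables; materially smaller folds make the certified optimum
statistically under-identified (the gap between the best and second-best
masks falls below the tie-resolution noise of the fitness itself), at
which point "finding the optimum" stops being a meaningful property of
any search.

Because enumeration scores tied samples by their exact expectation under
the uniform tie rule (a binomial sum over tie resolutions), while a
search run scores them by one seeded draw, certification of a found mask
uses the deterministic expectation (`expected_fitness()`), not the run's
noisy value.

Passing tests on these generators show that the search machinery finds
certified optima on landscapes with planted structure, that the
arithmetic of every stage is correct, and that runs replay exactly. They
do *not* show that the default pool's learners match any external tool's
learners, nor predict absolute MCC levels on real biomarker or image
data — real features are neither Gaussian nor independent, and real
pools' error correlations are not controlled.

## Repeated runs

The search is stochastic, so experiments are repeated (100 runs in the
original protocol) and summarised by mean/SD of MCC and accuracy plus
the number of distinct winning masks. Repeats reuse one fold split and
model store and vary only the GA seed; re-randomising folds per run is
the configurable alternative, but a fixed split isolates search
variability from fold variability. Test-suite and acceptance runs use
scaled-down sizes — mock pools of k = 8–12 with 20 runs each, pipeline
datasets of a few hundred samples, cheap threshold-learner pools where
the point under study is the store or the search rather than learner
quality — chosen to exercise every code path at desk scale.

## Known limitations

* Numeric feature matrices only; nominal features must be pre-coded, and
  missing values are rejected at read time rather than imputed.
* Base-learner hyperparameters are not tuned; the pool entries run at
  fixed, library-default-like settings.
* The exhaustive (α,β)-k solver and mock-pool certification are
  enumeration-bound (20 features, 16 pool members respectively).
* Vote fitness is a single stochastic realisation when ties occur; on
  landscapes whose top masks differ by less than the tie noise, no
  search can reliably identify "the" optimum, only the optimal plateau.
* Baseline comparisons (bagging, boosting, random forest) call existing
  implementations at their defaults; they are reference points, not
  tuned competitors.
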