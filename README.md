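# gaeoc — genetic-algorithm search for heterogeneous ensembles of classifiers

`gaeoc` is for analysts who have a pool of dissimilar base classifiers —
Bayes learners, linear models, nearest-neighbour, rule and tree learners —
and want the *subset* of that pool whose unweighted majority vote
generalises best, especially on class-imbalanced two-class problems such
as clinical biomarker panels. Picking the best individual classifier is
easy; picking the best committee is a combinatorial search over 2^k − 1
subsets (over a million for k = 20), and the best committee frequently
excludes the best individual member, because what matters is the
*diversity* of the members' errors, not their individual strength.

## The method

Every candidate ensemble is a k-bit mask **I**, bit *i* selecting pool
classifier *C<sub>i</sub>*. An ensemble labels a sample by unweighted
majority vote, with an exact tie broken uniformly at random. Performance
is measured by the Matthews correlation coefficient,

```
MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)) ,
```

which uses all four cells of the confusion matrix and stays honest under
class imbalance (a one-class predictor scores 0 by convention). The
fitness of a mask is the mean MCC of its majority vote across the 10
validation folds of a stratified cross-validation, computed from cached
per-fold predictions so that each base classifier is trained only once
per fold (k × 10 models in total).

A genetic algorithm searches the masks:

* population `|P| = min(5k, 12·2^k)` (100 individuals at k = 20),
* tournament selection with a pool of 10,
* uniform crossover at rate 0.60,
* random-bit-replacement mutation at rate `max(0.01, 1/|P|)`,
* elitism (the best individual survives unchanged),
* termination after 1000 generations, 50 stagnant generations, or a
  perfect fitness of 1.0.

Around the search sit the preprocessing stages: class-distribution
balancing (the shuffled majority class is split into minority-sized
chunks, each paired with the full minority class), supervised entropy/MDL
discretization that drops uninformative features, (α,β)-k minimum
feature-set selection with union/intersection consolidation, and
one-vs-all decomposition for multiclass input. The winning mask is
retrained on the full training set and scored on held-out test data;
a repeated-runs protocol summarises stability across seeds.

## Worked example

A synthetic 1:4 imbalanced Gaussian problem, end to end:

```r
library(gaeoc)
train <- gen_imbalanced_gaussian(60, 240, n_features = 6, separation = 2.5, seed = 42)
test  <- gen_imbalanced_gaussian(30, 30,  n_features = 6, separation = 2.5, seed = 43)

bal   <- balance_dataset(train, seed = 42)        # 4 balanced replicates
ds    <- bal$replicates[[1]]
folds <- make_cv_folds(ds, n_folds = 10, seed = 42)
pool  <- default_pool(seed = 42)                  # 20 heterogeneous learners
store <- train_fold_models(ds, folds, pool)       # 200 cached models
res   <- run_ga(ga_config(pool_size = 20, seed = 42), store)
res
#> <ga_result: fitness 0.8487 after 53 generation(s) [stagnation];
#>  mask 11100010100110010011; 306 distinct masks evaluated>
decode_individual(res$best, pool)
#>  [1] "BayesNet" "NaiveBayes" "NaiveBayesUpdateable" "SimpleLogistic"
#>  [5] "IBk" "OneR" "PART" "ZeroR" "RandomForest" "LMT"

fin <- finalize_and_test(res$best, pool, ds, test, tie_seed = 42)
fin$metrics[c("accuracy", "mcc")]
#> $accuracy [1] 0.8833   $mcc [1] 0.7781
```

The search evaluated 306 of the 1,048,575 possible ensembles before
stagnating on a 10-member committee whose cross-validated mean MCC is
0.849; retrained on the full replicate it reaches MCC 0.778 on the
held-out test set. Note the committee mixes strong members
(RandomForest) with individually weak ones (OneR, ZeroR) — error
diversity, not individual accuracy, is what the vote rewards.

The same pipeline is scriptable from a shell via the thin CLI in
`inst/cli/gaeoc.R` (`balance`, `select`, `run`, `simulate` subcommands).

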