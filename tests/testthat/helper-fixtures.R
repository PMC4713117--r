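# Shared fixture builders; everything is generated in code at test time.

# tiny CSV on disk with pos/neg string labels
write_tiny_csv <- function(path) {
  writeLines(c("a,b,class",
               "1.5,2.0,pos",
               "0.5,1.0,neg",
               "0.7,1.1,neg"), path)
  path
}

# k-class dataset with n_per_class samples each, 2 informative features
multiclass_dataset <- function(n_classes, n_per_class, seed = 1) {
  rng <- rng_stream(seed)
  n <- n_classes * n_per_class
  labs <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  x <- with_stream(rng, matrix(stats::rnorm(n * 2, mean = labs), ncol = 2))
  dataset(x, labs, c("u", "v"), name = "multiclass")
}

# store with a single member whose fold predictions realise the given
# per-fold MCCs exactly (20 samples per fold, 10/10 classes)
store_with_fold_mccs <- function(fold_mcc) {
  y <- rep(c(1L, 0L), each = 10)
  make_pred <- function(m) {
    # m = 0.8 -> one error per class; m = 0.6 -> two; m = 1 -> none
    n_err <- round((1 - m) * 10 / 2)
    p <- y
    if (n_err > 0) {
      p[seq_len(n_err)] <- 0L                  # fn errors
      p[10 + seq_len(n_err)] <- 1L             # fp errors
    }
    p
  }
  pm <- lapply(fold_mcc, function(m) matrix(make_pred(m), nrow = 1))
  mock_pool(pm, rep(list(y), length(fold_mcc)))
}

# deterministic 4-member pool: member 1 strong (2 errors) but its errors sit
# inside the weak members' disjoint error triples; optimum is the weak trio
diverse_vs_strong_pool <- function(n_folds = 10) {
  y <- rep(c(0L, 1L), 10)
  err_sets <- list(c(1, 4), c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  pm <- do.call(rbind, lapply(err_sets, function(e) {
    p <- y; p[e] <- 1L - y[e]; p
  }))
  mock_pool(rep(list(pm), n_folds), rep(list(y), n_folds))
}

# classifier_spec that ignores training and emits a fixed label vector
fixed_spec <- function(id, labels_fun) {
  classifier_spec(id, "baseline",
                  fit = function(x, y) NULL,
                  predict = function(model, x) labels_fun(nrow(x)))
}
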