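test_that("balanced 100-sample data splits into 10 perfectly stratified folds", {
  ds <- gen_imbalanced_gaussian(50, 50, 3, separation = 1, seed = 1)
  folds <- make_cv_folds(ds, 10, seed = 2)
  expect_identical(lengths(folds$validation_indices), rep(10L, 10))
  for (f in folds$validation_indices) {
    expect_identical(sum(ds$labels[f] == 1L), 5L)
  }
  expect_setequal(unlist(folds$validation_indices), seq_len(100))
})

test_that("odd sample counts keep folds and class proportions within one", {
  ds <- gen_imbalanced_gaussian(43, 40, 3, separation = 1, seed = 3)
  folds <- make_cv_folds(ds, 10, seed = 4)
  sizes <- lengths(folds$validation_indices)
  expect_true(all(sizes %in% c(8L, 9L)))
  expect_identical(sum(sizes), 83L)
  expect_identical(anyDuplicated(unlist(folds$validation_indices)), 0L)
  pos_per_fold <- vapply(folds$validation_indices,
                         function(f) sum(ds$labels[f] == 1L), integer(1))
  expect_true(all(abs(pos_per_fold - 4.3) <= 1))
})

test_that("fold construction is deterministic and guards its preconditions", {
  ds <- gen_imbalanced_gaussian(20, 20, 3, separation = 1, seed = 5)
  f1 <- make_cv_folds(ds, 5, seed = 9)
  f2 <- make_cv_folds(ds, 5, seed = 9)
  expect_identical(f1$validation_indices, f2$validation_indices)
  expect_error(make_cv_folds(ds, 25, seed = 1), "needs >=")
  expect_error(make_cv_folds(ds, 1, seed = 1), "n_folds")
})

test_that("the store caches one model per classifier per fold", {
  ds <- gen_imbalanced_gaussian(30, 30, 4, separation = 3, seed = 6)
  folds <- make_cv_folds(ds, 5, seed = 7)
  store <- train_fold_models(ds, folds, stump_pool(3), seed = 8)
  expect_identical(n_models(store), 15L)
  for (i in 1:3) {
    lens <- vapply(seq_len(5), function(f) {
      length(val_predictions(store, i, f))
    }, integer(1))
    expect_identical(sum(lens), 60L)
    expect_identical(lens, lengths(folds$validation_indices))
  }
})

test_that("a majority-class baseline predicts its training majority", {
  ds <- gen_imbalanced_gaussian(20, 30, 3, separation = 1, seed = 9)
  folds <- make_cv_folds(ds, 5, seed = 10)
  zero_r <- classifier_spec("ZeroR", "baseline",
                            fit = function(x, y) {
                              tab <- table(factor(y, levels = c(0L, 1L)))
                              as.integer(names(tab)[which.max(tab)])
                            },
                            predict = function(model, x) rep(model, nrow(x)))
  store <- train_fold_models(ds, folds, list(zero_r), seed = 1)
  for (f in seq_len(5)) {
    tr <- setdiff(seq_len(50), folds$validation_indices[[f]])
    maj <- as.integer(mean(ds$labels[tr]) > 0.5)
    expect_true(all(val_predictions(store, 1, f) == maj))
  }
})

test_that("the store is a pure function of its inputs", {
  ds <- gen_imbalanced_gaussian(25, 25, 3, separation = 2, seed = 11)
  folds <- make_cv_folds(ds, 5, seed = 12)
  s1 <- train_fold_models(ds, folds, stump_pool(4), seed = 13)
  s2 <- train_fold_models(ds, folds, stump_pool(4), seed = 13)
  expect_identical(s1$pred_matrix, s2$pred_matrix)
  expect_identical(s1$fold_labels, s2$fold_labels)
})

test_that("an erroring learner falls back to the majority class, recorded", {
  ds <- gen_imbalanced_gaussian(10, 20, 3, separation = 1, seed = 14)
  folds <- make_cv_folds(ds, 5, seed = 15)
  broken <- classifier_spec("Broken", "tree",
                            fit = function(x, y) stop("cannot fit"),
                            predict = function(model, x) integer(0))
  store <- train_fold_models(ds, folds, list(broken, stump_pool(2)[[1L]]),
                             seed = 16)
  expect_length(store$failures, 5L)
  expect_match(store$failures[1L], "Broken")
  for (f in seq_len(5)) {
    expect_true(all(val_predictions(store, 1, f) == 0L))  # majority is 0
  }
})

test_that("the full default pool trains and beats chance on separable data", {
  ds <- gen_imbalanced_gaussian(40, 40, 5, separation = 4, seed = 17)
  folds <- make_cv_folds(ds, 5, seed = 18)
  pool <- default_pool(seed = 19)
  store <- train_fold_models(ds, folds, pool, seed = 20)
  expect_identical(n_models(store), 100L)
  expect_length(store$failures, 0L)
  # every non-baseline learner should beat coin flipping here
  acc <- vapply(seq_along(pool), function(i) {
    mean(unlist(lapply(seq_len(5), function(f) {
      val_predictions(store, i, f) == store$fold_labels[[f]]
    })))
  }, numeric(1))
  ids <- vapply(pool, function(s) s$id, character(1))
  expect_true(all(acc[ids != "ZeroR"] > 0.6))
})
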