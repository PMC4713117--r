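test_that("delimited read maps labels with the declared positive class", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(path)
  ds <- read_dataset(path, label_column = "class", positive_label = "pos")
  expect_s3_class(ds, "gaeoc_dataset")
  expect_identical(ds$labels, c(1L, 0L, 0L))
  expect_identical(ncol(ds$features), 2L)
  expect_identical(ds$feature_names, c("a", "b"))
  expect_identical(unname(ds$label_map["pos"]), 1L)
})

test_that("minority class becomes positive when no positive label is given", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(path)
  ds <- read_dataset(path, label_column = "class")
  expect_identical(ds$labels, c(1L, 0L, 0L))  # pos is the minority
})

test_that("single-class input is accepted but rejected downstream", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,class", "1,x", "2,x", "3,x"), path)
  ds <- read_dataset(path, label_column = "class")
  expect_identical(length(unique(ds$labels)), 1L)
  expect_error(balance_dataset(ds, seed = 1), "single-class")
  expect_error(make_cv_folds(ds, 2, seed = 1), "two classes")
})

test_that("read errors are distinct and descriptive", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,class", "1,oops,pos"), path)
  expect_error(read_dataset(path, label_column = "class"), "non-numeric")
  expect_error(read_dataset(path, label_column = "nope"), "label column")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b,class", path2)
  expect_error(read_dataset(path2, label_column = "class"), "empty")
  expect_error(read_dataset("no_such_file.csv", label_column = "class"),
               "not found")
})

test_that("ARFF files read through the same interface", {
  path <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation tiny",
               "@attribute a numeric",
               "@attribute class {neg,pos}",
               "@data",
               "1.5,pos",
               "0.5,neg",
               "0.6,neg"), path)
  ds <- read_dataset(path, label_column = "class", positive_label = "pos")
  expect_identical(ds$labels, c(1L, 0L, 0L))
  expect_identical(ds$feature_names, "a")
})

test_that("a WBC-shaped table reads back with its class counts", {
  ds0 <- gen_imbalanced_gaussian(241, 458, 9, separation = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds0, path)
  ds <- read_dataset(path, label_column = "class", positive_label = "1")
  expect_identical(nrow(ds$features), 699L)
  expect_identical(ncol(ds$features), 9L)
  tab <- table(ds$labels)
  expect_identical(as.integer(tab[c("0", "1")]), c(458L, 241L))
})

test_that("write/read round-trips features, labels and names exactly", {
  ds0 <- gen_imbalanced_gaussian(10, 15, 4, separation = 1, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds0, path)
  ds <- read_dataset(path, label_column = "class", positive_label = "1")
  expect_equal(ds$features, ds0$features, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(ds$labels, ds0$labels)
  expect_identical(ds$feature_names, ds0$feature_names)
})

test_that("one_vs_all relabels the target class and preserves order", {
  ds <- multiclass_dataset(5, 90)
  bin <- one_vs_all(ds, 0L)
  expect_identical(sum(bin$labels == 1L), 90L)
  expect_identical(sum(bin$labels == 0L), 360L)
  expect_identical(bin$features, ds$features)

  skewed <- dataset(matrix(stats::rnorm(40), ncol = 2),
                    rep(c(0L, 1L, 2L), c(5, 5, 10)))
  bin2 <- one_vs_all(skewed, 2L)
  expect_identical(as.integer(table(bin2$labels)), c(10L, 10L))

  bin3 <- one_vs_all(bin, 1L)  # binary identity
  expect_identical(bin3$labels, bin$labels)
  expect_error(one_vs_all(ds, 99L), "absent")
})

test_that("one_vs_all positives partition the samples over target classes", {
  ds <- multiclass_dataset(4, 12, seed = 3)
  pos_total <- sum(vapply(0:3, function(cl) {
    sum(one_vs_all(ds, cl)$labels == 1L)
  }, numeric(1)))
  expect_equal(pos_total, 48)
})

test_that("report manifests round-trip and validate fold counts", {
  result <- list(best_mask = "0101", members = c("b", "d"),
                 per_fold_mcc = c(0.5, 0.7), n_folds = 2L,
                 fitness = 0.6, seed = 42L, generations = 12L)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(result, path)
  back <- read_report(path)
  expect_identical(back$best_mask, result$best_mask)
  expect_equal(back$per_fold_mcc, result$per_fold_mcc, tolerance = 1e-15)
  expect_identical(back$seed, 42L)

  bad <- result; bad$per_fold_mcc <- c(0.5, 0.7, 0.9)
  expect_error(write_report(bad, path), "n_folds")
  incomplete <- result; incomplete$fitness <- NULL
  expect_error(write_report(incomplete, path), "missing")

  path2 <- withr::local_tempfile(fileext = ".json")
  write_report(result, path2)
  expect_identical(readLines(path), readLines(path2))
})
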