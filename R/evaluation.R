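#' Retrain the selected ensemble on the full training set and score it on
#' held-out test data
#'
#' Each selected member is refitted on all of `train`; the unweighted
#' majority vote of the refitted members is taken over the test samples
#' (ties from a seeded stream) and the full metrics record plus confusion
#' matrix is returned. Test labels are consulted only after all
#' predictions are made.
#'
#' @param best 0/1 bit vector over the pool.
#' @param pool ordered list of [classifier_spec()]s.
#' @param train,test `gaeoc_dataset`s sharing the same feature schema.
#' @param tie_seed seed for vote tie-breaking.
#' @return List with `members`, `metrics`, `confusion`, `predictions`.
#' @export
finalize_and_test <- function(best, pool, train, test, tie_seed = 1L) {
  stopifnot(inherits(train, "gaeoc_dataset"), inherits(test, "gaeoc_dataset"))
  if (!identical(train$feature_names, test$feature_names)) {
    stop("train and test feature schemas differ")
  }
  members <- decode_individual(best, pool)
  idx <- which(as.integer(best) == 1L)
  tie_rng <- rng_stream(tie_seed)
  preds <- matrix(NA_integer_, nrow = length(idx), ncol = n_samples(test),
                  dimnames = list(members, NULL))
  for (r in seq_along(idx)) {
    spec <- pool[[idx[r]]]
    p <- tryCatch({
      model <- spec$fit(train$features, train$labels)
      as.integer(spec$predict(model, test$features))
    }, error = function(e) {
      rep(majority_label(train$labels), n_samples(test))
    })
    preds[r, ] <- p
  }
  yhat <- vote_matrix(preds, tie_rng)
  cm <- confusion(test$labels, yhat)
  list(members = members, metrics = classification_metrics(cm),
       confusion = cm, predictions = yhat)
}

#' Repeated-runs protocol: search many times, summarise spread
#'
#' Repeats the GA search (and final test evaluation) `n_runs` times with
#' seeds `base_seed .. base_seed + n_runs - 1`, reusing one fold split and
#' model store, and aggregates mean/standard deviation of the MCC and
#' accuracy plus the number of distinct winning masks — the stability
#' summary used to judge how consistently the search converges.
#'
#' @param store a `gaeoc_store` built from the training data.
#' @param pool the classifier pool behind the store.
#' @param train,test datasets for final evaluation; if `test` is NULL the
#'   summary covers validation fitness only.
#' @param n_runs number of repeats (>= 1).
#' @param base_seed first GA seed.
#' @param config_args extra arguments passed to [ga_config()].
#' @return A `run_summary`: `per_run` (list of seed, mask, fitness, test
#'   metrics), `mean_mcc`, `stdev_mcc`, `mean_accuracy`, `stdev_accuracy`,
#'   `mean_fitness`, `n_distinct_ensembles`.
#' @export
repeated_runs <- function(store, pool = NULL, train = NULL, test = NULL,
                          n_runs = 10L, base_seed = 1L, config_args = list()) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  do_test <- !is.null(test) && !is.null(train) && !is.null(pool)
  per_run <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    seed <- as.integer(base_seed + r - 1L)
    cfg <- do.call(ga_config,
                   c(list(pool_size = store$k, seed = seed), config_args))
    res <- run_ga(cfg, store)
    entry <- list(seed = seed, best_mask = mask_key(res$best),
                  fitness = res$best_fitness,
                  generations = res$generations_run,
                  termination = res$termination_reason)
    if (do_test) {
      fin <- finalize_and_test(res$best, pool, train, test, tie_seed = seed)
      entry$test_mcc <- fin$metrics$mcc
      entry$test_accuracy <- fin$metrics$accuracy
    }
    per_run[[r]] <- entry
  }
  mccs <- if (do_test) vapply(per_run, `[[`, numeric(1), "test_mcc") else
    vapply(per_run, `[[`, numeric(1), "fitness")
  accs <- if (do_test) vapply(per_run, `[[`, numeric(1), "test_accuracy") else
    rep(NA_real_, n_runs)
  structure(
    list(per_run = per_run,
         mean_mcc = mean(mccs),
         stdev_mcc = if (n_runs > 1L) stats::sd(mccs) else 0,
         mean_accuracy = mean(accs),
         stdev_accuracy = if (n_runs > 1L) stats::sd(accs) else 0,
         mean_fitness = mean(vapply(per_run, `[[`, numeric(1), "fitness")),
         n_distinct_ensembles =
           length(unique(vapply(per_run, `[[`, character(1), "best_mask")))),
    class = "run_summary"
  )
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "<run_summary: %d run(s); mean MCC %.4f (sd %.4f); %d distinct ensemble(s)>\n",
    length(x$per_run), x$mean_mcc, x$stdev_mcc, x$n_distinct_ensembles))
  invisible(x)
}

#' Compare the searched ensemble against off-the-shelf ensemble learners
#'
#' Fits each named baseline on `train` at library-default settings and
#' scores it on `test` alongside a supplied GA-selected ensemble result.
#' Baselines are calls into established implementations: `random_forest`
#' (randomForest), `bagging` (randomForest grown with mtry = all features,
#' i.e. bagged trees) and `boosting` (xgboost). An unavailable baseline is
#' skipped with a warning.
#'
#' @param train,test `gaeoc_dataset`s.
#' @param baselines character subset of
#'   `c("bagging", "boosting", "random_forest")`; duplicates rejected.
#' @param seed integer seed for the stochastic baselines.
#' @param gaeoc_metrics optional metrics record (from
#'   [finalize_and_test()]) reported as the `GA-EoC` row.
#' @return data.frame with one row per method and columns
#'   method/accuracy/precision/recall/f_measure/mcc.
#' @export
baseline_comparison <- function(train, test,
                                baselines = c("bagging", "boosting",
                                              "random_forest"),
                                seed = 1L, gaeoc_metrics = NULL) {
  if (anyDuplicated(baselines)) stop("duplicate baseline names")
  known <- c("bagging", "boosting", "random_forest")
  unknown <- setdiff(baselines, known)
  if (length(unknown)) stop("unknown baseline(s): ",
                            paste(unknown, collapse = ", "))
  rows <- list()
  add_row <- function(method, cm) {
    m <- classification_metrics(cm)
    rows[[length(rows) + 1L]] <<- data.frame(
      method = method, accuracy = m$accuracy, precision = m$precision,
      recall = m$recall, f_measure = m$f_measure, mcc = m$mcc)
  }
  if (!is.null(gaeoc_metrics)) {
    rows[[length(rows) + 1L]] <- data.frame(
      method = "GA-EoC", accuracy = gaeoc_metrics$accuracy,
      precision = gaeoc_metrics$precision, recall = gaeoc_metrics$recall,
      f_measure = gaeoc_metrics$f_measure, mcc = gaeoc_metrics$mcc)
  }
  y_tr <- as_binary_factor(train$labels)
  for (b in baselines) {
    pred <- tryCatch({
      if (b == "random_forest") {
        set.seed(seed)
        fit <- randomForest::randomForest(train$features, y_tr)
        as.integer(as.character(predict(fit, test$features)))
      } else if (b == "bagging") {
        set.seed(seed)
        fit <- randomForest::randomForest(train$features, y_tr,
                                          mtry = ncol(train$features))
        as.integer(as.character(predict(fit, test$features)))
      } else {
        if (!requireNamespace("xgboost", quietly = TRUE)) {
          stop("xgboost not installed")
        }
        fit <- xgboost::xgboost(data = train$features,
                                label = train$labels, nrounds = 50,
                                objective = "binary:logistic",
                                verbose = 0, nthread = 1,
                                params = list(seed = seed))
        as.integer(predict(fit, test$features) > 0.5)
      }
    }, error = function(e) {
      warning("baseline '", b, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(pred)) add_row(b, confusion(test$labels, pred))
  }
  do.call(rbind, rows)
}
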