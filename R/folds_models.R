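#' Stratified cross-validation folds
#'
#' Partitions sample indices into `n_folds` validation folds whose sizes
#' differ by at most one and whose per-fold class proportions are within
#' one sample of the global proportions. Stratification keeps every
#' validation fold two-class on small balanced data, without which a
#' fold's MCC would be degenerate.
#'
#' @param ds a binary `gaeoc_dataset`; each class needs >= `n_folds`
#'   samples.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the within-class shuffles.
#' @return A `gaeoc_folds` object: `validation_indices` (list of integer
#'   vectors partitioning 1..n), `n_folds`, `seed`, `labels`.
#' @export
make_cv_folds <- function(ds, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(ds, "gaeoc_dataset"))
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2")
  cc <- class_counts(ds)
  if (length(cc) < 2L) stop("cross-validation requires two classes")
  small <- cc[cc < n_folds]
  if (length(small)) {
    stop("class ", names(small)[1L], " has only ", small[1L],
         " samples; needs >= ", n_folds)
  }
  rng <- rng_stream(seed)
  # deal shuffled per-class indices onto a single cyclic fold sequence so
  # both fold sizes and class proportions stay within +/-1
  seq_all <- integer(0)
  for (lab in sort(unique(ds$labels))) {
    idx <- which(ds$labels == lab)
    seq_all <- c(seq_all, stream_sample(rng, idx))
  }
  fold_of <- rep_len(seq_len(n_folds), length(seq_all))
  validation <- split(seq_all, fold_of)
  validation <- lapply(unname(validation), sort)
  structure(
    list(validation_indices = validation, n_folds = n_folds,
         seed = as.integer(seed), labels = ds$labels),
    class = "gaeoc_folds"
  )
}

#' @export
print.gaeoc_folds <- function(x, ...) {
  cat(sprintf("<gaeoc_folds: %d folds over %d samples (seed %d); sizes %s>\n",
              x$n_folds, length(x$labels), x$seed,
              paste(lengths(x$validation_indices), collapse = "/")))
  invisible(x)
}

train_indices <- function(folds, f) {
  sort(unlist(folds$validation_indices[-f], use.names = FALSE))
}

#' Train every pool classifier on every training fold and cache validation
#' predictions
#'
#' For each (classifier, fold) pair the classifier is fitted on the other
#' `n_folds - 1` folds and its predictions on the held-out fold are
#' cached, yielding `n_pool * n_folds` entries (200 for the default
#' 20-learner pool under 10-fold CV). A learner that fails to train on a
#' fold is recorded as a failure and its fold predictions fall back to the
#' majority class of its training folds; the store is never aborted by one
#' learner. The store is a pure function of (dataset, folds, pool, seed).
#'
#' @param ds the training `gaeoc_dataset`.
#' @param folds a [make_cv_folds()] result for `ds`.
#' @param pool ordered list of [classifier_spec()]s; bit i of a GA
#'   individual refers to `pool[[i]]`.
#' @param seed integer seed recorded in provenance (base learners that
#'   randomise internally are seeded by the pool constructor).
#' @param keep_models keep fitted model handles (needed only if members
#'   will be retrained/inspected; validation predictions are always kept).
#' @return A `gaeoc_store`: `pred_matrix` (list over folds of k x
#'   fold-size 0/1 matrices, rows in pool order), `fold_labels`,
#'   `models`, `failures`, `pool_ids`, `k`, `n_folds`, `provenance`.
#' @export
train_fold_models <- function(ds, folds, pool, seed = 1L, keep_models = FALSE) {
  stopifnot(inherits(ds, "gaeoc_dataset"), inherits(folds, "gaeoc_folds"))
  ids <- validate_pool(pool)
  if (length(folds$labels) != n_samples(ds)) {
    stop("fold split does not match dataset size")
  }
  k <- length(pool)
  nf <- folds$n_folds
  pred_matrix <- vector("list", nf)
  fold_labels <- vector("list", nf)
  models <- if (keep_models) vector("list", k * nf) else NULL
  failures <- character(0)
  for (f in seq_len(nf)) {
    val_idx <- folds$validation_indices[[f]]
    tr_idx <- train_indices(folds, f)
    x_tr <- ds$features[tr_idx, , drop = FALSE]
    y_tr <- ds$labels[tr_idx]
    x_val <- ds$features[val_idx, , drop = FALSE]
    pm <- matrix(NA_integer_, nrow = k, ncol = length(val_idx),
                 dimnames = list(ids, NULL))
    for (i in seq_len(k)) {
      spec <- pool[[i]]
      pred <- tryCatch({
        model <- spec$fit(x_tr, y_tr)
        if (keep_models) models[[(f - 1L) * k + i]] <- model
        p <- as.integer(spec$predict(model, x_val))
        if (length(p) != length(val_idx) || !all(p %in% c(0L, 1L))) {
          stop("bad prediction vector")
        }
        p
      }, error = function(e) {
        failures <<- c(failures, sprintf("%s/fold%d: %s", spec$id, f,
                                         conditionMessage(e)))
        rep(majority_label(y_tr), length(val_idx))
      })
      pm[i, ] <- pred
    }
    pred_matrix[[f]] <- pm
    fold_labels[[f]] <- ds$labels[val_idx]
  }
  structure(
    list(pred_matrix = pred_matrix, fold_labels = fold_labels,
         models = models, failures = failures, pool_ids = ids,
         k = k, n_folds = nf,
         provenance = list(dataset = ds$name, seed = as.integer(seed),
                           n_samples = n_samples(ds))),
    class = "gaeoc_store"
  )
}

#' @export
print.gaeoc_store <- function(x, ...) {
  cat(sprintf(
    "<gaeoc_store: %d classifiers x %d folds = %d cached models ('%s')%s>\n",
    x$k, x$n_folds, x$k * x$n_folds, x$provenance$dataset,
    if (length(x$failures)) sprintf("; %d training failure(s)",
                                    length(x$failures)) else ""))
  invisible(x)
}

#' Number of cached (classifier, fold) entries in a store
#'
#' @param store a `gaeoc_store` (or mock pool).
#' @return Integer count, `k * n_folds`.
#' @export
n_models <- function(store) store$k * store$n_folds

#' Validation predictions of one classifier on one fold
#'
#' @param store a `gaeoc_store`.
#' @param classifier_id pool id or index.
#' @param fold fold number.
#' @return 0/1 integer vector over that fold's validation samples.
#' @export
val_predictions <- function(store, classifier_id, fold) {
  store$pred_matrix[[fold]][classifier_id, ]
}
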