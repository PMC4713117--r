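#' Default end-to-end run configuration
#'
#' All defaults equal the canonical search settings: 10 folds, population
#' sized by [population_size()], crossover 0.60, mutation by
#' [mutation_rate()], tournament 10, elitism 1, termination at
#' 1000 generations / 50 stagnant generations / fitness 1.0.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    label_column = "class",
    positive_label = NULL,
    n_folds = 10L,
    pool = "default",
    population_size = NULL,     # NULL -> sized from the pool via Eq-style rule
    crossover_rate = 0.60,
    mutation_rate = NULL,       # NULL -> rate rule from population size
    tournament_size = 10L,
    elite_count = 1L,
    max_generations = 1000L,
    stagnation_limit = 50L,
    optimum_fitness = 1.0,
    per_gene_bias = FALSE,
    featsel_mode = "plain",     # plain | uab | iab | ueab
    alpha = 1L,
    beta = 0L,
    n_runs = 1L,
    seed = 1L,
    version = "0.1.0"
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes a list), fills unset keys with
#' [default_run_config()] values, rejects unknown keys and validates
#' ranges with field-level messages. An empty file yields all defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list merged over the file values.
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(cfg, user, keep.null = TRUE)
  check_range <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!is.null(v) && (!is.numeric(v) || v < lo || v > hi)) {
      stop("config field '", field, "' must lie in [", lo, ", ", hi,
           "], got ", v)
    }
  }
  check_range("crossover_rate", 0, 1)
  check_range("mutation_rate", 0, 1)
  check_range("optimum_fitness", -1, 1)
  check_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.null(v) && (!is.numeric(v) || v < 1)) {
      stop("config field '", field, "' must be a positive integer, got ", v)
    }
  }
  for (f in c("n_folds", "population_size", "tournament_size",
              "max_generations", "stagnation_limit", "n_runs")) check_pos(f)
  if (!cfg$featsel_mode %in% c("plain", "uab", "iab", "ueab")) {
    stop("config field 'featsel_mode' must be one of plain/uab/iab/ueab")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Save a run configuration to YAML
#'
#' @param cfg a `run_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

#' End-to-end pipeline: balance, fold, train, search, evaluate
#'
#' Runs the full procedure on one training dataset (and optional test
#' set): class-distribution balancing when imbalanced, a full
#' fold/train/search per balanced replicate, and final test evaluation of
#' each replicate's best ensemble. One master seed drives every stage
#' through named streams.
#'
#' @param train a binary `gaeoc_dataset`.
#' @param test optional `gaeoc_dataset` with the same schema.
#' @param pool classifier pool (default [default_pool()]).
#' @param config a `run_config` (default [load_run_config()] defaults).
#' @return A `gaeoc_run` list: `replicates` (per-replicate GA result,
#'   store summary and test metrics), `config`, `seed`, and `summary`
#'   (mean fitness / test MCC across replicates).
#' @export
run_pipeline <- function(train, test = NULL, pool = NULL,
                         config = load_run_config()) {
  if (is.null(pool)) pool <- default_pool(seed = config$seed)
  streams <- seed_streams(config$seed)
  bal <- balance_dataset(train, seed = streams$balancing)
  replicates <- vector("list", length(bal$replicates))
  for (i in seq_along(bal$replicates)) {
    ds <- bal$replicates[[i]]
    folds <- make_cv_folds(ds, n_folds = config$n_folds,
                           seed = streams$folds + i)
    store <- train_fold_models(ds, folds, pool, seed = streams$models + i)
    pop <- if (is.null(config$population_size)) {
      population_size(length(pool))
    } else config$population_size
    cfg <- ga_config(
      pool_size = length(pool),
      population_size = pop,
      crossover_rate = config$crossover_rate,
      mutation_rate = if (is.null(config$mutation_rate)) {
        mutation_rate(pop)
      } else config$mutation_rate,
      tournament_size = config$tournament_size,
      elite_count = config$elite_count,
      max_generations = config$max_generations,
      stagnation_limit = config$stagnation_limit,
      optimum_fitness = config$optimum_fitness,
      per_gene_bias = config$per_gene_bias,
      seed = streams$ga + i
    )
    res <- run_ga(cfg, store)
    entry <- list(
      replicate = ds$name,
      result = res,
      n_models = n_models(store),
      training_failures = store$failures
    )
    if (!is.null(test)) {
      entry$test <- finalize_and_test(res$best, pool, ds, test,
                                      tie_seed = streams$ties + i)
    }
    replicates[[i]] <- entry
  }
  fits <- vapply(replicates, function(r) r$result$best_fitness, numeric(1))
  summary <- list(mean_fitness = mean(fits), n_replicates = length(replicates))
  if (!is.null(test)) {
    tm <- vapply(replicates, function(r) r$test$metrics$mcc, numeric(1))
    summary$mean_test_mcc <- mean(tm)
  }
  structure(list(replicates = replicates, config = unclass(config),
                 seed = config$seed, summary = summary),
            class = "gaeoc_run")
}

#' Assemble the JSON-ready report record for one pipeline run
#'
#' Flattens a [run_pipeline()] result into the manifest schema accepted by
#' [write_report()].
#'
#' @param run a `gaeoc_run`.
#' @param pool the pool used (for member names).
#' @return Named list suitable for [write_report()].
#' @export
run_report <- function(run, pool) {
  reps <- lapply(run$replicates, function(r) {
    out <- list(
      replicate = r$replicate,
      best_mask = mask_key(r$result$best),
      members = decode_individual(r$result$best, pool),
      fitness = r$result$best_fitness,
      per_fold_mcc = r$result$per_fold_mcc,
      generations = r$result$generations_run,
      termination = r$result$termination_reason
    )
    if (!is.null(r$test)) {
      m <- r$test$metrics
      out$test_metrics <- m[c("accuracy", "precision", "recall",
                              "f_measure", "mcc")]
    }
    out
  })
  best_rep <- which.max(vapply(run$replicates,
                               function(r) r$result$best_fitness, numeric(1)))
  r <- run$replicates[[best_rep]]
  list(
    best_mask = mask_key(r$result$best),
    members = decode_individual(r$result$best, pool),
    per_fold_mcc = r$result$per_fold_mcc,
    n_folds = length(r$result$per_fold_mcc),
    fitness = r$result$best_fitness,
    seed = run$seed,
    generations = r$result$generations_run,
    summary = run$summary,
    replicates = reps
  )
}
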