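#' Population-sizing rule
#'
#' |P| = min(5 k, 12 * 2^k) for a pool of k classifiers — linear in the
#' chromosome length once the search space is non-trivial, but capped by a
#' multiple of the number of distinct ensembles for tiny pools. k = 20
#' gives the canonical population of 100.
#'
#' @param k pool size (>= 1).
#' @return Integer population size.
#' @examples
#' population_size(20)  # 100
#' @export
population_size <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  as.integer(min(5 * k, 12 * 2^k))
}

#' Mutation-rate rule
#'
#' R_mu = max(0.01, 1/n) where n is the population size: one expected bit
#' flip per chromosome for small populations, floored at 1% to sustain
#' diversity. n = 100 gives the canonical 0.01.
#'
#' @param n population size (>= 1).
#' @return Mutation rate in (0, 1].
#' @examples
#' mutation_rate(100)  # 0.01
#' @export
mutation_rate <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  max(0.01, 1 / n)
}

#' GA configuration with canonical defaults
#'
#' Defaults follow the published search settings: population sized by
#' [population_size()], uniform crossover at rate 0.60, mutation by
#' [mutation_rate()], tournament of 10, elitism m = 1, and termination at
#' 1000 generations, 50 stagnant generations, or a fitness reaching 1.0
#' (a perfect MCC on every fold).
#'
#' @param pool_size chromosome length k.
#' @param population_size number of individuals.
#' @param crossover_rate probability a mating performs uniform mixing
#'   (otherwise the fitter parent is cloned).
#' @param mutation_rate per-bit random-replacement probability.
#' @param tournament_size individuals drawn (without replacement) per
#'   parent selection.
#' @param elite_count individuals copied unchanged each generation.
#' @param max_generations,stagnation_limit,optimum_fitness the three
#'   terminating conditions.
#' @param per_gene_bias alternative crossover reading: inherit each bit
#'   from parent 1 with probability `crossover_rate` (see Details in the
#'   vignette); default FALSE.
#' @param seed integer master seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pool_size,
                      population_size = gaeoc::population_size(pool_size),
                      crossover_rate = 0.60,
                      mutation_rate = gaeoc::mutation_rate(population_size),
                      tournament_size = 10L,
                      elite_count = 1L,
                      max_generations = 1000L,
                      stagnation_limit = 50L,
                      optimum_fitness = 1.0,
                      per_gene_bias = FALSE,
                      seed = 1L) {
  cfg <- list(pool_size = as.integer(pool_size),
              population_size = as.integer(population_size),
              crossover_rate = crossover_rate,
              mutation_rate = mutation_rate,
              tournament_size = as.integer(min(tournament_size, population_size)),
              elite_count = as.integer(elite_count),
              max_generations = as.integer(max_generations),
              stagnation_limit = as.integer(stagnation_limit),
              optimum_fitness = optimum_fitness,
              per_gene_bias = isTRUE(per_gene_bias),
              seed = as.integer(seed))
  if (cfg$pool_size < 1L) stop("pool_size must be >= 1")
  if (cfg$crossover_rate < 0 || cfg$crossover_rate > 1) {
    stop("crossover_rate must be in [0, 1]")
  }
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]")
  }
  if (cfg$tournament_size > cfg$population_size) {
    stop("tournament_size must not exceed population_size")
  }
  if (cfg$elite_count >= cfg$population_size) {
    stop("elite_count must be smaller than population_size")
  }
  class(cfg) <- "ga_config"
  cfg
}

#' Decode a bitmask individual into its ensemble members
#'
#' Bit i selects pool entry i; members are returned in pool order.
#'
#' @param bits 0/1 vector of length k.
#' @param pool ordered list of [classifier_spec()]s (or anything with
#'   ids via names).
#' @return Character vector of selected member ids.
#' @export
decode_individual <- function(bits, pool) {
  bits <- as.integer(bits)
  if (length(bits) != length(pool)) {
    stop("individual length ", length(bits), " does not match pool size ",
         length(pool))
  }
  if (!any(bits == 1L)) stop("all-zero individual encodes an empty ensemble")
  ids <- if (all(vapply(pool, inherits, logical(1), "classifier_spec"))) {
    pool_ids(pool)
  } else as.character(seq_along(pool))
  ids[bits == 1L]
}

mask_key <- function(bits) paste(bits, collapse = "")

#' Fitness of an individual: mean validation MCC over folds
#'
#' Decodes the bitmask, forms the majority-vote ensemble from the cached
#' per-fold validation predictions of the selected members, scores each
#' fold by MCC against its validation labels, and returns the mean over
#' folds. Results are memoised by bitmask in `cache` (an environment), so
#' re-encountered masks cost nothing.
#'
#' @param bits 0/1 vector, at least one bit set.
#' @param store a `gaeoc_store` or [gen_mock_pool()] result.
#' @param tie_rng a [rng_stream()] for vote ties.
#' @param cache optional environment for memoisation.
#' @return List with `fitness` (mean MCC) and `per_fold_mcc`.
#' @export
evaluate_fitness <- function(bits, store, tie_rng, cache = NULL) {
  key <- mask_key(bits)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  members <- which(as.integer(bits) == 1L)
  if (!length(members)) stop("cannot evaluate an empty ensemble")
  if (length(bits) != store$k) stop("individual length does not match store pool size")
  kk <- length(members)
  per_fold <- with_stream(tie_rng, vapply(seq_len(store$n_folds), function(f) {
    pm <- store$pred_matrix[[f]][members, , drop = FALSE]
    s <- colSums(pm)
    pred <- as.integer(s * 2 > kk)
    ties <- which(s * 2 == kk)
    if (length(ties)) pred[ties] <- as.integer(stats::runif(length(ties)) < 0.5)
    y <- store$fold_labels[[f]]
    mcc_counts(sum(pred == 1L & y == 1L), sum(pred == 1L & y == 0L),
               sum(pred == 0L & y == 0L), sum(pred == 0L & y == 1L))
  }, numeric(1)))
  out <- list(fitness = mean(per_fold), per_fold_mcc = per_fold)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

#' Tournament selection
#'
#' Draws `tournament_size` distinct individuals uniformly without
#' replacement and returns the index of the fittest (ties to the lowest
#' population index).
#'
#' @param fitnesses numeric vector of population fitnesses.
#' @param tournament_size pool size per tournament.
#' @param rng a [rng_stream()].
#' @return Index of the selected individual.
#' @export
tournament_select <- function(fitnesses, tournament_size, rng) {
  n <- length(fitnesses)
  if (n == 0L) stop("empty population")
  if (tournament_size > n) stop("tournament larger than population")
  with_stream(rng, tournament_core(fitnesses, tournament_size))
}

tournament_core <- function(fitnesses, tournament_size) {
  pool <- sort(sample.int(length(fitnesses), tournament_size))
  pool[which.max(fitnesses[pool])]  # sorted pool: ties -> lowest index
}

#' Uniform crossover
#'
#' With probability `rate` the offspring inherits each bit independently
#' from either parent with probability 1/2; otherwise it is a copy of the
#' fitter parent. With `per_gene_bias = TRUE` the alternative per-gene
#' reading is used instead: every bit comes from parent 1 with probability
#' `rate`, else from parent 2.
#'
#' @param p1,p2 parent bit vectors of equal length.
#' @param rate crossover rate in \[0, 1\].
#' @param rng a [rng_stream()].
#' @param fitter which parent (1 or 2) is fitter, used when the mating
#'   does not cross.
#' @param per_gene_bias switch to the per-gene interpretation.
#' @return Offspring bit vector.
#' @export
uniform_crossover <- function(p1, p2, rate, rng, fitter = 1L,
                              per_gene_bias = FALSE) {
  p1 <- as.integer(p1); p2 <- as.integer(p2)
  if (length(p1) != length(p2)) stop("parent lengths differ")
  with_stream(rng, crossover_core(p1, p2, rate, fitter, per_gene_bias))
}

crossover_core <- function(p1, p2, rate, fitter, per_gene_bias) {
  k <- length(p1)
  if (per_gene_bias) {
    from1 <- stats::runif(k) < rate
    return(ifelse(from1, p1, p2))
  }
  if (stats::runif(1) >= rate) {
    return(if (fitter == 1L) p1 else p2)
  }
  from1 <- stats::runif(k) < 0.5
  ifelse(from1, p1, p2)
}

#' Random-bit-replacement mutation with all-zero repair
#'
#' Each bit is independently replaced by a fresh uniform random bit with
#' probability `rate` (replacement, not flip: a mutated bit keeps its
#' value half the time). An all-zero result is repaired by setting one
#' uniformly chosen bit, since an empty ensemble has no defined vote.
#'
#' @param bits 0/1 vector.
#' @param rate per-bit replacement probability.
#' @param rng a [rng_stream()].
#' @return Mutated bit vector, never all-zero.
#' @export
mutate_bits <- function(bits, rate, rng) {
  bits <- as.integer(bits)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  with_stream(rng, mutate_core(bits, rate))
}

mutate_core <- function(bits, rate) {
  k <- length(bits)
  if (rate > 0) {
    hit <- stats::runif(k) < rate
    if (any(hit)) {
      bits[hit] <- as.integer(stats::runif(sum(hit)) < 0.5)
    }
  }
  repair_core(bits)
}

repair_core <- function(bits) {
  if (!any(bits == 1L)) {
    bits[sample.int(length(bits), 1L)] <- 1L
  }
  bits
}

random_individual <- function(k, rng) {
  with_stream(rng, repair_core(as.integer(stats::runif(k) < 0.5)))
}

#' Breed the next population
#'
#' Copies the `elite_count` fittest individuals verbatim, then fills the
#' population by repeated (tournament x2 -> uniform crossover -> mutation
#' -> repair). Elitism guarantees the best fitness never decreases.
#'
#' @param population list of bit vectors.
#' @param fitnesses their fitness values.
#' @param config a [ga_config()].
#' @param rng a [rng_stream()].
#' @return List of bit vectors of the same size.
#' @export
next_generation <- function(population, fitnesses, config, rng) {
  n <- length(population)
  stopifnot(n == length(fitnesses), n == config$population_size)
  elite_idx <- order(-fitnesses)[seq_len(config$elite_count)]
  out <- vector("list", n)
  out[seq_len(config$elite_count)] <- population[elite_idx]
  with_stream(rng, {
    for (j in seq.int(config$elite_count + 1L, n)) {
      i1 <- tournament_core(fitnesses, config$tournament_size)
      i2 <- tournament_core(fitnesses, config$tournament_size)
      fitter <- if (fitnesses[i2] > fitnesses[i1]) 2L else 1L
      child <- crossover_core(population[[i1]], population[[i2]],
                              config$crossover_rate, fitter,
                              config$per_gene_bias)
      out[[j]] <- mutate_core(child, config$mutation_rate)
    }
  })
  out
}

#' Run the genetic algorithm over ensemble bitmasks
#'
#' Starts from a population of uniform random (repaired) individuals and
#' iterates evaluate -> breed until one of three terminating conditions
#' holds: `max_generations` reached, best fitness stagnant for
#' `stagnation_limit` consecutive generations, or best fitness at the
#' optimum (mean MCC of 1.0 by default). Fitness values are memoised by
#' bitmask for the whole run. Returns the fittest individual ever
#' evaluated.
#'
#' @param config a [ga_config()] whose `pool_size` matches the store.
#' @param store a `gaeoc_store` or [gen_mock_pool()] result carrying
#'   per-fold validation predictions and labels.
#' @return A `ga_result`: `best` (bit vector), `best_fitness`,
#'   `per_fold_mcc`, `generations_run`, `fitness_history` (best-so-far per
#'   generation, non-decreasing), `termination_reason`, `n_evaluations`
#'   (distinct masks evaluated), `seed`.
#' @export
run_ga <- function(config, store) {
  stopifnot(inherits(config, "ga_config"))
  if (config$pool_size != store$k) {
    stop("config pool_size (", config$pool_size,
         ") does not match store pool size (", store$k, ")")
  }
  streams <- seed_streams(config$seed)
  rng <- rng_stream(streams$ga)
  tie_rng <- rng_stream(streams$ties)
  cache <- new.env(parent = emptyenv())
  eps <- 1e-12

  population <- replicate(config$population_size,
                          random_individual(config$pool_size, rng),
                          simplify = FALSE)
  best_bits <- NULL
  best_fit <- -Inf
  best_folds <- NULL
  history <- numeric(0)
  stagnant <- 0L
  gen <- 0L
  reason <- "max_generations"

  repeat {
    gen <- gen + 1L
    evals <- lapply(population, evaluate_fitness, store = store,
                    tie_rng = tie_rng, cache = cache)
    fits <- vapply(evals, `[[`, numeric(1), "fitness")
    gen_best <- which.max(fits)
    improved <- fits[gen_best] > best_fit + eps
    if (fits[gen_best] > best_fit) {
      best_fit <- fits[gen_best]
      best_bits <- population[[gen_best]]
      best_folds <- evals[[gen_best]]$per_fold_mcc
    }
    history <- c(history, best_fit)
    stagnant <- if (improved) 0L else stagnant + 1L
    if (best_fit >= config$optimum_fitness - eps) { reason <- "optimum"; break }
    if (stagnant >= config$stagnation_limit) { reason <- "stagnation"; break }
    if (gen >= config$max_generations) { reason <- "max_generations"; break }
    population <- next_generation(population, fits, config, rng)
  }

  structure(
    list(best = best_bits, best_fitness = best_fit,
         per_fold_mcc = best_folds, generations_run = gen,
         fitness_history = history, termination_reason = reason,
         n_evaluations = length(ls(cache)), seed = config$seed),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result: fitness %.4f after %d generation(s) [%s]; mask %s; %d distinct masks evaluated>\n",
    x$best_fitness, x$generations_run, x$termination_reason,
    mask_key(x$best), x$n_evaluations))
  invisible(x)
}
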