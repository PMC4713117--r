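test_that("the sizing rules reproduce their closed forms", {
  expect_identical(population_size(20), 100L)
  expect_identical(population_size(2), 10L)
  expect_identical(population_size(1), 5L)
  expect_error(population_size(0), ">= 1")
  expect_equal(mutation_rate(100), 0.01)
  expect_equal(mutation_rate(50), 0.02)
  expect_equal(mutation_rate(1000), 0.01)
  expect_error(mutation_rate(0), ">= 1")
})

test_that("config invariants are enforced", {
  expect_error(ga_config(8, crossover_rate = 1.5), "crossover_rate")
  expect_error(ga_config(8, population_size = 10, elite_count = 10),
               "elite_count")
  cfg <- ga_config(20)
  expect_identical(cfg$population_size, 100L)
  expect_equal(cfg$mutation_rate, 0.01)
  expect_identical(cfg$tournament_size, 10L)
})

test_that("bitmasks decode to pool members in pool order", {
  pool <- stump_pool(20)
  bits <- c(1L, rep(0L, 18), 1L)
  expect_identical(decode_individual(bits, pool),
                   c(pool[[1L]]$id, pool[[20L]]$id))
  expect_length(decode_individual(rep(1L, 20), pool), 20L)
  expect_error(decode_individual(rep(0L, 20), pool), "empty ensemble")
  expect_error(decode_individual(c(1L, 0L), pool), "match pool size")
})

test_that("fitness is the arithmetic mean of per-fold validation MCCs", {
  perfect <- store_with_fold_mccs(rep(1, 10))
  f <- evaluate_fitness(c(1L), perfect, rng_stream(1))
  expect_identical(f$fitness, 1)

  mixed <- store_with_fold_mccs(c(rep(0.8, 5), rep(0.6, 5)))
  f2 <- evaluate_fitness(c(1L), mixed, rng_stream(1))
  expect_equal(f2$fitness, 0.7, tolerance = 1e-12)
  expect_equal(f2$per_fold_mcc, c(rep(0.8, 5), rep(0.6, 5)),
               tolerance = 1e-12)
})

test_that("fitness evaluation is deterministic and memoised", {
  mp <- gen_mock_pool(6, n_per_fold = 30, seed = 2)
  bits <- c(1L, 1L, 0L, 1L, 0L, 0L)
  a <- evaluate_fitness(bits, mp, rng_stream(5))
  b <- evaluate_fitness(bits, mp, rng_stream(5))
  expect_identical(a, b)
  cache <- new.env()
  c1 <- evaluate_fitness(bits, mp, rng_stream(5), cache)
  c2 <- evaluate_fitness(bits, mp, rng_stream(99), cache)  # cache hit
  expect_identical(c1, c2)
})

test_that("tournament selection prefers fitness and degenerates correctly", {
  fits <- c(0.2, 0.9, 0.5, 0.4, 0.9)
  # exhaustive tournament always returns the global best (lowest index on tie)
  for (s in 1:5) {
    expect_identical(tournament_select(fits, 5, rng_stream(s)), 2L)
  }
  # tournament of 1 is a uniform draw; equal fitness is uniform too
  picks1 <- vapply(1:3000, function(s) {
    tournament_select(rep(0.5, 4), 1, rng_stream(s))
  }, integer(1))
  freq <- table(factor(picks1, levels = 1:4)) / 3000
  expect_true(all(abs(freq - 0.25) < 0.04))
  expect_error(tournament_select(numeric(0), 1, rng_stream(1)), "empty")
})

test_that("crossover honours its rate semantics", {
  p1 <- rep(1L, 10); p2 <- rep(0L, 10)
  expect_identical(uniform_crossover(p1, p1, 1, rng_stream(1)), p1)
  expect_identical(uniform_crossover(p1, p2, 0, rng_stream(2), fitter = 2L),
                   p2)
  # complementary parents at rate 1: per-bit origin is a fair coin
  bitsum <- Reduce(`+`, lapply(1:2000, function(s) {
    uniform_crossover(p1, p2, 1, rng_stream(s))
  }))
  expect_true(all(abs(bitsum / 2000 - 0.5) < 0.05))
  expect_error(uniform_crossover(p1, c(0L, 1L), 0.5, rng_stream(3)),
               "lengths differ")
})

test_that("mutation implements random replacement with all-zero repair", {
  bits <- c(1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L)
  expect_identical(mutate_bits(bits, 0, rng_stream(1)), bits)
  # replacement at rate 1: expected Hamming distance k/2
  dist <- vapply(1:2000, function(s) {
    sum(mutate_bits(bits, 1, rng_stream(s)) != bits)
  }, numeric(1))
  expect_equal(mean(dist), 4, tolerance = 0.15)
  # forced all-zero outcome repairs to exactly one set bit
  repaired <- mutate_bits(c(0L, 0L, 0L), 0, rng_stream(2))
  expect_identical(sum(repaired), 1L)
})

test_that("breeding preserves elites and closes over genotypes when inert", {
  mp <- gen_mock_pool(6, n_per_fold = 30, seed = 3)
  cfg <- ga_config(6, population_size = 12, tournament_size = 4,
                   crossover_rate = 0, mutation_rate = 0, seed = 1)
  rng <- rng_stream(4)
  pop <- replicate(12, {
    b <- as.integer(stream_runif(rng, 6) < 0.5)
    if (!any(b == 1L)) b[1L] <- 1L
    b
  }, simplify = FALSE)
  fits <- vapply(pop, function(b) {
    evaluate_fitness(b, mp, rng_stream(1))$fitness
  }, numeric(1))
  nxt <- next_generation(pop, fits, cfg, rng_stream(5))
  expect_length(nxt, 12L)
  expect_identical(nxt[[1L]], pop[[which.max(fits)]])  # elite verbatim
  keys <- vapply(pop, paste, character(1), collapse = "")
  expect_true(all(vapply(nxt, paste, character(1), collapse = "") %in% keys))
  # determinism on replay
  nxt2 <- next_generation(pop, fits, cfg, rng_stream(5))
  expect_identical(nxt, nxt2)
})

test_that("a perfect member triggers the optimum terminating condition", {
  y <- rep(c(0L, 1L), 15)
  pm <- rbind(y, 1L - y, rep(0L, 30))
  mp <- mock_pool(rep(list(pm), 10), rep(list(y), 10))
  res <- run_ga(ga_config(3, seed = 6), mp)
  expect_identical(res$termination_reason, "optimum")
  expect_identical(res$best_fitness, 1)
  expect_identical(res$best, c(1L, 0L, 0L))
})

test_that("a flat landscape stops by stagnation within the limit", {
  y <- rep(c(0L, 1L), 10)
  p <- y; p[1:4] <- 1L - y[1:4]
  pm <- rbind(p, p, p)  # identical imperfect members: every mask equal
  mp <- mock_pool(rep(list(pm), 5), rep(list(y), 5))
  res <- run_ga(ga_config(3, stagnation_limit = 50, seed = 7), mp)
  expect_identical(res$termination_reason, "stagnation")
  expect_lte(res$generations_run, 51L)
})

test_that("the search matches the exhaustive optimum on planted pools", {
  mp <- gen_mock_pool(8, seed = 21)
  hits <- 0L
  for (s in 1:5) {
    res <- run_ga(ga_config(8, seed = s), mp)
    expect_true(all(diff(res$fitness_history) >= 0))
    expect_lte(res$n_evaluations,
               ga_config(8)$population_size * (res$generations_run + 1))
    if (expected_fitness(res$best, mp) >= mp$true_best_fitness - 1e-9) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 4L)
})

test_that("replaying a seed reproduces the whole result bit for bit", {
  mp <- gen_mock_pool(7, n_per_fold = 30, seed = 8)
  r1 <- run_ga(ga_config(7, seed = 123), mp)
  r2 <- run_ga(ga_config(7, seed = 123), mp)
  expect_identical(r1, r2)
  r3 <- run_ga(ga_config(7, seed = 124), mp)
  expect_false(identical(r1$fitness_history, r3$fitness_history))
})
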