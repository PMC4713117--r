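test_that("a perfectly class-ordered feature gets one accepted cut", {
  x <- c(seq(-1, -0.1, length.out = 10), seq(0.1, 1, length.out = 10))
  y <- rep(c(0L, 1L), each = 10)
  ds <- dataset(cbind(good = x, const = rep(1, 20)), y)
  dds <- mdl_discretize_filter(ds)
  expect_identical(dds$kept_features, 1L)
  expect_length(dds$cutpoints[[1L]], 1L)
  expect_true(dds$cutpoints[[1L]] > -0.1 && dds$cutpoints[[1L]] < 0.1)
  expect_identical(as.integer(dds$codes[, 1L]), y)
})

test_that("label-independent features fail the MDL bound and are dropped", {
  rng <- rng_stream(123)
  x <- with_stream(rng, stats::rnorm(50))
  y <- with_stream(rng, as.integer(stats::runif(50) < 0.5))
  if (length(unique(y)) < 2L) y[1:2] <- c(0L, 1L)
  ds <- dataset(cbind(noise = x), y)
  # independent oracle: best single-cut gain vs the MDL threshold
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  ent <- function(v) {
    p <- mean(v == 1L)
    h <- 0
    if (p > 0) h <- h - p * log2(p)
    if (p < 1) h <- h - (1 - p) * log2(1 - p)
    h
  }
  gains <- vapply(which(diff(xs) > 0), function(i) {
    ent(ys) - (i / 50) * ent(ys[1:i]) - ((50 - i) / 50) * ent(ys[-(1:i)])
  }, numeric(1))
  best_i <- which(diff(xs) > 0)[which.max(gains)]
  y1 <- ys[1:best_i]; y2 <- ys[-(1:best_i)]
  delta <- log2(3^2 - 2) - (2 * ent(ys) - length(unique(y1)) * ent(y1) -
                              length(unique(y2)) * ent(y2))
  threshold <- (log2(49) + delta) / 50
  expect_lte(max(gains), threshold)   # oracle agrees the cut is unjustified
  dds <- mdl_discretize_filter(ds)
  expect_length(dds$kept_features, 0L)
})

test_that("discretization is invariant to strictly monotone transforms", {
  rng <- rng_stream(7)
  x <- with_stream(rng, stats::rnorm(60))
  y <- as.integer(x + with_stream(rng, stats::rnorm(60, sd = 0.3)) > 0)
  ds1 <- dataset(cbind(f = x), y)
  ds2 <- dataset(cbind(f = exp(2 * x)), y)   # strictly increasing transform
  d1 <- mdl_discretize_filter(ds1)
  d2 <- mdl_discretize_filter(ds2)
  expect_identical(d1$kept_features, d2$kept_features)
  expect_identical(d1$codes, d2$codes)
})

test_that("single-class input is rejected by the discretizer", {
  ds <- dataset(matrix(stats::rnorm(10), ncol = 1), rep(1L, 10))
  expect_error(mdl_discretize_filter(ds), "single-class")
})

test_that("a single perfect discriminator is selected alone", {
  codes <- cbind(f1 = c(0L, 0L, 1L, 1L), f2 = c(0L, 1L, 0L, 1L),
                 f3 = c(1L, 1L, 1L, 0L))
  dds <- discrete_dataset(codes, c(0L, 0L, 1L, 1L))
  expect_identical(ab_k_select(dds, alpha = 1, beta = 0), 1L)
  expect_identical(ab_k_select(dds, alpha = 1, beta = 0,
                               solver = "exhaustive"), 1L)
})

test_that("greedy matches the exhaustive minimum cardinality on toy instances", {
  for (seed in c(1, 2, 3)) {
    inst <- gen_toy_abk_instance(seed)
    g <- ab_k_select(inst$data, inst$alpha, inst$beta, solver = "greedy")
    e <- ab_k_select(inst$data, inst$alpha, inst$beta, solver = "exhaustive")
    expect_true(abk_satisfies(inst$data, g, inst$alpha, inst$beta))
    expect_true(abk_satisfies(inst$data, e, inst$alpha, inst$beta))
    expect_identical(length(e), inst$min_cardinality)
    expect_gte(length(g), length(e))
    # greedy set-cover guarantee: within H(#constraints) of the optimum
    n_pairs <- choose(nrow(inst$data$codes), 2)
    expect_lte(length(g), length(e) * sum(1 / seq_len(n_pairs)))
  }
})

test_that("infeasible alpha reports the violating pair, not a relaxed answer", {
  codes <- cbind(f1 = c(0L, 1L), f2 = c(0L, 1L))
  dds <- discrete_dataset(codes, c(0L, 1L))
  expect_error(ab_k_select(dds, alpha = 3), "infeasible")
  expect_error(ab_k_select(dds, alpha = 3), "maximum feasible alpha")
})

test_that("exhaustive solver refuses oversized universes", {
  codes <- rbind(rep(0L, 25), rep(1L, 25))
  colnames(codes) <- paste0("f", 1:25)
  dds <- discrete_dataset(codes, c(0L, 1L))
  expect_error(ab_k_select(dds, alpha = 1, solver = "exhaustive",
                           exhaustive_cap = 20), "cap")
})

test_that("consolidation implements plain set union and intersection", {
  expect_identical(consolidate_features(list(c(1L, 2L), c(2L, 3L)), "union"),
                   c(1L, 2L, 3L))
  expect_identical(
    consolidate_features(list(c(1L, 2L), c(2L, 3L)), "intersection"), 2L)
  expect_identical(consolidate_features(list(c(4L, 2L)), "union"), c(2L, 4L))
  expect_identical(consolidate_features(list(c(4L, 2L)), "intersection"),
                   c(2L, 4L))
  expect_error(consolidate_features(list()), "empty")
})
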