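#' Imbalanced two-class Gaussian feature table
#'
#' Two spherical unit-variance Gaussian classes whose means are
#' `separation` apart along the all-ones direction, with the minority
#' class labelled 1. `separation = 0` makes the classes
#' indistinguishable; large separations make a linear rule nearly
#' perfect. Deterministic per seed.
#'
#' @param n_minority,n_majority class sizes (>= 1).
#' @param n_features dimensionality.
#' @param separation Euclidean distance between class means (>= 0).
#' @param seed integer seed.
#' @return A `gaeoc_dataset` (minority rows first).
#' @export
gen_imbalanced_gaussian <- function(n_minority, n_majority, n_features = 5L,
                                    separation = 2, seed = 1L) {
  if (n_minority < 1L || n_majority < 1L) stop("class counts must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  rng <- rng_stream(seed)
  shift <- separation / sqrt(n_features)
  x <- with_stream(rng, {
    x1 <- matrix(stats::rnorm(n_minority * n_features, mean = shift),
                 nrow = n_minority)
    x0 <- matrix(stats::rnorm(n_majority * n_features, mean = 0),
                 nrow = n_majority)
    rbind(x1, x0)
  })
  dataset(x, c(rep(1L, n_minority), rep(0L, n_majority)),
          paste0("f", seq_len(n_features)),
          name = sprintf("gauss_%dv%d_sep%g_seed%d",
                         n_minority, n_majority, separation, seed))
}

#' Low-level mock classifier pool
#'
#' Wraps fixed per-fold validation predictions and labels in the same
#' interface as a trained model store, so ensemble fitness is exactly
#' computable without training anything. The exhaustive optimum over all
#' non-empty masks is certified by [enumerate_best_mask()] and stored.
#'
#' @param pred_matrix list over folds of k x fold-size 0/1 matrices.
#' @param fold_labels list over folds of 0/1 label vectors.
#' @return A `gaeoc_mock_pool` (also usable wherever a `gaeoc_store` is),
#'   with `true_best_mask` and `true_best_fitness` fields.
#' @export
mock_pool <- function(pred_matrix, fold_labels) {
  stopifnot(length(pred_matrix) == length(fold_labels))
  k <- nrow(pred_matrix[[1L]])
  for (f in seq_along(pred_matrix)) {
    stopifnot(nrow(pred_matrix[[f]]) == k,
              ncol(pred_matrix[[f]]) == length(fold_labels[[f]]))
  }
  store <- structure(
    list(pred_matrix = pred_matrix, fold_labels = fold_labels,
         pool_ids = sprintf("mock%02d", seq_len(k)),
         k = k, n_folds = length(pred_matrix)),
    class = c("gaeoc_mock_pool", "gaeoc_store")
  )
  best <- enumerate_best_mask(store)
  store$true_best_mask <- best$mask
  store$true_best_fitness <- best$fitness
  store
}

#' Exhaustive fitness maximum over all non-empty masks
#'
#' Brute-force enumeration of all 2^k - 1 ensembles, scoring each by the
#' same mean-fold-MCC rule the GA's fitness uses. Samples whose vote
#' splits exactly (possible for even ensembles) contribute their exact
#' expectation under the uniform tie rule: the expected MCC is summed over
#' the binomial distribution of tie resolutions, which is exact because
#' the MCC depends on the tied samples only through how many resolve
#' correctly per class. Ties in the maximum resolve to the lowest mask
#' index. Vote counts for all masks are formed by one matrix product per
#' fold, so enumeration at k = 12 stays fast.
#'
#' @param store a `gaeoc_store`-like object (k <= 16).
#' @return List with `mask` (0/1 vector) and `fitness`.
#' @export
enumerate_best_mask <- function(store) {
  k <- store$k
  if (k > 16L) stop("exhaustive certification limited to k <= 16")
  masks <- as.matrix(expand.grid(rep(list(0:1), k)))[-1L, , drop = FALSE]
  dimnames(masks) <- NULL
  km <- rowSums(masks)
  nm <- nrow(masks)
  acc <- numeric(nm)
  for (f in seq_len(store$n_folds)) {
    pm <- store$pred_matrix[[f]]
    y <- store$fold_labels[[f]]
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    votes <- masks %*% pm                 # masks x samples positive-vote counts
    pos <- votes * 2 > km                 # km recycles down columns = per mask
    tie <- votes * 2 == km
    tp0 <- as.vector(pos %*% (y == 1L))
    fp0 <- as.vector(pos %*% (y == 0L))
    t1 <- as.vector(tie %*% (y == 1L))
    t0 <- as.vector(tie %*% (y == 0L))
    # tie-free masks: closed-form MCC, vectorised
    fn <- n1 - tp0 - t1
    tn <- n0 - fp0 - t0
    num <- tp0 * tn - fp0 * fn
    den <- sqrt((tp0 + fp0) * (tp0 + fn) * (tn + fp0) * (tn + fn))
    m <- ifelse(den == 0, 0, num / den)
    tied <- which(t1 + t0 > 0L)
    for (i in tied) {
      m[i] <- expected_mcc_counts(tp0[i], fp0[i], n1, n0, t1[i], t0[i])
    }
    acc <- acc + m
  }
  fits <- acc / store$n_folds
  best <- which.max(fits)                 # ties -> lowest mask index
  list(mask = as.integer(masks[best, ]), fitness = fits[best])
}

#' Expected fitness of one mask under the uniform tie rule
#'
#' The same mean-fold-MCC quantity the GA optimises, but with exact-tie
#' samples contributing their expectation instead of a random draw —
#' deterministic, so suitable for certifying that a found mask attains
#' the enumerated optimum.
#'
#' @param bits 0/1 mask.
#' @param store a `gaeoc_store`-like object.
#' @return Expected mean MCC over folds.
#' @export
expected_fitness <- function(bits, store) {
  members <- which(as.integer(bits) == 1L)
  if (!length(members)) stop("empty mask")
  kk <- length(members)
  per_fold <- vapply(seq_len(store$n_folds), function(f) {
    pm <- store$pred_matrix[[f]][members, , drop = FALSE]
    s <- colSums(pm)
    y <- store$fold_labels[[f]]
    pos <- s * 2 > kk
    tie <- s * 2 == kk
    expected_mcc_counts(sum(pos & y == 1L), sum(pos & y == 0L),
                        sum(y == 1L), sum(y == 0L),
                        sum(tie & y == 1L), sum(tie & y == 0L))
  }, numeric(1))
  mean(per_fold)
}

# E[MCC] over binomial(1/2) resolutions of t1 positive-class and t0
# negative-class tied samples, given tie-free counts tp0/fp0 and class
# sizes n1/n0.
expected_mcc_counts <- function(tp0, fp0, n1, n0, t1, t0) {
  ev <- 0
  for (a in 0:t1) {
    wa <- stats::dbinom(a, t1, 0.5)
    for (b in 0:t0) {
      w <- wa * stats::dbinom(b, t0, 0.5)
      tp <- tp0 + a; fp <- fp0 + b
      fn <- n1 - tp; tn <- n0 - fp
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      ev <- ev + if (den == 0) 0 else w * (tp * tn - fp * fn) / sqrt(den)
    }
  }
  ev
}

#' Mock classifier pool with planted error structure
#'
#' Builds fixed per-fold validation labels (balanced 0/1) and per-member
#' prediction vectors, so ensemble fitness is exactly computable and the
#' optimal subset is certified by exhaustive enumeration with the same
#' fitness rule the search uses.
#'
#' By default the pool carries a planted structure emulating a realistic
#' heterogeneous pool: `n_planted` members are accurate (error rate
#' `planted_error`) with mutually independent errors — a diverse subset
#' whose majority vote is the clearly best ensemble — while the remaining
#' members are weaker (rates drawn from `background_error`) and share a
#' latent error mask (`background_correlation`), so combining them adds
#' little. Supplying `member_error_rates` (with `correlation`) overrides
#' the planting and gives every member the stated marginal rate with the
#' stated probability of following the shared latent mask.
#'
#' @param k pool size (<= 16 so the optimum can be certified).
#' @param n_per_fold validation samples per fold.
#' @param n_folds number of folds.
#' @param member_error_rates optional length-k vector (recycled) of
#'   marginal error rates in \[0, 1\]; NULL for the planted default.
#' @param correlation probability a member's error slot follows the
#'   shared latent mask rather than its own draw (used with
#'   `member_error_rates`).
#' @param n_planted number of planted accurate, diverse members (odd
#'   keeps the planted majority tie-free).
#' @param planted_error marginal error rate of planted members.
#' @param background_error range the remaining members' rates are drawn
#'   from.
#' @param background_correlation latent-mask weight of the remaining
#'   members.
#' @param seed integer seed.
#' @return A `gaeoc_mock_pool` (see [mock_pool()]), with `planted`
#'   (indices of planted members, if planted) and `member_error_rates`.
#' @export
gen_mock_pool <- function(k, n_per_fold = 70L, n_folds = 10L,
                          member_error_rates = NULL, correlation = 0,
                          n_planted = 3L, planted_error = 0.15,
                          background_error = c(0.30, 0.45),
                          background_correlation = 0.8,
                          seed = 1L) {
  if (k > 16L) stop("k must be <= 16 for exhaustive certification")
  rng <- rng_stream(seed)
  planted <- integer(0)
  if (is.null(member_error_rates)) {
    if (n_planted > k) stop("n_planted must not exceed k")
    planted <- sort(stream_sample(rng, seq_len(k), size = n_planted))
    rates <- with_stream(rng, stats::runif(k, background_error[1L],
                                           background_error[2L]))
    rates[planted] <- planted_error
    corr <- rep(background_correlation, k)
    corr[planted] <- 0
  } else {
    rates <- rep_len(member_error_rates, k)
    corr <- rep_len(correlation, k)
  }
  if (any(rates < 0 | rates > 1)) stop("error rates must lie in [0, 1]")
  if (any(corr < 0 | corr > 1)) stop("correlation must be in [0, 1]")
  pred_matrix <- vector("list", n_folds)
  fold_labels <- vector("list", n_folds)
  with_stream(rng, {
    for (f in seq_len(n_folds)) {
      y <- rep_len(c(0L, 1L), n_per_fold)
      latent <- stats::runif(n_per_fold)  # shared error propensity per sample
      pm <- matrix(0L, nrow = k, ncol = n_per_fold)
      for (i in seq_len(k)) {
        use_latent <- stats::runif(n_per_fold) < corr[i]
        own <- stats::runif(n_per_fold)
        u <- ifelse(use_latent, latent, own)
        err <- u < rates[i]
        pm[i, ] <- ifelse(err, 1L - y, y)
      }
      pred_matrix[[f]] <- pm
      fold_labels[[f]] <- y
    }
  })
  out <- mock_pool(pred_matrix, fold_labels)
  out$planted <- planted
  out$member_error_rates <- rates
  out
}

#' Toy discrete instance with a certified minimum (alpha, beta)-k answer
#'
#' A small discrete dataset (6 samples, 5 binary features) whose minimum
#' feasible feature set at the stored (alpha, beta) is found by subset
#' enumeration and shipped alongside the data, so greedy and exhaustive
#' solvers can be checked against an independent recount.
#'
#' @param seed integer seed (permutes feature columns so the answer is
#'   not positional).
#' @return List with `data` (a `gaeoc_discrete`), `alpha`, `beta`,
#'   `min_cardinality`, `min_set` (one certified minimum set, in permuted
#'   coordinates).
#' @export
gen_toy_abk_instance <- function(seed = 1L) {
  # base design: f1 separates classes perfectly; f2+f3 jointly give a
  # second difference for every inter-class pair; f4, f5 are noise
  codes <- rbind(
    c(0L, 0L, 0L, 0L, 1L),
    c(0L, 0L, 1L, 1L, 0L),
    c(0L, 1L, 0L, 0L, 1L),
    c(1L, 1L, 1L, 1L, 0L),
    c(1L, 0L, 1L, 0L, 1L),
    c(1L, 1L, 0L, 1L, 1L)
  )
  labels <- c(0L, 0L, 0L, 1L, 1L, 1L)
  rng <- rng_stream(seed)
  perm <- stream_sample(rng, seq_len(ncol(codes)))
  codes <- codes[, perm, drop = FALSE]
  colnames(codes) <- paste0("g", seq_len(ncol(codes)))
  dds <- discrete_dataset(codes, labels, name = sprintf("toy_abk_seed%d", seed))
  alpha <- 2L; beta <- 0L
  cert <- abk_enumerate_minimum(dds, alpha, beta)
  list(data = dds, alpha = alpha, beta = beta,
       min_cardinality = cert$cardinality, min_set = cert$set)
}

#' Independent brute-force minimum for (alpha, beta)-k instances
#'
#' Checks all subsets in order of cardinality with a direct pair recount
#' ([abk_satisfies()]); independent of the greedy/exhaustive solvers in
#' [ab_k_select()].
#'
#' @inheritParams ab_k_select
#' @return List with `cardinality` and `set`, or NULL if infeasible.
#' @export
abk_enumerate_minimum <- function(dds, alpha = 1L, beta = 0L) {
  p <- ncol(dds$codes)
  for (size in seq_len(p)) {
    combs <- utils::combn(p, size)
    for (ci in seq_len(ncol(combs))) {
      s <- combs[, ci]
      if (abk_satisfies(dds, s, alpha, beta)) {
        return(list(cardinality = size, set = s))
      }
    }
  }
  NULL
}
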