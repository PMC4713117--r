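#' Supervised entropy/MDL discretization with feature filtering
#'
#' Per feature, recursively picks the boundary cut point that minimises
#' the class-information entropy of the induced partition, accepting a cut
#' only when its information gain clears the minimum-description-length
#' threshold
#' gain > (log2(N - 1) + log2(3^c - 2) - c*Ent(S) + c1*Ent(S1) + c2*Ent(S2)) / N,
#' where c, c1, c2 count the classes present in the parent and child
#' intervals. Features for which no cut is accepted carry no class
#' information under this criterion and are dropped. Because only the rank
#' order of a feature's values matters, the result is invariant to any
#' strictly monotone transform.
#'
#' @param ds a binary `gaeoc_dataset` with >= 2 samples.
#' @return A `gaeoc_discrete` object: `codes` (samples x kept features,
#'   small non-negative integer interval codes), `labels`, `cutpoints`
#'   (list of sorted thresholds per kept feature), `kept_features`
#'   (column indices into the source), `feature_names`, `name`.
#' @export
mdl_discretize_filter <- function(ds) {
  stopifnot(inherits(ds, "gaeoc_dataset"))
  if (length(unique(ds$labels)) < 2L) {
    stop("entropy split undefined for single-class input")
  }
  if (n_samples(ds) < 2L) stop("need at least 2 samples")
  if (!all(ds$labels %in% c(0L, 1L))) stop("binary labels required")

  p <- ncol(ds$features)
  cuts <- vector("list", p)
  for (j in seq_len(p)) {
    cuts[[j]] <- mdlp_cuts(ds$features[, j], ds$labels)
  }
  kept <- which(lengths(cuts) > 0L)
  codes <- vapply(kept, function(j) {
    findInterval(ds$features[, j], cuts[[j]])
  }, integer(n_samples(ds)))
  if (length(kept) == 1L) codes <- matrix(codes, ncol = 1L)
  if (length(kept) == 0L) codes <- matrix(integer(0), nrow = n_samples(ds))
  colnames(codes) <- ds$feature_names[kept]
  discrete_dataset(codes, ds$labels, cuts[kept], kept,
                   ds$feature_names[kept], ds$name)
}

#' Discrete (interval-coded) dataset
#'
#' @param codes integer matrix of interval codes (samples x features).
#' @param labels binary label vector.
#' @param cutpoints list of sorted numeric thresholds per feature (may be
#'   empty lists for inherently discrete data).
#' @param kept_features indices into the source dataset's columns.
#' @param feature_names,name as in [dataset()].
#' @return A `gaeoc_discrete` object.
#' @export
discrete_dataset <- function(codes, labels,
                             cutpoints = rep(list(numeric(0)), ncol(codes)),
                             kept_features = seq_len(ncol(codes)),
                             feature_names = colnames(codes),
                             name = "discrete") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  labels <- as.integer(labels)
  stopifnot(nrow(codes) == length(labels))
  if (any(codes < 0L)) stop("codes must be non-negative")
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(codes)))
  structure(
    list(codes = codes, labels = labels, cutpoints = cutpoints,
         kept_features = as.integer(kept_features),
         feature_names = feature_names, name = name),
    class = "gaeoc_discrete"
  )
}

#' @export
print.gaeoc_discrete <- function(x, ...) {
  cat(sprintf("<gaeoc_discrete '%s': %d samples, %d kept feature(s)>\n",
              x$name, nrow(x$codes), ncol(x$codes)))
  invisible(x)
}

# Shannon entropy (base 2) of a binary label vector.
entropy2 <- function(y) {
  n <- length(y)
  if (n == 0L) return(0)
  p <- sum(y == 1L) / n
  h <- 0
  if (p > 0) h <- h - p * log2(p)
  if (p < 1) h <- h - (1 - p) * log2(1 - p)
  h
}

# Recursive minimum-entropy cut selection with the MDL stopping rule.
# Returns the sorted accepted cut points (possibly empty).
mdlp_cuts <- function(x, y) {
  ord <- order(x)
  rec <- function(xs, ys) {
    n <- length(xs)
    if (n < 2L) return(numeric(0))
    # candidate cuts: midpoints between adjacent distinct values
    distinct <- which(diff(xs) > 0)
    if (!length(distinct)) return(numeric(0))
    ent_s <- entropy2(ys)
    best_gain <- -Inf; best_i <- NA_integer_; best_e1 <- 0; best_e2 <- 0
    for (i in distinct) {
      y1 <- ys[seq_len(i)]; y2 <- ys[(i + 1L):n]
      e1 <- entropy2(y1); e2 <- entropy2(y2)
      gain <- ent_s - (i / n) * e1 - ((n - i) / n) * e2
      if (gain > best_gain) {
        best_gain <- gain; best_i <- i; best_e1 <- e1; best_e2 <- e2
      }
    }
    if (!is.finite(best_gain) || best_gain <= 0) return(numeric(0))
    y1 <- ys[seq_len(best_i)]; y2 <- ys[(best_i + 1L):n]
    c_all <- length(unique(ys))
    c1 <- length(unique(y1)); c2 <- length(unique(y2))
    delta <- log2(3^c_all - 2) -
      (c_all * ent_s - c1 * best_e1 - c2 * best_e2)
    threshold <- (log2(n - 1) + delta) / n
    if (best_gain <= threshold) return(numeric(0))
    cut <- (xs[best_i] + xs[best_i + 1L]) / 2
    left <- seq_len(best_i)
    c(rec(xs[left], ys[left]), cut, rec(xs[-left], ys[-left]))
  }
  sort(rec(x[ord], y[ord]))
}

#' (alpha, beta)-k minimum feature-set selection
#'
#' Finds a small set of features S such that every inter-class sample pair
#' differs on at least `alpha` features of S and every intra-class pair
#' agrees on at least `beta` features of S — jointly maximising inter-class
#' discrimination and intra-class equity. Difference/agreement is judged
#' on the discrete interval codes.
#'
#' The greedy solver repeatedly adds the feature that advances the most
#' still-unsatisfied pair constraints (ties to the lowest feature index);
#' the exhaustive solver enumerates subsets in order of cardinality and
#' returns a provably minimum feasible set. Infeasible (alpha, beta) are
#' reported — with the violating pair and the maximum feasible alpha at
#' the requested beta — rather than silently relaxed.
#'
#' @param dds a `gaeoc_discrete` (both classes present).
#' @param alpha minimum number of selected features on which every
#'   inter-class pair must differ (>= 1).
#' @param beta minimum number of selected features on which every
#'   intra-class pair must agree (>= 0).
#' @param solver `"greedy"` or `"exhaustive"`.
#' @param exhaustive_cap refuse exhaustive enumeration above this many
#'   features.
#' @return Integer vector of selected feature indices (columns of
#'   `dds$codes`), sorted.
#' @export
ab_k_select <- function(dds, alpha = 1L, beta = 0L,
                        solver = c("greedy", "exhaustive"),
                        exhaustive_cap = 20L) {
  solver <- match.arg(solver)
  stopifnot(inherits(dds, "gaeoc_discrete"))
  alpha <- as.integer(alpha); beta <- as.integer(beta)
  if (alpha < 1L) stop("alpha must be >= 1")
  if (beta < 0L) stop("beta must be >= 0")
  if (length(unique(dds$labels)) < 2L) stop("both classes must be present")
  p <- ncol(dds$codes)
  if (p == 0L) stop("no features to select from")

  cov <- abk_coverage(dds)   # pairs x features logical; TRUE = feature covers pair
  req <- ifelse(cov$inter, alpha, beta)
  keep <- req > 0L
  cov_m <- cov$m[keep, , drop = FALSE]
  req <- req[keep]
  pair_ids <- cov$pairs[keep, , drop = FALSE]

  # upfront feasibility: total coverage per pair must meet its requirement
  total <- rowSums(cov_m)
  bad <- which(total < req)
  if (length(bad)) {
    b <- bad[1L]
    max_alpha <- if (any(cov$inter[keep][bad])) {
      inter_rows <- cov$inter[keep]
      min(rowSums(cov_m[inter_rows, , drop = FALSE]))
    } else NA_integer_
    stop(sprintf(
      "(alpha=%d, beta=%d) infeasible: samples %d and %d share coverage on only %d feature(s)%s",
      alpha, beta, pair_ids[b, 1L], pair_ids[b, 2L], total[b],
      if (!is.na(max_alpha)) sprintf("; maximum feasible alpha at beta=%d is %d",
                                     beta, max_alpha) else ""))
  }

  if (nrow(cov_m) == 0L) return(integer(0))

  if (solver == "greedy") {
    selected <- integer(0)
    have <- integer(nrow(cov_m))
    repeat {
      unsat <- have < req
      if (!any(unsat)) break
      gains <- colSums(cov_m[unsat, , drop = FALSE])
      gains[selected] <- -1L
      j <- unname(which.max(gains))   # ties -> lowest index
      if (gains[j] <= 0L) stop("greedy solver stalled on a feasible instance")
      selected <- c(selected, j)
      have <- have + cov_m[, j]
    }
    return(sort(selected))
  }

  if (p > exhaustive_cap) {
    stop("exhaustive solver refused: ", p, " features exceeds cap of ",
         exhaustive_cap)
  }
  for (size in seq_len(p)) {
    combs <- utils::combn(p, size)
    for (ci in seq_len(ncol(combs))) {
      s <- combs[, ci]
      if (all(rowSums(cov_m[, s, drop = FALSE]) >= req)) return(s)
    }
  }
  stop("no feasible subset found")  # unreachable after feasibility check
}

# Pair-constraint coverage matrix: one row per sample pair, one column per
# feature; inter-class pairs are covered where codes differ, intra-class
# pairs where codes agree.
abk_coverage <- function(dds) {
  n <- nrow(dds$codes)
  pr <- utils::combn(n, 2L)
  i <- pr[1L, ]; j <- pr[2L, ]
  inter <- dds$labels[i] != dds$labels[j]
  diffm <- dds$codes[i, , drop = FALSE] != dds$codes[j, , drop = FALSE]
  m <- diffm
  m[!inter, ] <- !diffm[!inter, , drop = FALSE]
  list(m = m, inter = inter, pairs = cbind(i, j))
}

#' Verify that a feature set satisfies the (alpha, beta) constraints
#'
#' Direct pair enumeration; used post-hoc in tests and reports.
#'
#' @inheritParams ab_k_select
#' @param features integer feature indices to check.
#' @return TRUE/FALSE.
#' @export
abk_satisfies <- function(dds, features, alpha = 1L, beta = 0L) {
  if (!length(features)) return(FALSE)
  cov <- abk_coverage(dds)
  have <- rowSums(cov$m[, features, drop = FALSE])
  req <- ifelse(cov$inter, alpha, beta)
  all(have >= req)
}

#' Consolidate per-replicate feature sets
#'
#' Union or intersection of feature-index sets over one shared feature
#' universe — the consolidation step used when feature selection runs once
#' per balanced replicate.
#'
#' @param feature_sets non-empty list of integer index vectors.
#' @param mode `"union"` or `"intersection"`.
#' @return Sorted integer vector.
#' @export
consolidate_features <- function(feature_sets, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!length(feature_sets)) stop("empty list of feature sets")
  out <- Reduce(if (mode == "union") union else intersect, feature_sets)
  sort(as.integer(out))
}
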