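#' Class-distribution balancing by majority-class partitioning
#'
#' For an imbalanced two-class dataset, all minority-class samples are set
#' aside, the majority class is shuffled (seeded) and split into
#' q = max(1, round(n_majority / n_minority)) near-equal chunks, and each
#' chunk is paired with the full minority class to form q balanced
#' replicates. A dataset whose classes are already equal in size is passed
#' through as a single replicate. Every majority sample appears in exactly
#' one replicate, so the chunks partition the majority class.
#'
#' Remainder rows (when n_majority is not a multiple of q) are spread one
#' per chunk, keeping every replicate's imbalance within one sample of 1:1.
#' Within a replicate the original row order of the source dataset is kept.
#'
#' @param ds a binary `gaeoc_dataset`, both classes non-empty.
#' @param seed integer seed for the majority shuffle.
#' @return A `gaeoc_balanced` object: list with `replicates` (list of
#'   `gaeoc_dataset`), `source_name`, `minority_label`, `n_minority`,
#'   `n_majority`, and `majority_chunks` (the index partition, for audit).
#' @examples
#' ds <- gen_imbalanced_gaussian(90, 360, 5, separation = 2, seed = 1)
#' length(balance_dataset(ds, seed = 1)$replicates)  # 4
#' @export
balance_dataset <- function(ds, seed) {
  stopifnot(inherits(ds, "gaeoc_dataset"))
  cc <- class_counts(ds)
  if (n_samples(ds) == 0L) stop("empty dataset")
  if (length(cc) < 2L) stop("single-class dataset cannot be balanced")
  if (length(cc) > 2L) stop("balancing is defined for two-class data")
  minority_label <- as.integer(names(cc)[which.min(cc)])
  if (cc[1L] == cc[2L]) minority_label <- 1L  # balanced: positive class by convention
  n_min <- min(cc); n_maj <- max(cc)
  min_idx <- which(ds$labels == minority_label)
  maj_idx <- which(ds$labels != minority_label)

  if (n_min == n_maj) {
    return(structure(
      list(replicates = list(ds), source_name = ds$name,
           minority_label = minority_label, n_minority = n_min,
           n_majority = n_maj, majority_chunks = list(maj_idx)),
      class = "gaeoc_balanced"
    ))
  }

  q <- max(1L, as.integer(round(n_maj / n_min)))
  rng <- rng_stream(seed)
  shuffled <- stream_sample(rng, maj_idx)
  base <- n_maj %/% q
  extra <- n_maj %% q
  sizes <- rep(base, q) + c(rep(1L, extra), rep(0L, q - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  chunks <- lapply(seq_len(q), function(i) shuffled[starts[i]:ends[i]])

  replicates <- lapply(seq_len(q), function(i) {
    idx <- sort(c(min_idx, chunks[[i]]))
    dataset(ds$features[idx, , drop = FALSE], ds$labels[idx],
            ds$feature_names,
            name = sprintf("%s_bal%02d", ds$name, i),
            label_map = ds$label_map)
  })
  structure(
    list(replicates = replicates, source_name = ds$name,
         minority_label = minority_label, n_minority = n_min,
         n_majority = n_maj, majority_chunks = chunks),
    class = "gaeoc_balanced"
  )
}

#' @export
print.gaeoc_balanced <- function(x, ...) {
  cat(sprintf(
    "<gaeoc_balanced from '%s': %d replicate(s), minority=%d (n=%d), majority n=%d>\n",
    x$source_name, length(x$replicates), x$minority_label,
    x$n_minority, x$n_majority))
  invisible(x)
}
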