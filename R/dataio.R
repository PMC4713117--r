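#' Labelled tabular dataset
#'
#' The container every pipeline stage consumes: a numeric feature matrix,
#' an integer label vector (0/1 for binary tasks, arbitrary contiguous
#' codes for multiclass input awaiting one-vs-all decomposition), unique
#' feature names and a dataset name. The label map records how original
#' labels were coded.
#'
#' @param features numeric matrix, samples in rows.
#' @param labels integer vector, one label per row.
#' @param feature_names optional character vector; defaults to column names
#'   or `f1..fp`.
#' @param name dataset identifier.
#' @param label_map optional named integer vector mapping original label
#'   strings to codes.
#' @return A `gaeoc_dataset`.
#' @export
dataset <- function(features, labels, feature_names = NULL,
                    name = "dataset", label_map = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("features has ", nrow(features), " rows but labels has length ",
         length(labels))
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(features)))
  }
  if (length(feature_names) != ncol(features)) {
    stop("feature_names length must equal the number of feature columns")
  }
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (anyNA(features)) stop("missing values in features are not supported")
  if (anyNA(labels)) stop("missing labels are not supported")
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, name = name, label_map = label_map),
    class = "gaeoc_dataset"
  )
}

#' @export
print.gaeoc_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<gaeoc_dataset '%s': %d samples x %d features; classes: %s>\n",
              x$name, nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

n_samples <- function(ds) nrow(ds$features)

class_counts <- function(ds) {
  tab <- table(factor(ds$labels))
  stats::setNames(as.integer(tab), names(tab))
}

#' Majority/minority class ratio of a binary dataset
#'
#' @param ds a binary `gaeoc_dataset`.
#' @return n_majority / n_minority.
#' @export
imbalance_ratio <- function(ds) {
  cc <- class_counts(ds)
  if (length(cc) != 2L) stop("imbalance ratio is defined for two-class data")
  max(cc) / min(cc)
}

#' Read a labelled dataset from delimited text or ARFF
#'
#' CSV files must carry a header row; the label column is named explicitly.
#' For two-class data labels are recoded so the positive class is 1: the
#' class named by `positive_label` if given, otherwise the minority class
#' (ties broken toward the label sorting last, so \{neg,pos\} -> pos).
#' Multiclass labels are coded to contiguous integers 0..(K-1) in sorted
#' order, for later [one_vs_all()] decomposition. Row order is preserved
#' and the original-label coding is recorded in `label_map`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"delimited"` or `"arff"`.
#' @param label_column name of the label column.
#' @param positive_label optional original label to code as 1 (binary only).
#' @param name dataset name; defaults to the file stem.
#' @return A `gaeoc_dataset`.
#' @export
read_dataset <- function(path, format = c("auto", "delimited", "arff"),
                         label_column = "class", positive_label = NULL,
                         name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff" else "delimited"
  }
  df <- if (format == "arff") {
    foreign::read.arff(path)
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) stop("empty dataset file: ", path)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found; columns are: ",
         paste(names(df), collapse = ", "))
  }
  labels_raw <- as.character(df[[label_column]])
  feats <- df[setdiff(names(df), label_column)]
  bad <- names(feats)[!vapply(feats, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric feature column(s): ", paste(bad, collapse = ", "))
  }
  uniq <- sort(unique(labels_raw))
  if (length(uniq) <= 2L) {
    if (!is.null(positive_label)) {
      if (!positive_label %in% uniq) {
        stop("positive_label '", positive_label, "' not present in labels")
      }
      pos <- positive_label
    } else if (length(uniq) == 1L) {
      pos <- uniq  # single-class input: flagged, downstream stages reject it
    } else {
      cnt <- table(labels_raw)[uniq]
      pos <- uniq[order(cnt, -seq_along(uniq))][1L]  # minority class positive
    }
    map <- stats::setNames(as.integer(uniq == pos), uniq)
  } else {
    map <- stats::setNames(seq_along(uniq) - 1L, uniq)
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  dataset(as.matrix(feats), map[labels_raw], names(feats),
          name = name, label_map = map)
}

#' Write a dataset back to CSV
#'
#' Inverse of [read_dataset()] for delimited output; the label column holds
#' the integer codes.
#'
#' @param ds a `gaeoc_dataset`.
#' @param path output path.
#' @param label_column label column name.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, label_column = "class") {
  df <- as.data.frame(ds$features, check.names = FALSE)
  df[[label_column]] <- ds$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-vs-all binary decomposition
#'
#' Relabels the target class as positive (1) and every other class as 0,
#' preserving sample order. Applied once per class this partitions the
#' samples: each sample is positive in exactly one of the derived binary
#' problems.
#'
#' @param ds a `gaeoc_dataset` with >= 2 classes.
#' @param target_class label code to treat as positive.
#' @return A binary `gaeoc_dataset` named `<name>_vs_all_<target>`.
#' @export
one_vs_all <- function(ds, target_class) {
  labs <- unique(ds$labels)
  if (length(labs) < 2L) stop("one_vs_all needs at least two classes")
  if (!target_class %in% labs) {
    stop("target class ", target_class, " absent from label set")
  }
  dataset(ds$features, as.integer(ds$labels == target_class),
          ds$feature_names,
          name = paste0(ds$name, "_vs_all_", target_class),
          label_map = NULL)
}

#' Write a search-result manifest as JSON
#'
#' Serialises the best bitmask, selected member names, per-fold MCCs,
#' fitness, test metrics, seed and generation count. The document
#' round-trips losslessly through [read_report()], and identical results
#' produce byte-identical files.
#'
#' @param result named list; must contain `best_mask`, `members`,
#'   `per_fold_mcc`, `fitness`, `seed`, `generations`; `n_folds` (for
#'   validation) and arbitrary extra fields (e.g. `test_metrics`) allowed.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  required <- c("best_mask", "members", "per_fold_mcc", "fitness",
                "seed", "generations")
  miss <- setdiff(required, names(result))
  if (length(miss)) stop("result record incomplete; missing: ",
                         paste(miss, collapse = ", "))
  if (!is.null(result$n_folds) &&
      length(result$per_fold_mcc) != result$n_folds) {
    stop("per_fold_mcc has length ", length(result$per_fold_mcc),
         " but n_folds is ", result$n_folds)
  }
  jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
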