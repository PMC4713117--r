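#' Base-classifier specification
#'
#' A pool entry: a stable id, a coarse family tag, and `fit`/`predict`
#' closures. `fit(x, y)` receives a numeric matrix and an integer 0/1
#' vector and returns any model handle; `predict(model, x)` returns 0/1
#' predictions. Pools are ordered lists of these specs — bit i of a GA
#' individual refers to pool position i — so the search is completely
#' pool-agnostic and pools are pluggable.
#'
#' @param id unique classifier name.
#' @param family one of `"bayes"`, `"linear"`, `"svm"`, `"knn"`, `"rule"`,
#'   `"tree"`, `"baseline"`.
#' @param fit function(x, y) -> model.
#' @param predict function(model, x) -> 0/1 vector.
#' @param hyperparameters named list, recorded for provenance.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(id, family, fit, predict, hyperparameters = list()) {
  family <- match.arg(family,
    c("bayes", "linear", "svm", "knn", "rule", "tree", "baseline"))
  stopifnot(is.function(fit), is.function(predict))
  structure(list(id = id, family = family, fit = fit, predict = predict,
                 hyperparameters = hyperparameters),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec '%s' [%s]>\n", x$id, x$family))
  invisible(x)
}

validate_pool <- function(pool) {
  if (!length(pool)) stop("empty classifier pool")
  if (!all(vapply(pool, inherits, logical(1), "classifier_spec"))) {
    stop("pool entries must be classifier_spec objects")
  }
  ids <- vapply(pool, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("classifier ids must be unique within a pool")
  ids
}

pool_ids <- function(pool) vapply(pool, `[[`, character(1), "id")

as_binary_factor <- function(y) factor(y, levels = c("0", "1"))

# rpart with a given depth/cp; shared by several rule/tree analogues
rpart_spec <- function(id, family, maxdepth = 30L, cp = 0.01, minsplit = 20L) {
  classifier_spec(
    id, family,
    fit = function(x, y) {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- as_binary_factor(y)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = maxdepth,
                                                  cp = cp,
                                                  minsplit = minsplit,
                                                  xval = 0L))
    },
    predict = function(model, x) {
      as.integer(as.character(
        predict(model, data.frame(x, check.names = FALSE), type = "class")))
    },
    hyperparameters = list(maxdepth = maxdepth, cp = cp, minsplit = minsplit)
  )
}

naive_bayes_spec <- function(id, laplace = 0) {
  classifier_spec(
    id, "bayes",
    fit = function(x, y) e1071::naiveBayes(x, as_binary_factor(y), laplace = laplace),
    predict = function(model, x) as.integer(as.character(predict(model, x))),
    hyperparameters = list(laplace = laplace)
  )
}

svm_spec <- function(id, kernel) {
  classifier_spec(
    id, "svm",
    fit = function(x, y) e1071::svm(x, as_binary_factor(y), kernel = kernel,
                                    scale = apply(x, 2, stats::sd) > 0),
    predict = function(model, x) as.integer(as.character(predict(model, x))),
    hyperparameters = list(kernel = kernel)
  )
}

#' The default pool of 20 heterogeneous base classifiers
#'
#' Twenty named learners spanning Bayes, linear/function, kNN, rule and
#' tree families, built on established R implementations (e1071, rpart,
#' randomForest, ranger, class, nnet, MASS, stats::glm). The names mirror
#' common data-mining suites (NaiveBayes, SGD, IBk, J48, ...) but each is
#' an analogue chosen from R's ecosystem, not a re-implementation; the
#' search method is pool-agnostic and any pool of `classifier_spec`s can
#' be substituted. Near-duplicate entries (the two Gaussian naive Bayes
#' variants) are kept as distinct bits to preserve the 20-bit search
#' space. The final entry, ZeroR, always predicts the training majority
#' class.
#'
#' @param seed integer seed given to the stochastic learners (forests,
#'   random trees).
#' @return List of 20 `classifier_spec`s.
#' @export
default_pool <- function(seed = 1L) {
  glm_spec <- function(id) classifier_spec(
    id, "linear",
    fit = function(x, y) {
      df <- data.frame(x, check.names = FALSE); df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    predict = function(model, x) {
      p <- predict(model, data.frame(x, check.names = FALSE), type = "response")
      as.integer(p > 0.5)
    }
  )
  lda_spec <- classifier_spec(
    "SimpleLogistic", "linear",
    fit = function(x, y) MASS::lda(x, as_binary_factor(y)),
    predict = function(model, x) as.integer(as.character(predict(model, x)$class))
  )
  perceptron_spec <- classifier_spec(
    "VotedPerceptron", "linear",
    fit = function(x, y) {
      nnet::nnet(x, y, size = 0, skip = TRUE, entropy = TRUE,
                 maxit = 200, trace = FALSE)
    },
    predict = function(model, x) as.integer(predict(model, x) > 0.5)
  )
  knn_spec <- classifier_spec(
    "IBk", "knn",
    fit = function(x, y) list(x = x, y = y),  # lazy learner: store the data
    predict = function(model, x) {
      as.integer(as.character(class::knn(model$x, x, as_binary_factor(model$y), k = 1L)))
    },
    hyperparameters = list(k = 1L)
  )
  rf_spec <- function(id, ntree) classifier_spec(
    id, "tree",
    fit = function(x, y) {
      set.seed(seed)
      randomForest::randomForest(x, as_binary_factor(y), ntree = ntree)
    },
    predict = function(model, x) as.integer(as.character(predict(model, x))),
    hyperparameters = list(ntree = ntree, seed = seed)
  )
  random_tree_spec <- classifier_spec(
    "RandomTree", "rule",
    fit = function(x, y) {
      df <- data.frame(x, check.names = FALSE)
      df$.y <- as_binary_factor(y)
      ranger::ranger(.y ~ ., data = df, num.trees = 1L,
                     mtry = max(1L, floor(sqrt(ncol(x)))),
                     seed = seed, num.threads = 1L)
    },
    predict = function(model, x) {
      as.integer(as.character(
        predict(model, data.frame(x, check.names = FALSE),
                num.threads = 1L)$predictions))
    },
    hyperparameters = list(num.trees = 1L, seed = seed)
  )
  nnet_spec <- classifier_spec(
    "LMT", "tree",
    fit = function(x, y) {
      set.seed(seed)
      nnet::nnet(x, y, size = 2L, decay = 0.01, entropy = TRUE,
                 maxit = 200, trace = FALSE)
    },
    predict = function(model, x) as.integer(predict(model, x) > 0.5)
  )
  zero_r <- classifier_spec(
    "ZeroR", "baseline",
    fit = function(x, y) majority_label(y),
    predict = function(model, x) rep(model, nrow(x))
  )
  list(
    naive_bayes_spec("BayesNet", laplace = 1),
    naive_bayes_spec("NaiveBayes", laplace = 0),
    naive_bayes_spec("NaiveBayesUpdateable", laplace = 0),
    svm_spec("LibSVM", "radial"),
    glm_spec("Logistic"),
    svm_spec("SGD", "linear"),
    lda_spec,
    perceptron_spec,
    knn_spec,
    rpart_spec("DecisionTable", "rule", maxdepth = 2L),
    rpart_spec("JRip", "rule", maxdepth = 3L, minsplit = 10L),
    rpart_spec("OneR", "rule", maxdepth = 1L, cp = 0),
    rpart_spec("PART", "rule", cp = 0.001, minsplit = 5L),
    random_tree_spec,
    rpart_spec("REPTree", "rule"),
    zero_r,
    rpart_spec("DecisionStump", "tree", maxdepth = 1L),
    rpart_spec("J48", "tree", cp = 0.01),
    rf_spec("RandomForest", ntree = 100L),
    nnet_spec
  )
}

majority_label <- function(y) {
  tab <- table(factor(y, levels = c(0L, 1L)))
  as.integer(names(tab)[which.max(tab)])  # ties -> 0 (first level)
}

#' A cheap pool of k single-feature threshold learners
#'
#' Lightweight stand-ins for benchmarking the store machinery: member i
#' thresholds feature (i mod p) at the class-conditional midpoint; every
#' k-th member is a majority-class baseline. Useful when the point under
#' study is the search or the store, not learner quality.
#'
#' @param k pool size.
#' @return List of `classifier_spec`s.
#' @export
stump_pool <- function(k) {
  make_stump <- function(i) {
    classifier_spec(
      sprintf("stump%02d", i), "tree",
      fit = function(x, y) {
        j <- ((i - 1L) %% ncol(x)) + 1L
        m0 <- mean(x[y == 0L, j]); m1 <- mean(x[y == 1L, j])
        list(j = j, cut = (m0 + m1) / 2, flip = m1 < m0)
      },
      predict = function(model, x) {
        p <- as.integer(x[, model$j] > model$cut)
        if (model$flip) p <- 1L - p
        p
      }
    )
  }
  pool <- lapply(seq_len(k), make_stump)
  if (k >= 4L) {
    pool[[k]] <- classifier_spec(
      sprintf("baseline%02d", k), "baseline",
      fit = function(x, y) majority_label(y),
      predict = function(model, x) rep(model, nrow(x))
    )
  }
  pool
}
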