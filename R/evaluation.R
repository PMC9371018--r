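#' Built-in learner factories
#'
#' A learner is a list with \code{fit(X, y) -> fitted} and
#' \code{predict(fitted, X) -> labels}, where \code{X} is a numeric (one-hot)
#' matrix and \code{y} a factor. These factories wrap the standard engines a
#' practitioner would use: CART (\pkg{rpart}, Gini splits), random forest
#' (\pkg{randomForest}), support-vector machine and naive Bayes
#' (\pkg{e1071}) and a k-nearest-neighbour classifier (\pkg{class}). All keep
#' their packages' default hyperparameters; seeded engines are wrapped so a
#' factory's learner is deterministic.
#'
#' @param seed Seed for stochastic engines.
#' @param k Neighbour count for \code{learner_knn_class}.
#' @return A learner factory: a zero-argument function returning a learner.
#' @name learners
NULL

as_learner_df <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("x", seq_len(ncol(df)))
  df
}

#' @rdname learners
#' @export
learner_rpart <- function(seed = 1L) {
  function() list(
    fit = function(X, y) {
      if (!requireNamespace("rpart", quietly = TRUE)) stop("rpart not available")
      df <- as_learner_df(X); df$.y <- y
      with_seed(seed, rpart::rpart(.y ~ ., data = df, method = "class"))
    },
    predict = function(fitted, X) {
      as.character(stats::predict(fitted, as_learner_df(X), type = "class"))
    })
}

#' @rdname learners
#' @export
learner_forest <- function(seed = 1L) {
  function() list(
    fit = function(X, y) {
      if (!requireNamespace("randomForest", quietly = TRUE)) {
        stop("randomForest not available")
      }
      with_seed(seed, randomForest::randomForest(x = X, y = droplevels(y)))
    },
    predict = function(fitted, X) as.character(stats::predict(fitted, X)))
}

#' @rdname learners
#' @export
learner_svm <- function(seed = 1L) {
  function() list(
    fit = function(X, y) {
      if (!requireNamespace("e1071", quietly = TRUE)) stop("e1071 not available")
      with_seed(seed, e1071::svm(x = X, y = droplevels(y)))
    },
    predict = function(fitted, X) as.character(stats::predict(fitted, X)))
}

#' @rdname learners
#' @export
learner_naive_bayes <- function(seed = 1L) {
  function() list(
    fit = function(X, y) {
      if (!requireNamespace("e1071", quietly = TRUE)) stop("e1071 not available")
      list(model = e1071::naiveBayes(x = as_learner_df(X), y = droplevels(y)))
    },
    predict = function(fitted, X) {
      as.character(stats::predict(fitted$model, as_learner_df(X)))
    })
}

#' @rdname learners
#' @export
learner_knn_class <- function(k = 5L, seed = 1L) {
  function() list(
    fit = function(X, y) list(X = X, y = droplevels(y)),
    predict = function(fitted, X) {
      if (!requireNamespace("class", quietly = TRUE)) stop("class not available")
      with_seed(seed, as.character(
        class::knn(fitted$X, X, fitted$y, k = min(k, nrow(fitted$X)))))
    })
}

#' Majority-class stub learner
#'
#' Predicts the training majority label for every query; useful as a cheap
#' deterministic baseline in benchmarks and tests.
#' @rdname learners
#' @export
learner_majority <- function() {
  function() list(
    fit = function(X, y) {
      lv <- levels(y)
      list(label = lv[which.max(table(y))])
    },
    predict = function(fitted, X) rep(fitted$label, nrow(X)))
}

stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    # rotate fold ids so class remainders don't always land in fold 1
    fold <- ((fold + sample.int(k, 1L) - 1L) %% k) + 1L
  })
  fold
}

#' Repeated stratified k-fold classification accuracy
#'
#' Scores a complete table by downstream classification: per repeat, rows are
#' dealt into \code{k} stratified folds from a seeded shuffle; each fold in
#' turn is the test set (train:test 9:1 at k = 10) and the classifier is
#' fitted on the one-hot encoded features of the remaining rows. The repeat's
#' accuracy is the mean over folds; the function returns mean and standard
#' deviation over repeats.
#'
#' @param table A complete \code{discrete_table} with a class column.
#' @param classifier_factory A learner factory (see \code{\link{learners}}).
#' @param k Number of folds (>= 2, default 10).
#' @param repeats Number of repeats (default 5).
#' @param seed RNG seed for fold assignment.
#' @return List with \code{mean}, \code{sd} and \code{per_repeat} accuracies.
#' @export
repeated_kfold_accuracy <- function(table, classifier_factory, k = 10L,
                                    repeats = 5L, seed = 1L) {
  if (any(missing_mask(table))) stop("evaluation requires a complete table")
  ci <- class_attr(table$schema)
  if (ci == 0L) stop("the schema declares no class attribute")
  stopifnot(k >= 2L, repeats >= 1L)
  layout <- onehot_layout(table$schema, table)
  feat <- setdiff(seq_along(table$schema$attributes), ci)
  X <- encode_one_hot(table, layout, attrs = feat)
  y <- factor(table$data[[ci]], levels = schema_domain(table$schema, ci))
  per_repeat <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(as.character(y), k, derive_seed(seed, r))
    acc <- numeric(k)
    for (f in seq_len(k)) {
      test <- fold == f
      if (!any(test)) { acc[f] <- NA; next }
      ytr <- y[!test]
      if (length(unique(ytr)) < length(unique(y))) {
        warning("a class is absent from a training fold; fold kept")
      }
      learner <- classifier_factory()
      fitted <- learner$fit(X[!test, , drop = FALSE], ytr)
      pred <- learner$predict(fitted, X[test, , drop = FALSE])
      acc[f] <- mean(pred == as.character(y[test]))
    }
    per_repeat[r] <- mean(acc, na.rm = TRUE)
  }
  list(mean = mean(per_repeat),
       sd = if (repeats > 1L) stats::sd(per_repeat) else 0,
       per_repeat = per_repeat)
}

#' Built-in imputer registry for benchmarking
#'
#' Returns a named list of imputer functions with the uniform signature
#' \code{function(table, mechanism, seed)}, covering the nine methods the
#' benchmark compares: mode, random, hot-deck, knn, tree, forest,
#' autoencoder, mlp and the momentum-trained per-type network (\code{imlp}).
#'
#' @param methods Character vector of method names to include.
#' @param config \code{\link{train_config}} for the network-based methods.
#' @param k Neighbour count for the knn imputer.
#' @return Named list of imputer functions.
#' @export
imputer_registry <- function(methods = c("mode", "random", "hotdeck", "knn",
                                         "tree", "forest", "autoencoder",
                                         "mlp", "imlp"),
                             config = train_config(), k = 5L) {
  all <- list(
    mode = function(table, mechanism, seed) impute_mode(table),
    random = function(table, mechanism, seed) impute_random(table, seed = seed),
    hotdeck = function(table, mechanism, seed) impute_hotdeck(table),
    knn = function(table, mechanism, seed) impute_knn(table, k = k),
    tree = function(table, mechanism, seed) {
      impute_learner(table, learner_rpart(seed = seed))
    },
    forest = function(table, mechanism, seed) {
      impute_learner(table, learner_forest(seed = seed))
    },
    autoencoder = function(table, mechanism, seed) {
      cfg <- config; cfg$seed <- seed
      impute_autoencoder(table, cfg)
    },
    mlp = function(table, mechanism, seed) {
      cfg <- config; cfg$seed <- seed
      impute_mlp(table, cfg)
    },
    imlp = function(table, mechanism, seed) {
      cfg <- config; cfg$seed <- seed
      impute_typed_mlp(table, mechanism, cfg)
    })
  all[match.arg(methods, names(all), several.ok = TRUE)]
}

# Deterministic small integer from a cell key, for per-cell seeds.
key_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "|")
  h <- sum(utf8ToInt(key) * (seq_len(nchar(key)) %% 97 + 1))
  derive_seed(seed, h %% 1e6)
}

#' Run the full imputation benchmark grid
#'
#' For every (dataset, mechanism, rate) a complete table is amputed once with
#' a per-cell derived seed; every imputer then fills that same amputed table
#' (method comparisons are paired on identical masks) and every classifier
#' scores the filled table by \code{\link{repeated_kfold_accuracy}}. An
#' un-amputed "origin" control row is evaluated per (dataset, classifier).
#' Per-cell failures are recorded and the grid continues. The result is
#' independent of grid ordering: every cell's seed derives only from its key.
#'
#' @param datasets Named list of complete \code{discrete_table}s.
#' @param mechanisms Character vector among \code{"MCAR"}, \code{"MAR"},
#'   \code{"NMAR"}.
#' @param rates Numeric vector of missing rates (default the canonical grid
#'   \code{seq(0.10, 0.30, by = 0.05)}).
#' @param imputers Named list of imputer functions
#'   \code{function(table, mechanism, seed)}; see
#'   \code{\link{imputer_registry}}.
#' @param classifiers Named list of learner factories.
#' @param k,repeats Cross-validation folds and repeats.
#' @param seed Master seed; all per-cell seeds derive from it.
#' @return A data frame with one row per grid cell: \code{dataset},
#'   \code{mechanism}, \code{rate}, \code{imputer}, \code{classifier},
#'   \code{mean_accuracy}, \code{sd_accuracy}, \code{repeats}, \code{status}.
#' @export
run_benchmark <- function(datasets, mechanisms = c("MCAR", "MAR", "NMAR"),
                          rates = seq(0.10, 0.30, by = 0.05),
                          imputers = imputer_registry(),
                          classifiers = list(majority = learner_majority()),
                          k = 10L, repeats = 5L, seed = 1L) {
  stopifnot(length(datasets) > 0, !is.null(names(datasets)),
            length(imputers) > 0, length(classifiers) > 0)
  rows <- list()
  add <- function(ds, mech, rate, imp, clf, res, status = "ok") {
    rows[[length(rows) + 1L]] <<- data.frame(
      dataset = ds, mechanism = mech, rate = rate, imputer = imp,
      classifier = clf,
      mean_accuracy = if (is.null(res)) NA_real_ else res$mean,
      sd_accuracy = if (is.null(res)) NA_real_ else res$sd,
      repeats = repeats, status = status, stringsAsFactors = FALSE)
  }
  for (ds in names(datasets)) {
    tab <- datasets[[ds]]
    for (clf in names(classifiers)) {
      res <- tryCatch(
        repeated_kfold_accuracy(tab, classifiers[[clf]], k = k,
                                repeats = repeats,
                                seed = key_seed(seed, ds, "eval", clf)),
        error = function(e) NULL)
      add(ds, "origin", 0, "origin", clf, res,
          if (is.null(res)) "error" else "ok")
    }
    for (mech in mechanisms) {
      for (rate in rates) {
        amp <- tryCatch(
          ampute(tab, ampute_config(mech, rate,
                                    seed = key_seed(seed, ds, mech, rate))),
          error = function(e) NULL)
        for (imp in names(imputers)) {
          filled <- if (is.null(amp)) NULL else tryCatch(
            imputers[[imp]](amp, mech, key_seed(seed, ds, mech, rate, imp)),
            error = function(e) NULL)
          for (clf in names(classifiers)) {
            if (is.null(filled)) {
              add(ds, mech, rate, imp, clf, NULL, "error")
              next
            }
            res <- tryCatch(
              repeated_kfold_accuracy(filled, classifiers[[clf]], k = k,
                                      repeats = repeats,
                                      seed = key_seed(seed, ds, "eval", clf)),
              error = function(e) NULL)
            add(ds, mech, rate, imp, clf, res,
                if (is.null(res)) "error" else "ok")
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate benchmark results over missing rates
#'
#' @param results Output of \code{\link{run_benchmark}}.
#' @return A data frame averaged over rates per (dataset, mechanism, imputer,
#'   classifier).
#' @export
aggregate_benchmark <- function(results) {
  r <- results[results$status == "ok" & results$mechanism != "origin", ]
  agg <- stats::aggregate(mean_accuracy ~ dataset + mechanism + imputer + classifier,
                          data = r, FUN = mean)
  names(agg)[names(agg) == "mean_accuracy"] <- "accuracy_over_rates"
  agg[order(agg$dataset, agg$mechanism, agg$classifier, agg$imputer), ]
}
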