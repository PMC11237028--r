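#' Model configuration for the prediction benchmark
#'
#' @param kind One of `recurrent`, `bidirectional_recurrent`,
#'   `boosted_ensemble`, `bagged_trees`, `bagged_neighbors`,
#'   `multilayer_perceptron`.
#' @param layers,hidden_units,learning_rate,max_epochs Network
#'   hyperparameters; the recurrent default is 2 layers of 128 cells,
#'   learning rate 0.01, at most 100 epochs, with a log-softmax head.
#' @param ... Extra kind-specific settings (`ntree`, `nrounds`, `n_neighbors`,
#'   `bags`), recorded in the config.
#' @return A `model_config` list.
#' @export
model_config <- function(kind, layers = 2L, hidden_units = 128L,
                         learning_rate = 0.01, max_epochs = 100L, ...) {
  kind <- match.arg(kind, c("recurrent", "bidirectional_recurrent",
                            "boosted_ensemble", "bagged_trees",
                            "bagged_neighbors", "multilayer_perceptron"))
  structure(list(kind = kind, layers = as.integer(layers),
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 output_head = "log_softmax", ...),
            class = "model_config")
}

#' The six benchmark model configurations
#'
#' The two recurrent models use the headline hyperparameters (2 x 128,
#' learning rate 0.01, 100 epochs); the others use their libraries'
#' customary defaults, recorded in each config.
#'
#' @param max_epochs Epoch budget for the networks (reduce for quick runs).
#' @param hidden_units Hidden size for the networks.
#' @return Named list of [model_config()]s.
#' @export
default_model_configs <- function(max_epochs = 100L, hidden_units = 128L) {
  list(
    multilayer_perceptron = model_config("multilayer_perceptron", layers = 1L,
                                         hidden_units = 32L,
                                         max_epochs = max_epochs),
    bagged_neighbors = model_config("bagged_neighbors", n_neighbors = 5L, bags = 10L),
    boosted_ensemble = model_config("boosted_ensemble", nrounds = 50L,
                                    max_depth = 3L),
    bagged_trees = model_config("bagged_trees", ntree = 100L),
    bidirectional_recurrent = model_config("bidirectional_recurrent",
                                           hidden_units = hidden_units,
                                           max_epochs = max_epochs),
    recurrent = model_config("recurrent", hidden_units = hidden_units,
                             max_epochs = max_epochs)
  )
}

# deterministic flattening of a sequence batch to day-level rows
# (patient-major, then day order)
flatten_days <- function(X) {
  n <- dim(X)[1]; T_ <- dim(X)[2]; p <- dim(X)[3]
  out <- matrix(NA_real_, n * T_, p)
  for (j in seq_len(p)) out[, j] <- as.vector(t(X[, , j]))
  colnames(out) <- dimnames(X)[[3]]
  out
}

#' Build a trainable classifier from a configuration
#'
#' Sequence models (`recurrent`, `bidirectional_recurrent`) consume per-day
#' feature arrays `x(0..T-1)` (an `n x T x p` array) and emit per-day
#' log-probabilities for the two classes.  Static models consume day-level
#' feature vectors; a sequence array is flattened deterministically
#' (patient-major, day order) into rows, and their probabilistic outputs are
#' wrapped into the same log-probability head.
#'
#' @param config A [model_config()].
#' @return An object of class `nfabt_model` with closures `fit(X, y, seed)`
#'   (returns a fitted state) and `predict(state, X)` (returns `n x T x 2`
#'   per-day class log-probabilities).
#' @export
make_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  kind <- config$kind
  seq_model <- kind %in% c("recurrent", "bidirectional_recurrent")

  logp_from_p1 <- function(p1m) {  # n x T matrix of P(class 1)
    # numeric floor keeps log finite for hard 0/1 votes
    p1m <- pmin(pmax(p1m, 1e-12), 1 - 1e-12)
    arr <- array(NA_real_, c(nrow(p1m), ncol(p1m), 2L))
    arr[, , 1L] <- log(1 - p1m)
    arr[, , 2L] <- log(p1m)
    arr
  }

  if (seq_model) {
    fit <- function(X, y, seed = 1L) {
      lstm_train(X, y, hidden = config$hidden_units, layers = config$layers,
                 lr = config$learning_rate, epochs = config$max_epochs,
                 seed = seed,
                 bidirectional = kind == "bidirectional_recurrent")
    }
    pred <- function(state, X) lstm_forward(state, X)
  } else {
    fit <- function(X, y, seed = 1L) {
      xs <- flatten_days(X)
      ys <- as.vector(t(y))
      with_seed(seed, switch(kind,
        multilayer_perceptron = nnet::nnet(
          xs, ys, size = config$hidden_units, maxit = config$max_epochs,
          entropy = TRUE, trace = FALSE,
          MaxNWts = (ncol(xs) + 2L) * config$hidden_units + 1000L),
        bagged_trees = randomForest::randomForest(
          xs, factor(ys, levels = c(0, 1)), mtry = ncol(xs),
          ntree = config$ntree %||% 100L),
        boosted_ensemble = xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = config$max_depth %||% 3L,
                        nthread = 1L),
          data = xgboost::xgb.DMatrix(xs, label = ys),
          nrounds = config$nrounds %||% 50L, verbose = 0),
        bagged_neighbors = {
          n <- nrow(xs)
          bags <- config$bags %||% 10L
          idx <- lapply(seq_len(bags), function(b) {
            sample(n, n, replace = TRUE)
          })
          list(x = xs, y = ys, idx = idx, k = config$n_neighbors %||% 5L,
               seed = seed)
        }))
    }
    pred <- function(state, X) {
      n <- dim(X)[1]; T_ <- dim(X)[2]
      xs <- flatten_days(X)
      p1 <- switch(kind,
        multilayer_perceptron = as.vector(stats::predict(state, xs)),
        bagged_trees = stats::predict(state, xs, type = "prob")[, "1"],
        boosted_ensemble = stats::predict(state, xgboost::xgb.DMatrix(xs)),
        bagged_neighbors = with_seed(state$seed + 999L, {
          # knn breaks distance ties randomly; seed for reproducibility
          votes <- vapply(state$idx, function(ii) {
            as.integer(as.character(class::knn(
              state$x[ii, , drop = FALSE], xs,
              factor(state$y[ii], levels = c(0, 1)), k = state$k)))
          }, integer(nrow(xs)))
          rowMeans(matrix(votes, nrow(xs)))
        }))
      # flatten_days is patient-major: row i of the reshape is patient i
      logp_from_p1(matrix(p1, n, T_, byrow = TRUE))
    }
  }
  structure(list(config = config, fit = fit, predict = pred),
            class = "nfabt_model")
}

# day-level feature array (n x T x p), labels (n x T) and ids from a cohort
cohort_arrays <- function(cohort, features = NULL) {
  if (is.null(cohort$panel) || is.null(cohort$labels)) {
    stop("cohort needs trajectories and daily labels")
  }
  p <- cohort$panel
  if (is.null(features)) {
    features <- setdiff(names(p), c("id", "day"))
    features <- features[vapply(p[features], is.numeric, TRUE)]
  }
  ids <- unique(p$id)
  T_ <- max(p$day) + 1L
  X <- array(NA_real_, c(length(ids), T_, length(features)),
             dimnames = list(ids, NULL, features))
  ord <- order(match(p$id, ids), p$day)
  for (j in seq_along(features)) {
    X[, , j] <- matrix(p[[features[j]]][ord], length(ids), T_, byrow = TRUE)
  }
  l <- cohort$labels
  lord <- order(match(l$id, ids), l$day)
  y <- matrix(l$prbc[lord], length(ids), T_, byrow = TRUE)
  if (anyNA(X)) stop("missing feature cells; impute before benchmarking")
  list(X = X, y = y, ids = ids)
}

#' Cross-validated day-level accuracy of one model
#'
#' Patient-level k-fold cross-validation: folds partition patients, so no
#' patient contributes days to both the training and test side of a fold.
#' Per run, the model is refit on each fold's training patients and day-level
#' labels on the held-out patients are scored; the run's accuracy pools all
#' held-out days.  Folds and fits are reseeded per run; a training fold
#' containing a single class is reported and skipped.
#'
#' @param cohort A preprocessed cohort with daily labels.
#' @param config A [model_config()].
#' @param folds Number of folds (default 5).
#' @param runs Number of repeated runs (default 10).
#' @param seed Integer seed; run r derives its folds from `seed + r`.
#' @param features Panel features to use (default: all numeric).
#' @return A list (class `cv_result`): `kind`, `mean_accuracy` (percent),
#'   `accuracies` (per run), `folds`, `runs`, `seed`.
#' @export
run_cv <- function(cohort, config, folds = 5L, runs = 10L, seed = 1L,
                   features = NULL) {
  arr <- cohort_arrays(cohort, features)
  n <- length(arr$ids)
  if (n < folds) stop("fewer patients than folds")
  model <- make_model(config)
  acc <- vapply(seq_len(runs), function(r) {
    run_seed <- as.integer(seed) + r
    fold_id <- with_seed(run_seed, sample(rep_len(seq_len(folds), n)))
    pred <- rep(NA_integer_, n * dim(arr$y)[2])
    truth <- as.vector(arr$y)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      ytr <- arr$y[tr, , drop = FALSE]
      if (length(unique(as.vector(ytr))) < 2L) {
        warning("single-class training fold skipped (run ", r,
                ", fold ", f, ")")
        next
      }
      st <- model$fit(arr$X[tr, , , drop = FALSE], ytr,
                      seed = run_seed * 10L + f)
      lp <- model$predict(st, arr$X[!tr, , , drop = FALSE])
      cls <- (lp[, , 2L, drop = FALSE] > lp[, , 1L, drop = FALSE])[, , 1L]
      idx <- which(rep(!tr, times = dim(arr$y)[2]))
      pred[idx] <- as.integer(cls)
    }
    keep <- !is.na(pred)
    100 * mean(pred[keep] == truth[keep])
  }, numeric(1))
  structure(list(kind = config$kind, mean_accuracy = mean(acc),
                 accuracies = acc, folds = folds, runs = runs, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s: mean day-level accuracy %.1f%% over %d run(s) of %d-fold CV\n",
              x$kind, x$mean_accuracy, x$runs, x$folds))
  invisible(x)
}

#' Benchmark several models on identical folds
#'
#' Runs [run_cv()] for each configuration with the same seeds, so every
#' model sees identical patient fold assignments in each run, and reports
#' mean percent accuracies.
#'
#' @inheritParams run_cv
#' @param configs Named list of [model_config()]s (default: the six shipped
#'   configurations).
#' @return A `bench_result`: list with `per_model` (one `cv_result` each),
#'   `folds`, `runs`, `seed`; `as.data.frame()` gives the ranking table.
#' @export
compare_models <- function(cohort, configs = default_model_configs(),
                           folds = 5L, runs = 10L, seed = 1L,
                           features = NULL) {
  if (length(configs) < 2L) stop("need at least 2 configurations")
  per <- lapply(configs, function(cfg) {
    run_cv(cohort, cfg, folds = folds, runs = runs, seed = seed,
           features = features)
  })
  structure(list(per_model = per, folds = folds, runs = runs, seed = seed),
            class = "bench_result")
}

#' @export
as.data.frame.bench_result <- function(x, ...) {
  d <- data.frame(
    method = vapply(x$per_model, `[[`, "", "kind"),
    mean_accuracy = vapply(x$per_model, `[[`, 0, "mean_accuracy")
  )
  rownames(d) <- NULL
  d[order(d$mean_accuracy), , drop = FALSE]
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("Mean day-level prediction accuracy (%%), %d runs of %d-fold CV\n",
              x$runs, x$folds))
  d <- as.data.frame(x)
  d$mean_accuracy <- sprintf("%.1f", d$mean_accuracy)
  print(d, row.names = FALSE)
  invisible(x)
}
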