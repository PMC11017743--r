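#' Interval-forest classifiers for calcium traces
#'
#' @description
#' Two forest-based time-series classifiers built from random intervals of
#' the input trace, each interval's features feeding a CART decision tree,
#' with the ensemble prediction taken by majority vote:
#'
#' * **TSF (time series forest)** — each tree sees `sqrt(m)` random
#'   intervals of an `m`-frame trace and, per interval, three summary
#'   features: mean, standard deviation and least-squares slope.
#' * **RISE (random interval spectral ensemble)** — each tree sees one
#'   random interval (the first tree the whole series) converted to
#'   spectral coefficients: autocorrelations, Yule-Walker autoregressive
#'   coefficients and periodogram magnitudes, zero-padded to a fixed
#'   length.
#'
#' A trained model records its training length in frames and refuses to
#' score traces longer than that: the number of frames used for testing
#' must not exceed the number of frames used for training.
#'
#' @param train A [training_set()] containing both classes.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed; training is bit-reproducible from it.
#' @param min_interval_length Minimum interval length in frames
#'   (3 for TSF, 16 for RISE).
#' @param normalization_mode `"dff0"` or `"raw"`: which trace scale the
#'   model was trained on (recorded for prediction-time checks).
#'
#' @return An object of class `forest_model`.
#' @name interval_forests
NULL

MODEL_FORMAT_VERSION <- 1L

check_two_classes <- function(train) {
  if (train$metadata$n_segments == 0L) {
    stop("training set is empty", call. = FALSE)
  }
  if (train$metadata$n_active == 0L || train$metadata$n_inactive == 0L) {
    stop("training requires both classes; got ",
         train$metadata$n_active, " active and ",
         train$metadata$n_inactive, " inactive segments", call. = FALSE)
  }
}

fit_tree <- function(features, labels) {
  d <- as.data.frame(features)
  d$.y <- factor(labels, levels = c("inactive", "active"))
  rpart::rpart(.y ~ ., data = d, method = "class",
               control = rpart::rpart.control(
                 minsplit = 5, cp = 0.005, xval = 0,
                 maxcompete = 0, maxsurrogate = 0))
}

#' @rdname interval_forests
#' @export
train_tsf <- function(train, n_trees = 500, seed = 1L,
                      min_interval_length = 3L,
                      normalization_mode = "dff0") {
  stopifnot(inherits(train, "training_set"))
  check_two_classes(train)
  m <- train$metadata$segment_length
  n_int <- max(1L, floor(sqrt(m)))
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(b) {
      iv <- sample_intervals(m, n_int, min_interval_length)
      feats <- tsf_features(train$segments, iv)
      list(intervals = iv, tree = fit_tree(feats, train$labels))
    })
  })
  structure(list(
    algorithm = "TSF", trees = trees, n_trees = as.integer(n_trees),
    training_length = m, sampling_rate = train$sampling_rate,
    class_labels = c("inactive", "active"), seed = as.integer(seed),
    normalization_mode = normalization_mode,
    format_version = MODEL_FORMAT_VERSION),
    class = "forest_model")
}

#' @rdname interval_forests
#' @export
train_rise <- function(train, n_trees = 500, seed = 1L,
                       min_interval_length = 16L,
                       normalization_mode = "dff0") {
  stopifnot(inherits(train, "training_set"))
  check_two_classes(train)
  m <- train$metadata$segment_length
  layout <- rise_layout(m)
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(b) {
      iv <- if (b == 1L) c(start = 1L, end = m) else {
        sample_rise_interval(m, min_interval_length, layout$ar_order)
      }
      feats <- rise_features(train$segments, iv, layout)
      list(intervals = rbind(iv), tree = fit_tree(feats, train$labels))
    })
  })
  structure(list(
    algorithm = "RISE", trees = trees, n_trees = as.integer(n_trees),
    training_length = m, sampling_rate = train$sampling_rate,
    class_labels = c("inactive", "active"), seed = as.integer(seed),
    normalization_mode = normalization_mode,
    feature_layout = layout,
    format_version = MODEL_FORMAT_VERSION),
    class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf(
    "<forest_model> %s: %d trees, training_length %d frames @ %.4g Hz (seed %d)\n",
    x$algorithm, x$n_trees, x$training_length, x$sampling_rate, x$seed))
  invisible(x)
}

# Per-segment matrix of tree votes ("active"/"inactive"), segments x trees.
forest_votes <- function(model, X) {
  votes <- matrix("", nrow(X), length(model$trees))
  for (b in seq_along(model$trees)) {
    tr <- model$trees[[b]]
    feats <- if (model$algorithm == "TSF") {
      tsf_features(X, tr$intervals)
    } else {
      rise_features(X, tr$intervals[1L, ], model$feature_layout)
    }
    votes[, b] <- as.character(
      predict(tr$tree, as.data.frame(feats), type = "class"))
  }
  votes
}

#' Predict activity labels with a trained forest
#'
#' Scores each trace by majority vote over the ensemble's trees. Traces
#' longer than the model's training length are rejected (testing may not
#' use more frames than training did). Shorter traces are right-padded
#' with their edge value, with a warning. Traces sampled faster than the
#' model's rate are automatically downsampled by linear interpolation
#' (with a warning); a slower rate only warns. A tied vote goes to the
#' negative (inactive) class.
#'
#' @param object A `forest_model`.
#' @param traces A normalised [trace_matrix()] to score.
#' @param ... Unused.
#' @return A [label_set()] (source `"predicted_tsf"` or
#'   `"predicted_rise"`) with a `vote_fraction` column: the fraction of
#'   trees voting active.
#' @export
predict.forest_model <- function(object, traces, ...) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (object$normalization_mode == "dff0") {
    assert_normalized(traces, "predict")
  }
  rate_ratio <- traces$sampling_rate / object$sampling_rate
  if (rate_ratio > 1.01) {
    warning(sprintf(
      "input sampled at %.4g Hz but model trained at %.4g Hz; downsampling by linear interpolation",
      traces$sampling_rate, object$sampling_rate), call. = FALSE)
    traces <- resample_linear(traces, object$sampling_rate)
  } else if (rate_ratio < 0.99) {
    warning(sprintf(
      "input sampled at %.4g Hz, slower than the model's %.4g Hz; features may be distorted",
      traces$sampling_rate, object$sampling_rate), call. = FALSE)
  }
  nf <- n_frames(traces)
  if (nf > object$training_length) {
    stop(sprintf(
      paste0("input has %d frames but the model was trained on %d: the ",
             "number of frames used for testing must not exceed the ",
             "number of frames used for training"),
      nf, object$training_length), call. = FALSE)
  }
  X <- traces$values
  if (nf < object$training_length) {
    warning(sprintf(
      "input has %d frames; right-padding with edge values to the training length (%d)",
      nf, object$training_length), call. = FALSE)
    pad <- matrix(X[, nf], nrow(X), object$training_length - nf)
    X <- cbind(X, pad)
  }
  votes <- forest_votes(object, X)
  frac_active <- rowMeans(votes == "active")
  labels <- ifelse(frac_active > 0.5, "active", "inactive")  # tie -> inactive
  label_set(traces$neuron_ids, labels,
            source = paste0("predicted_", tolower(object$algorithm)),
            vote_fraction = frac_active)
}

# Stratified fold assignment: within each class, shuffled indices dealt
# round-robin into k folds.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      stop(sprintf("class '%s' has %d members, fewer than k = %d folds",
                   cl, length(idx), k), call. = FALSE)
    }
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits the training set into `k` stratified folds, trains on `k - 1`
#' and scores the held-out fold, reporting per-fold and mean sensitivity,
#' specificity and accuracy. Optionally an initial stratified holdout
#' split (e.g. 80:20) is made first: cross-validation runs on the
#' retained fraction and the final model, fit on all of it, is also
#' evaluated once on the holdout.
#'
#' @param train A [training_set()].
#' @param algorithm `"rise"` or `"tsf"`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and tree training.
#' @param n_trees Trees per forest (default 500).
#' @param holdout_fraction Fraction held out before cross-validation
#'   (0 disables; 0.2 reproduces an 80:20 split followed by 5-fold CV).
#' @return A list with `folds` (per-fold metric data frame), `mean`
#'   (named numeric vector of mean sensitivity/specificity/accuracy) and,
#'   when a holdout was requested, `holdout` (metrics of the full-data
#'   model on the holdout).
#' @export
crossvalidate <- function(train, algorithm = c("rise", "tsf"), k = 5,
                          seed = 1L, n_trees = 500, holdout_fraction = 0) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(train, "training_set"))
  check_two_classes(train)
  trainer <- if (algorithm == "rise") train_rise else train_tsf

  subset_ts <- function(ts, idx) {
    training_set(ts$segments[idx, , drop = FALSE], ts$labels[idx],
                 ts$provenance[idx], ts$sampling_rate)
  }
  eval_model <- function(model, ts, idx) {
    probe <- trace_matrix(ts$segments[idx, , drop = FALSE],
                          ts$sampling_rate, normalized = TRUE,
                          neuron_ids = paste0("s", idx))
    pred <- predict(model, probe)
    truth <- label_set(paste0("s", idx), ts$labels[idx],
                       source = "ground_truth_lidocaine")
    evaluation_metrics(confusion(truth, pred))
  }

  holdout_idx <- integer(0)
  cv_train <- train
  if (holdout_fraction > 0) {
    holdout_idx <- with_seed(seed + 7L, {
      unlist(lapply(split(seq_along(train$labels), train$labels),
                    function(idx) {
                      n_h <- max(1L, round(holdout_fraction * length(idx)))
                      sample(idx, n_h)
                    }), use.names = FALSE)
    })
    cv_train <- subset_ts(train, setdiff(seq_along(train$labels), holdout_idx))
    check_two_classes(cv_train)
  }

  fold <- with_seed(seed, stratified_folds(cv_train$labels, k))
  fold_rows <- lapply(seq_len(k), function(f) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    model <- trainer(subset_ts(cv_train, tr_idx), n_trees = n_trees,
                     seed = seed + f)
    m <- eval_model(model, cv_train, te_idx)
    data.frame(fold = f, n_test = length(te_idx),
               sensitivity = m$sensitivity, specificity = m$specificity,
               accuracy = m$accuracy)
  })
  folds <- do.call(rbind, fold_rows)
  out <- list(
    algorithm = toupper(algorithm), folds = folds,
    mean = c(sensitivity = mean(folds$sensitivity, na.rm = TRUE),
             specificity = mean(folds$specificity, na.rm = TRUE),
             accuracy = mean(folds$accuracy)))
  if (length(holdout_idx)) {
    full_model <- trainer(cv_train, n_trees = n_trees, seed = seed)
    out$holdout <- eval_model(full_model, train, holdout_idx)
  }
  out
}
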