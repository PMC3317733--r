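#' Stratified cross-validation folds
#'
#' Randomly partitions instances into `folds` disjoint index sets of as
#' equal size as possible (differing by at most one, overall and within each
#' class), stratified by class so every fold keeps the corpus' class ratio.
#' The partition is a deterministic function of the seed.
#'
#' @param labels Labels over \{+1, -1\}.
#' @param folds Number of folds (default 10); must not exceed the size of
#'   either class.
#' @param seed Integer seed controlling the shuffle.
#' @return List of `folds` integer index vectors partitioning
#'   `seq_along(labels)`.
#' @export
make_cv_folds <- function(labels, folds = 10L, seed = 1L) {
  labels <- check_labels(labels)
  if (!is.numeric(folds) || length(folds) != 1L || folds < 2 ||
      folds != round(folds)) {
    stop("'folds' must be a single integer >= 2", call. = FALSE)
  }
  folds <- as.integer(folds)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == -1)
  if (folds > min(n_pos, n_neg)) {
    stop("cannot build ", folds, " stratified folds from ", n_pos,
         " positive and ", n_neg, " negative instances", call. = FALSE)
  }
  shuffled <- withr::with_seed(seed, {
    c(sample(which(labels == 1)), sample(which(labels == -1)))
  })
  assignment <- integer(length(labels))
  assignment[shuffled] <- rep(seq_len(folds), length.out = length(labels))
  lapply(seq_len(folds), function(f) sort(which(assignment == f)))
}

# --- internal SVM plumbing ---------------------------------------------------

# Column-wise standardisation statistics from a training matrix; constant
# columns get unit scale so they pass through unchanged.
scaler_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

scaler_apply <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2L, scaler$center), 2L, scaler$scale, "/")
}

# Fit one RBF SVM. The decision-value column name tells which factor level
# LIBSVM treats as positive; 'flip' normalises scores so that score > 0
# always means class +1.
fit_rbf_svm <- function(x, y, C, gamma) {
  yf <- factor(y, levels = c(1, -1))
  model <- e1071::svm(x, yf, type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE)
  dv <- attr(stats::predict(model, x[1L, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (identical(colnames(dv), "-1/1")) -1 else 1
  list(model = model, flip = flip)
}

decision_scores <- function(fit, x) {
  p <- stats::predict(fit$model, x, decision.values = TRUE)
  as.vector(attr(p, "decision.values")) * fit$flip
}

# Decision scores to hard labels: the zero score maps to +1 by convention.
score_to_label <- function(scores) ifelse(scores >= 0, 1, -1)

# Grid search over (C, gamma) on one fixed fold partition. For every pair
# the out-of-fold decision scores are collected; mean per-fold accuracy
# ranks the pairs, ties going to the smallest C then the smallest gamma.
cv_grid_search <- function(x, labels, folds_list, c_grid, gamma_grid,
                           scale = TRUE) {
  if (length(c_grid) == 0L || length(gamma_grid) == 0L) {
    stop("'c_grid' and 'gamma_grid' must be non-empty", call. = FALSE)
  }
  if (any(c_grid <= 0) || any(gamma_grid <= 0)) {
    stop("grid values for C and gamma must be positive", call. = FALSE)
  }
  grid <- expand.grid(gamma = sort(gamma_grid), C = sort(c_grid),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), , drop = FALSE]
  n <- nrow(x)
  k <- length(folds_list)

  prep <- lapply(folds_list, function(test_idx) {
    train_idx <- setdiff(seq_len(n), test_idx)
    scaler <- if (scale) scaler_fit(x[train_idx, , drop = FALSE]) else NULL
    list(train_idx = train_idx,
         test_idx = test_idx,
         xtr = scaler_apply(x[train_idx, , drop = FALSE], scaler),
         xte = scaler_apply(x[test_idx, , drop = FALSE], scaler))
  })

  n_pairs <- nrow(grid)
  oof_scores <- matrix(NA_real_, nrow = n, ncol = n_pairs)
  fold_acc <- matrix(NA_real_, nrow = k, ncol = n_pairs)
  for (p in seq_len(n_pairs)) {
    ok <- TRUE
    for (f in seq_len(k)) {
      pr <- prep[[f]]
      fit <- tryCatch(
        fit_rbf_svm(pr$xtr, labels[pr$train_idx], grid$C[p], grid$gamma[p]),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      sc <- decision_scores(fit, pr$xte)
      oof_scores[pr$test_idx, p] <- sc
      fold_acc[f, p] <- mean(score_to_label(sc) == labels[pr$test_idx])
    }
    if (!ok) fold_acc[, p] <- NA_real_
  }
  mean_acc <- colMeans(fold_acc)
  if (all(is.na(mean_acc))) {
    stop("SVM training failed at every grid point", call. = FALSE)
  }
  best <- which.max(mean_acc)  # first maximum: smallest C, then gamma
  list(grid = data.frame(C = grid$C, gamma = grid$gamma,
                         accuracy = mean_acc),
       C = grid$C[best], gamma = grid$gamma[best],
       best_accuracy = mean_acc[best],
       oof_scores = oof_scores[, best],
       oof_labels = score_to_label(oof_scores[, best]),
       fold_accuracy = fold_acc[, best])
}

# --- the central fitting function --------------------------------------------

#' Fit a grid-searched RBF-SVM bioluminescence classifier
#'
#' The central modelling function: encodes a set of labelled PSSM profiles
#' with the chosen descriptor, selects the SVM cost `C` and RBF kernel width
#' `gamma` by grid search under stratified k-fold cross-validation on one
#' fixed, seeded fold partition, and refits the winning pair on the full
#' dataset. The decision function is the usual kernel expansion
#' \deqn{f(x) = \sum_i y_i \alpha_i K(x_i, x) + b, \qquad
#'   K(u, v) = \exp(-\gamma \|u - v\|^2)}
#' with class +1 assigned when \eqn{f(x) \ge 0}. The returned object keeps
#' the full grid-accuracy table, the out-of-fold cross-validation report for
#' the selected pair (the headline accuracy is the mean of the per-fold
#' accuracies) and the encoder configuration digest, so prediction-time
#' encoding mismatches are detected.
#'
#' @param x Either a list of [pssm_profile()] objects (encoded according to
#'   `encoder`) or a numeric feature matrix, rows = instances.
#' @param labels Class labels over \{+1, -1\}; +1 is the bioluminescent
#'   (positive) class. Both classes must be present.
#' @param encoder `"pssm-ac"` (auto-covariance, dimension `lg * 20`) or
#'   `"pssm-400"` (composition, dimension 400). Ignored when `x` is already
#'   a matrix.
#' @param lg Maximum auto-covariance lag (default 30, the value selected on
#'   the bioluminescent-protein corpus).
#' @param normalization,aggregate Encoder options, see [encode_pssm_ac()]
#'   and [encode_pssm_400()].
#' @param c_grid,gamma_grid Candidate values for the grid search; defaults
#'   are the standard LIBSVM-guide grids \eqn{C \in 2^{-5}, 2^{-3}, ...,
#'   2^{15}} and \eqn{\gamma \in 2^{-15}, 2^{-13}, ..., 2^{3}}.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold partition; the whole fit is a
#'   deterministic function of the inputs and this seed.
#' @param scale If `TRUE` (default), features are standardised to zero mean
#'   and unit variance using training-fold statistics only (and full-data
#'   statistics for the final refit).
#' @return Object of class `pssm_svm` with `print`, `summary`, `predict`
#'   and `plot` methods. Notable elements: `C`, `gamma`, `grid` (the full
#'   grid-accuracy table), `cv` (the out-of-fold [eval_report()]),
#'   `encoder` (configuration and digest).
#' @examples
#' spec <- synth_spec(n_pos = 15, n_neg = 15, length_range = c(40, 60),
#'                    seed = 7)
#' corpus <- generate_profiles(spec)
#' fit <- pssm_svm(corpus$profiles, corpus$labels, encoder = "pssm-ac",
#'                 lg = 3, c_grid = c(1, 8), gamma_grid = c(0.01, 0.1),
#'                 folds = 5, seed = 7)
#' fit
#' predict(fit, corpus$profiles[1:2])
#' @export
pssm_svm <- function(x, labels, encoder = c("pssm-ac", "pssm-400"),
                     lg = 30L,
                     normalization = c("raw", "sigmoid"),
                     aggregate = c("mean", "sum"),
                     c_grid = 2^seq(-5, 15, by = 2),
                     gamma_grid = 2^seq(-15, 3, by = 2),
                     folds = 10L, seed = 1L, scale = TRUE) {
  encoder <- match.arg(encoder)
  normalization <- match.arg(normalization)
  aggregate <- match.arg(aggregate)
  labels <- check_labels(labels)

  if (is.matrix(x)) {
    features <- x
    enc_info <- list(encoder = "matrix", digest = attr(x, "encoder_digest"))
  } else {
    features <- encode_dataset(x, encoder = encoder, lg = lg,
                               normalization = normalization,
                               aggregate = aggregate)
    enc_info <- list(encoder = encoder, lg = if (encoder == "pssm-ac") lg,
                     normalization = normalization,
                     aggregate = if (encoder == "pssm-400") aggregate,
                     digest = attr(features, "encoder_digest"))
  }
  if (nrow(features) != length(labels)) {
    stop(nrow(features), " instances but ", length(labels), " labels",
         call. = FALSE)
  }
  if (sum(labels == 1) == 0 || sum(labels == -1) == 0) {
    stop("training requires both classes to be present", call. = FALSE)
  }

  folds_list <- make_cv_folds(labels, folds = folds, seed = seed)
  gs <- cv_grid_search(features, labels, folds_list,
                       c_grid = c_grid, gamma_grid = gamma_grid,
                       scale = scale)
  scaler <- if (scale) scaler_fit(features) else NULL
  final <- fit_rbf_svm(scaler_apply(features, scaler), labels,
                       gs$C, gs$gamma)
  cv <- eval_report(labels, gs$oof_labels, gs$oof_scores,
                    fold_accuracy = gs$fold_accuracy)

  structure(list(svm = final$model, flip = final$flip,
                 C = gs$C, gamma = gs$gamma,
                 grid = gs$grid, cv = cv,
                 folds = folds_list, scaler = scaler,
                 encoder = enc_info, dim = ncol(features),
                 ids = rownames(features), labels = labels,
                 seed = seed, call = match.call()),
            class = "pssm_svm")
}

#' Predict class labels and decision scores
#'
#' Applies a fitted [pssm_svm()] model to new data. Profiles are encoded
#' with the configuration stored in the model; a feature matrix is accepted
#' directly provided its dimension matches the training dimension and, when
#' it carries an `encoder_digest` attribute, that digest matches the
#' model's.
#'
#' @param object A fitted `pssm_svm` model.
#' @param newdata List of [pssm_profile()] objects or a numeric feature
#'   matrix.
#' @param type `"both"` (default; data frame of id, score, label),
#'   `"class"` or `"score"`.
#' @param ... Unused.
#' @return See `type`. Labels are +1 when the decision score is >= 0.
#' @export
predict.pssm_svm <- function(object, newdata,
                             type = c("both", "class", "score"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) {
    digest <- attr(newdata, "encoder_digest")
    if (!is.null(digest) && !is.null(object$encoder$digest) &&
        !identical(digest, object$encoder$digest)) {
      stop("encoder mismatch: model was trained on '",
           object$encoder$digest, "' but features carry '", digest, "'",
           call. = FALSE)
    }
    features <- newdata
  } else if (is.list(newdata)) {
    if (identical(object$encoder$encoder, "matrix")) {
      stop("model was trained on a raw feature matrix; supply a matrix, ",
           "not profiles", call. = FALSE)
    }
    features <- encode_dataset(newdata, encoder = object$encoder$encoder,
                               lg = if (is.null(object$encoder$lg)) 30L
                                    else object$encoder$lg,
                               normalization = object$encoder$normalization,
                               aggregate = if (is.null(object$encoder$aggregate))
                                             "mean"
                                           else object$encoder$aggregate)
  } else {
    stop("'newdata' must be a list of pssm_profile objects or a matrix",
         call. = FALSE)
  }
  if (nrow(features) == 0L) {
    stop("empty prediction set", call. = FALSE)
  }
  if (ncol(features) != object$dim) {
    stop("feature dimension mismatch: model expects ", object$dim,
         " features, got ", ncol(features), call. = FALSE)
  }
  scores <- decision_scores(list(model = object$svm, flip = object$flip),
                            scaler_apply(features, object$scaler))
  labels <- score_to_label(scores)
  switch(type,
         both = data.frame(id = rownames(features) %||%
                             as.character(seq_along(scores)),
                           score = scores, label = labels,
                           row.names = NULL, stringsAsFactors = FALSE),
         class = labels,
         score = scores)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print pssm_svm
print.pssm_svm <- function(x, ...) {
  cat("RBF-SVM bioluminescence classifier\n")
  cat("  encoder:   ", x$encoder$digest %||% x$encoder$encoder, "\n", sep = "")
  cat("  training:  ", length(x$labels), " instances (",
      sum(x$labels == 1), " +1 / ", sum(x$labels == -1), " -1), ",
      x$dim, " features\n", sep = "")
  cat(sprintf("  selected:  C = %g, gamma = %g (grid of %d pairs, %d-fold CV)\n",
              x$C, x$gamma, nrow(x$grid), length(x$folds)))
  cat(sprintf("  CV accuracy (mean over folds): %.4f\n",
              x$cv$mean_fold_accuracy))
  invisible(x)
}

#' @export
#' @method summary pssm_svm
summary.pssm_svm <- function(object, ...) {
  structure(list(fit = object), class = "summary.pssm_svm")
}

#' @export
#' @method print summary.pssm_svm
print.summary.pssm_svm <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nCross-validation report (pooled out-of-fold predictions):\n")
  print(fit$cv)
  top <- fit$grid[order(-fit$grid$accuracy), , drop = FALSE]
  cat("\nTop grid points by CV accuracy:\n")
  print(utils::head(top, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
#' @method plot pssm_svm
plot.pssm_svm <- function(x, ...) {
  plot(x$cv, main = sprintf("Out-of-fold ROC (AUC = %.3f)", x$cv$auc), ...)
  invisible(x)
}

# --- persistence -------------------------------------------------------------

MODEL_FORMAT <- "lumipred-pssm-svm/1"

#' Save / load a fitted model
#'
#' The archive stores the kernel parameters, support coefficients, scaler
#' statistics, encoder digest and a format-version string; a reloaded model
#' reproduces the original predictions exactly, and predicting from features
#' with a different encoder digest fails with a configuration error.
#'
#' @param model A fitted [pssm_svm()] model.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pssm_svm"))
  saveRDS(list(format = MODEL_FORMAT, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read model file '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(payload) || !identical(payload$format, MODEL_FORMAT) ||
      !inherits(payload$model, "pssm_svm")) {
    stop("'", path, "' is not a ", MODEL_FORMAT, " model archive",
         call. = FALSE)
  }
  payload$model
}

# --- protocols ---------------------------------------------------------------

#' Cross-validated evaluation of the full pipeline
#'
#' Runs encoding, grid search and stratified k-fold cross-validation (see
#' [pssm_svm()]) and returns the out-of-fold evaluation report of the
#' selected (C, gamma) pair: pooled confusion counts, Sn/Sp/ACC, ROC/AUC
#' from pooled out-of-fold decision scores, and the per-fold accuracy
#' vector whose mean is the headline cross-validation accuracy.
#'
#' @inheritParams pssm_svm
#' @param ... Passed on to [pssm_svm()].
#' @return An [eval_report()] with an additional attribute `fit`, the
#'   underlying `pssm_svm` model.
#' @export
evaluate_cv <- function(x, labels, ...) {
  fit <- pssm_svm(x, labels, ...)
  report <- fit$cv
  attr(report, "fit") <- fit
  report
}

#' Independent-test evaluation of a fitted model
#'
#' Single-pass prediction on an untouched test set, supporting heavily
#' imbalanced label ratios (e.g. the realistic screening regime of a few
#' positives against thousands of negatives).
#'
#' @param model A fitted [pssm_svm()] model.
#' @param x Test profiles (list) or feature matrix.
#' @param labels True labels over \{+1, -1\}.
#' @return An [eval_report()].
#' @export
evaluate_independent <- function(model, x, labels) {
  stopifnot(inherits(model, "pssm_svm"))
  labels <- check_labels(labels)
  if ((is.matrix(x) && nrow(x) == 0L) || (is.list(x) && !is.matrix(x) &&
                                          length(x) == 0L)) {
    stop("empty test set", call. = FALSE)
  }
  pred <- predict(model, x, type = "both")
  if (nrow(pred) != length(labels)) {
    stop(nrow(pred), " predictions but ", length(labels), " labels",
         call. = FALSE)
  }
  eval_report(labels, pred$label, pred$score)
}

# --- lag selection -----------------------------------------------------------

#' Sweep the maximum auto-covariance lag
#'
#' Model selection for the PSSM-AC encoder: for every candidate maximum lag
#' the profiles are re-encoded, a full grid-searched cross-validation is
#' run, and the lag with the highest cross-validation accuracy is selected
#' (ties going to the smallest lag). The default candidate set is
#' 1, 5, 10, ..., 50; every profile must be longer than the largest
#' candidate.
#'
#' @param profiles List of [pssm_profile()] objects.
#' @param labels Labels over \{+1, -1\}.
#' @param lag_values Candidate maximum lags (default `c(1, seq(5, 50, 5))`).
#' @param ... Passed on to [pssm_svm()] (grids, folds, seed, ...).
#' @return Object of class `lag_sweep`: a table of lag, accuracy and the
#'   selected (C, gamma) per lag; `best_lag`; `best_accuracy`; and the
#'   per-lag [eval_report()]s in `reports`.
#' @export
sweep_lag <- function(profiles, labels, lag_values = c(1L, seq(5L, 50L, 5L)),
                      ...) {
  if (length(lag_values) == 0L) {
    stop("'lag_values' must be non-empty", call. = FALSE)
  }
  lag_values <- sort(unique(as.integer(lag_values)))
  lens <- vapply(profiles, `[[`, numeric(1), "n")
  too_short <- lens <= max(lag_values)
  if (any(too_short)) {
    ids <- vapply(profiles[too_short], `[[`, character(1), "id")
    stop("profiles too short for maximum lag ", max(lag_values), ": ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  fits <- lapply(lag_values, function(lg) {
    pssm_svm(profiles, labels, encoder = "pssm-ac", lg = lg, ...)
  })
  acc <- vapply(fits, function(f) f$cv$mean_fold_accuracy, numeric(1))
  best <- which.max(acc)  # first maximum: smallest lag wins ties
  structure(list(table = data.frame(lag = lag_values, accuracy = acc,
                                    C = vapply(fits, `[[`, numeric(1), "C"),
                                    gamma = vapply(fits, `[[`, numeric(1),
                                                   "gamma")),
                 lags = lag_values, accuracies = acc,
                 best_lag = lag_values[best], best_accuracy = acc[best],
                 reports = lapply(fits, `[[`, "cv")),
            class = "lag_sweep")
}

#' @export
#' @method print lag_sweep
print.lag_sweep <- function(x, ...) {
  cat("Auto-covariance lag sweep over", length(x$lags), "candidate lags\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("best lag: %d (CV accuracy %.4f)\n", x$best_lag,
              x$best_accuracy))
  invisible(x)
}

#' @export
#' @method plot lag_sweep
plot.lag_sweep <- function(x, ...) {
  graphics::plot(x$lags, x$accuracies, type = "b", pch = 19,
                 xlab = "maximum lag lg", ylab = "CV accuracy", ...)
  graphics::abline(v = x$best_lag, lty = 3, col = "grey50")
  invisible(x)
}
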