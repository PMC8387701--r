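## Classifier families and hyperparameter tuning. Four algorithms: balanced
## random forest (brf), random forest (rf), k-nearest neighbours (knn) and
## RBF support vector machine (svm). Tuning is an exhaustive grid search
## scored by mean balanced accuracy over stratified k-fold cross-validation
## of the training set, with any rebalancing applied inside each training
## fold only (never to validation folds, which would leak synthetic copies
## of validation compounds into training).

#' Default hyperparameter grid for an algorithm
#'
#' Small standard grids, overridable via the `grid` argument of
#' [qsar_train()]:
#' * `knn`: k in 1,3,5,7,9,11 x weighting uniform / inverse-distance;
#' * `brf`, `rf`: trees in 100,250,500 x mtry rule sqrt / log2;
#' * `svm`: RBF kernel, cost in 0.1,1,10,100 x gamma scale / 0.01 / 0.001
#'   (`"scale"` = 1 / (n_features x mean feature variance)).
#'
#' @param algorithm One of `"brf"`, `"rf"`, `"knn"`, `"svm"`.
#' @return Data frame, one row per grid point.
#' @export
default_grid <- function(algorithm = c("brf", "rf", "knn", "svm")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    knn = expand.grid(k = c(1, 3, 5, 7, 9, 11),
                      weighting = c("uniform", "inverse"),
                      stringsAsFactors = FALSE),
    brf = ,
    rf = expand.grid(ntree = c(100, 250, 500),
                     mtry_rule = c("sqrt", "log2"),
                     stringsAsFactors = FALSE),
    svm = expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = c("scale", "0.01", "0.001"),
                      stringsAsFactors = FALSE))
}

# ---- per-algorithm fitting backends ---------------------------------------

fit_one <- function(algorithm, x, y, params, seed) {
  set.seed(seed)
  switch(algorithm,
    brf = {
      nmin <- min(table(y))
      mtry <- resolve_mtry(params$mtry_rule, ncol(x))
      randomForest::randomForest(x, y, ntree = params$ntree, mtry = mtry,
                                 strata = y, sampsize = c(nmin, nmin),
                                 replace = TRUE)
    },
    rf = {
      mtry <- resolve_mtry(params$mtry_rule, ncol(x))
      randomForest::randomForest(x, y, ntree = params$ntree, mtry = mtry)
    },
    knn = structure(list(x = x, y = y, k = params$k,
                         weighting = params$weighting),
                    class = "knn_fit"),
    svm = {
      gamma <- if (identical(params$gamma, "scale")) {
        v <- mean(apply(x, 2L, stats::var))
        1 / (ncol(x) * max(v, .Machine$double.eps))
      } else as.numeric(params$gamma)
      e1071::svm(x, y, kernel = "radial", cost = params$cost, gamma = gamma,
                 probability = TRUE)
    },
    stop("unknown algorithm: ", algorithm))
}

resolve_mtry <- function(rule, p) {
  m <- switch(as.character(rule),
              sqrt = floor(sqrt(p)),
              log2 = floor(log2(p)),
              as.integer(rule))
  max(1L, min(p, m))
}

# active-class probability from a fitted backend
prob_active <- function(algorithm, fit, x) {
  switch(algorithm,
    brf = ,
    rf = unname(stats::predict(fit, x, type = "prob")[, "active"]),
    knn = knn_prob_active(fit, x),
    svm = {
      pred <- stats::predict(fit, x, probability = TRUE)
      unname(attr(pred, "probabilities")[, "active"])
    })
}

# knn: distances to training rows; neighbour ties broken by row order;
# uniform weighting = fraction of active neighbours, inverse = 1/(d+eps)
knn_prob_active <- function(fit, x) {
  tx <- fit$x
  act <- fit$y == "active"
  k <- min(fit$k, nrow(tx))
  cross <- outer(rowSums(x^2), rep(1, nrow(tx))) +
    outer(rep(1, nrow(x)), rowSums(tx^2)) - 2 * x %*% t(tx)
  cross[cross < 0] <- 0
  vapply(seq_len(nrow(x)), function(i) {
    d <- sqrt(cross[i, ])
    nn <- order(d)[seq_len(k)]
    if (fit$weighting == "uniform") {
      mean(act[nn])
    } else {
      w <- 1 / (d[nn] + 1e-12)
      sum(w * act[nn]) / sum(w)
    }
  }, numeric(1))
}

# ---- tuning and the fitted-model object -----------------------------------

#' Train a QSAR classifier with cross-validated hyperparameter tuning
#'
#' Exhaustive grid search: every grid point is scored by mean balanced
#' accuracy over stratified `nfolds`-fold cross-validation of the training
#' data, the best point (ties: first in grid order) is refit on the full
#' training set, and the result is returned as a `qsar_model` object with
#' `predict`, `print` and `summary` methods.
#'
#' Rebalancing: `rf`, `knn` and `svm` train on SMOTE-rebalanced data by
#' default (`resample = "smote"`), applied inside each training fold only;
#' validation folds and any later test data are never resampled. `brf`
#' rebalances internally through balanced per-tree bootstraps and refuses an
#' external resampling plan.
#'
#' @param x Numeric descriptor matrix (already pruned and scaled).
#' @param y Binary activity vector.
#' @param algorithm `"brf"`, `"rf"`, `"knn"` or `"svm"`.
#' @param grid Hyperparameter grid (default [default_grid()]).
#' @param features Optional character vector restricting `x` to a selected
#'   descriptor subset.
#' @param resample `"smote"` or `"none"`; default `"none"` for brf and
#'   `"smote"` otherwise.
#' @param smote_k,target_ratio SMOTE parameters (see [smote_oversample()]).
#' @param nfolds Cross-validation folds.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return Object of class `qsar_model`.
#' @export
qsar_train <- function(x, y, algorithm = c("brf", "rf", "knn", "svm"),
                       grid = NULL, features = NULL, resample = NULL,
                       smote_k = 5, target_ratio = 1, nfolds = 10,
                       seed = 1) {
  algorithm <- match.arg(algorithm)
  y <- as_activity(y)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (is.null(features)) features <- colnames(x)
  missing_cols <- setdiff(features, colnames(x))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- x[, features, drop = FALSE]
  if (is.null(resample)) {
    resample <- if (algorithm == "brf") "none" else "smote"
  }
  resample <- match.arg(resample, c("none", "smote"))
  if (algorithm == "brf" && resample != "none") {
    stop("brf rebalances internally through balanced per-tree bootstraps; ",
         "an external resampling plan is not allowed")
  }
  if (is.null(grid)) grid <- default_grid(algorithm)
  if (!nrow(grid)) stop("empty hyperparameter grid")

  maybe_resample <- function(xt, yt, seed) {
    if (resample == "smote") {
      s <- smote_oversample(xt, yt, k = smote_k, target_ratio = target_ratio,
                            seed = seed)
      list(x = s$x, y = s$y)
    } else list(x = xt, y = yt)
  }

  fold <- stratified_folds(y, nfolds, substream_seed(seed, "tune"))
  cv <- matrix(NA_real_, nrow(grid), nfolds)
  for (g in seq_len(nrow(grid))) {
    params <- grid[g, , drop = FALSE]
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      dat <- maybe_resample(x[tr, , drop = FALSE], y[tr],
                            substream_seed(seed, sprintf("res_f%d", f)))
      fit <- fit_one(algorithm, dat$x, dat$y, params,
                     substream_seed(seed, sprintf("fit_g%d_f%d", g, f)))
      p <- prob_active(algorithm, fit, x[!tr, , drop = FALSE])
      cv[g, f] <- balanced_accuracy(y[!tr], prob_to_label(p))
    }
  }
  best <- which.max(rowMeans(cv))  # first max = first grid point on ties

  dat <- maybe_resample(x, y, substream_seed(seed, "res_final"))
  final <- fit_one(algorithm, dat$x, dat$y, grid[best, , drop = FALSE],
                   substream_seed(seed, "fit_final"))
  structure(list(
    algorithm = algorithm,
    params = as.list(grid[best, , drop = FALSE]),
    features = features,
    resample = resample,
    fit = final,
    cv_report = data.frame(fold = seq_len(nfolds), ba = cv[best, ]),
    cv_grid = cbind(grid, cv_ba_mean = rowMeans(cv)),
    nfolds = nfolds,
    seed = seed,
    n_train = nrow(x),
    class_counts = table(y)),
    class = "qsar_model")
}

# probability >= threshold convention: exactly 0.5 -> inactive
prob_to_label <- function(p, threshold = 0.5) {
  factor(ifelse(p > threshold, "active", "inactive"),
         levels = c("inactive", "active"))
}

#' Predict from a fitted QSAR model
#'
#' @param object A `qsar_model`.
#' @param newdata Numeric matrix containing the model's feature columns
#'   (scaled with the training statistics).
#' @param type `"label"` (factor inactive/active), `"prob"` (probability of
#'   the active class) or `"both"` (data frame with `label`,
#'   `probability_active` and `probability_predicted_class`). A compound is
#'   called active when its active-class probability exceeds 0.5; a
#'   probability of exactly 0.5 yields the inactive label.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.qsar_model <- function(object, newdata,
                               type = c("label", "prob", "both"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, colnames(newdata))
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- newdata[, object$features, drop = FALSE]
  p <- prob_active(object$algorithm, object$fit, x)
  switch(type,
         prob = p,
         label = prob_to_label(p),
         both = data.frame(label = prob_to_label(p),
                           probability_active = p,
                           probability_predicted_class = pmax(p, 1 - p)))
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("QSAR classifier: %s (%d features, %s rebalancing)\n",
              toupper(x$algorithm), length(x$features),
              if (x$resample == "none" && x$algorithm == "brf")
                "per-tree balanced-bootstrap" else x$resample))
  cat("  tuned parameters:",
      paste(names(x$params), unlist(x$params), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  %d-fold CV balanced accuracy: %.3f\n", x$nfolds,
              mean(x$cv_report$ba)))
  invisible(x)
}

#' @export
summary.qsar_model <- function(object, ...) {
  print(object)
  cat(sprintf("  training compounds: %d (%s)\n", object$n_train,
              paste(names(object$class_counts), object$class_counts,
                    sep = " = ", collapse = ", ")))
  cat("  per-fold CV BA:",
      paste(sprintf("%.2f", object$cv_report$ba), collapse = " "), "\n")
  cat("  grid search (mean CV BA):\n")
  print(object$cv_grid, row.names = FALSE)
  invisible(object)
}

#' Prediction table for a compound set
#'
#' Convenience wrapper producing the standard prediction output: one row
#' per compound with the label, the active-class probability, the
#' predicted-class probability and the applicability-domain flag
#' (predicted-class probability at or above `domain_threshold`).
#'
#' @param model A `qsar_model`.
#' @param x Scaled descriptor matrix.
#' @param ids Compound identifiers (default: row names of `x`).
#' @param domain_threshold Predicted-class probability defining the
#'   response domain.
#' @return Data frame `id, label, probability_active,
#'   probability_predicted_class, in_domain`.
#' @export
qsar_predict_table <- function(model, x, ids = rownames(x),
                               domain_threshold = 0.65) {
  pred <- predict(model, x, type = "both")
  data.frame(id = ids %||% seq_len(nrow(x)),
             label = pred$label,
             probability_active = pred$probability_active,
             probability_predicted_class = pred$probability_predicted_class,
             in_domain = pred$probability_predicted_class >= domain_threshold,
             stringsAsFactors = FALSE)
}
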