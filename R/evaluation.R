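## Model evaluation: confusion matrices, Cooper's statistics (sensitivity,
## specificity, balanced accuracy), Matthews correlation, Y-scrambling,
## probability-threshold applicability-domain curves and two-model
## unanimity consensus.

#' Confusion matrix of a binary classification
#'
#' @param y_true,y_pred Binary activity vectors of equal length (active =
#'   positive class).
#' @return Object of class `confusion_matrix`: list with integer counts
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  y_true <- as_activity(y_true)
  y_pred <- as_activity(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (!length(y_true)) stop("empty input")
  cm <- list(tp = sum(y_true == "active" & y_pred == "active"),
             tn = sum(y_true == "inactive" & y_pred == "inactive"),
             fp = sum(y_true == "inactive" & y_pred == "active"),
             fn = sum(y_true == "active" & y_pred == "inactive"))
  structure(lapply(cm, as.integer), class = "confusion_matrix")
}

#' Build a confusion matrix from counts
#'
#' @param tn,fp,tp,fn Non-negative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_from_counts <- function(tn, fp, tp, fn) {
  stopifnot(tn >= 0, fp >= 0, tp >= 0, fn >= 0, tn + fp + tp + fn > 0)
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2,
              dimnames = list(predicted = c("inactive", "active"),
                              observed = c("inactive", "active")))
  print(m)
  invisible(x)
}

#' Cooper's statistics
#'
#' Sensitivity `SEN = TP / (TP + FN)`, specificity `SPE = TN / (TN + FP)`
#' and balanced accuracy `BA = (SEN + SPE) / 2`.
#'
#' @param cm A `confusion_matrix`.
#' @return Named numeric vector `sen`, `spe`, `ba` (full precision; round
#'   with [round_half_up()] for reporting).
#' @export
cooper_stats <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) stop("no positive samples: sensitivity undefined")
  if (cm$tn + cm$fp == 0) stop("no negative samples: specificity undefined")
  sen <- cm$tp / (cm$tp + cm$fn)
  spe <- cm$tn / (cm$tn + cm$fp)
  c(sen = sen, spe = spe, ba = (sen + spe) / 2)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#' `[-1, 1]`. When any denominator factor is zero the coefficient is
#' defined as 0 (the standard convention for degenerate margins).
#'
#' @param cm A `confusion_matrix`.
#' @return MCC value.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  fac <- as.numeric(c(cm$tp + cm$fp, cm$tp + cm$fn,
                      cm$tn + cm$fp, cm$tn + cm$fn))
  if (any(fac == 0)) return(0)
  num <- as.numeric(cm$tp) * cm$tn - as.numeric(cm$fp) * cm$fn
  num / sqrt(prod(fac))
}

#' Balanced accuracy of a prediction
#'
#' @param y_true,y_pred Binary activity vectors.
#' @return `(sensitivity + specificity) / 2`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  unname(cooper_stats(confusion_matrix(y_true, y_pred))["ba"])
}

#' Full metrics report
#'
#' @param y_true,y_pred Binary activity vectors.
#' @return List with the confusion matrix, `sen`, `spe`, `ba`, `mcc`, `n`.
#' @export
classification_report <- function(y_true, y_pred) {
  cm <- confusion_matrix(y_true, y_pred)
  cs <- cooper_stats(cm)
  list(confusion = cm, sen = unname(cs["sen"]), spe = unname(cs["spe"]),
       ba = unname(cs["ba"]), mcc = mcc(cm),
       n = cm$tp + cm$tn + cm$fp + cm$fn)
}

#' Y-scrambling (response permutation) test
#'
#' Retrains the model on `n_permutations` uniformly shuffled copies of the
#' activity labels and scores each by cross-validated balanced accuracy.
#' The empirical p-value is `(c + 1) / (n + 1)`, with `c` the number of
#' permutations whose score exceeds the baseline (unpermuted)
#' cross-validated score; it is never zero. An informative model should
#' show permuted scores collapsing to ~0.5 and a p-value near 1/(n+1).
#'
#' @param x Scaled descriptor matrix.
#' @param y Binary activity vector.
#' @param fit_fun `function(x, y, seed)` returning a fitted model whose
#'   `predict(model, x)` yields labels. Defaults to a 50-tree balanced
#'   random forest (a reduced forest keeps the 100-permutation protocol
#'   affordable; the permuted-score null is insensitive to forest size).
#' @param n_permutations Number of label permutations.
#' @param nfolds Cross-validation folds for the BA score.
#' @param seed Integer seed.
#' @return Object of class `scrambling_result`: list with `baseline_score`,
#'   `permuted_scores`, `c`, `p_value`, `n_permutations`.
#' @export
y_scramble <- function(x, y, fit_fun = NULL, n_permutations = 100,
                       nfolds = 10, seed = 1) {
  stopifnot(n_permutations >= 1)
  y <- as_activity(y)
  if (is.null(fit_fun)) {
    fit_fun <- function(x, y, seed) {
      set.seed(seed)
      nmin <- min(table(y))
      randomForest::randomForest(x, y, ntree = 50, strata = y,
                                 sampsize = c(nmin, nmin), replace = TRUE)
    }
  }
  cv_ba <- function(yy, tag) {
    fold <- stratified_folds(yy, nfolds, substream_seed(seed, tag))
    bas <- vapply(seq_len(nfolds), function(f) {
      tr <- fold != f
      fit <- fit_fun(x[tr, , drop = FALSE], yy[tr],
                     substream_seed(seed, paste0(tag, "_f", f)))
      balanced_accuracy(yy[!tr], stats::predict(fit, x[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(bas)
  }
  baseline <- cv_ba(y, "scramble_baseline")
  set.seed(substream_seed(seed, "scramble_perms"))
  perms <- replicate(n_permutations, sample.int(length(y)))
  scores <- vapply(seq_len(n_permutations), function(b) {
    cv_ba(y[perms[, b]], paste0("scramble_p", b))
  }, numeric(1))
  c_count <- sum(scores > baseline)
  structure(list(baseline_score = baseline, permuted_scores = scores,
                 c = c_count,
                 p_value = (c_count + 1) / (n_permutations + 1),
                 n_permutations = n_permutations),
            class = "scrambling_result")
}

#' @export
print.scrambling_result <- function(x, ...) {
  cat(sprintf(paste0("Y-scrambling: baseline CV BA = %.2f; mean permuted",
                     " BA = %.2f (n = %d); p = %.2f\n"),
              round_half_up(x$baseline_score),
              round_half_up(mean(x$permuted_scores)),
              x$n_permutations, round_half_up(x$p_value)))
  invisible(x)
}

#' Applicability-domain curve from prediction probabilities
#'
#' Sweeps a predicted-class probability threshold: at each threshold only
#' compounds predicted with at least that probability are considered in
#' domain, and the balanced accuracy is recomputed on the retained subset.
#' Coverage (fraction retained) is non-increasing in the threshold; at 0.5
#' it is exactly 1 because predicted-class probabilities are at least 0.5
#' by construction. Raising the threshold trades coverage for accuracy and
#' makes the fuzzy boundary of the model's domain explicit.
#'
#' @param prob_predicted_class Probability of the predicted class (in
#'   `[0.5, 1]`).
#' @param y_true,y_pred Binary activity vectors.
#' @param thresholds Increasing thresholds in `[0.5, 1]`.
#' @return Object of class `domain_curve`: data frame
#'   `threshold, coverage, n_kept, ba` (`ba` is `NA`, flagged in
#'   `degenerate`, when a class empties in the retained subset).
#' @export
domain_curve <- function(prob_predicted_class, y_true, y_pred,
                         thresholds = seq(0.5, 1, by = 0.05)) {
  if (!length(thresholds)) stop("empty threshold list")
  y_true <- as_activity(y_true)
  y_pred <- as_activity(y_pred)
  stopifnot(length(prob_predicted_class) == length(y_true),
            length(y_true) == length(y_pred))
  if (any(prob_predicted_class < 0.5 - 1e-12)) {
    stop("prob_predicted_class must be >= 0.5 (predicted-class convention)")
  }
  n <- length(y_true)
  rows <- lapply(thresholds, function(t) {
    keep <- prob_predicted_class >= t
    ba <- NA_real_
    degenerate <- TRUE
    if (any(keep)) {
      yk <- y_true[keep]
      if (all(table(yk) > 0)) {
        ba <- balanced_accuracy(yk, y_pred[keep])
        degenerate <- FALSE
      }
    }
    data.frame(threshold = t, coverage = sum(keep) / n, n_kept = sum(keep),
               ba = ba, degenerate = degenerate)
  })
  structure(do.call(rbind, rows), class = c("domain_curve", "data.frame"))
}

#' Unanimity consensus of two models
#'
#' A compound receives a consensus label only when both models agree;
#' disagreements are conflicts and are excluded from consensus metrics.
#' When reference activities are supplied, each compound is classified as
#' concordant-correct, concordant-wrong or conflict, and a metrics report
#' is computed on the concordant subset.
#'
#' @param pred_a,pred_b Predicted labels from the two models, aligned by
#'   compound (same id order).
#' @param y_true Optional reference activities.
#' @param ids Optional compound identifiers (checked for alignment when
#'   both predictions carry names).
#' @return Object of class `consensus_result`: list with `status` (factor
#'   `concordant_correct` / `concordant_wrong` / `conflict`, or
#'   `concordant` / `conflict` without `y_true`), `label` (consensus label,
#'   `NA` for conflicts), `coverage`, `n`, and `metrics`
#'   ([classification_report()] on the concordant subset) when `y_true` is
#'   given.
#' @export
consensus <- function(pred_a, pred_b, y_true = NULL, ids = NULL) {
  pred_a <- as_activity(pred_a)
  pred_b <- as_activity(pred_b)
  if (length(pred_a) != length(pred_b)) {
    stop("prediction vectors must be aligned (equal length)")
  }
  agree <- pred_a == pred_b
  label <- ifelse(agree, as.character(pred_a), NA_character_)
  label <- factor(label, levels = c("inactive", "active"))
  metrics <- NULL
  if (!is.null(y_true)) {
    y_true <- as_activity(y_true)
    stopifnot(length(y_true) == length(pred_a))
    status <- ifelse(!agree, "conflict",
              ifelse(label == y_true, "concordant_correct",
                     "concordant_wrong"))
    status <- factor(status, levels = c("concordant_correct",
                                        "concordant_wrong", "conflict"))
    if (any(agree)) {
      metrics <- classification_report(y_true[agree], label[agree])
    }
  } else {
    status <- factor(ifelse(agree, "concordant", "conflict"),
                     levels = c("concordant", "conflict"))
  }
  structure(list(status = status, label = label, ids = ids,
                 coverage = mean(agree), n = length(pred_a),
                 metrics = metrics),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Unanimity consensus: %d/%d concordant (coverage %.2f)\n",
              round(x$coverage * x$n), x$n, x$coverage))
  if (!is.null(x$metrics)) {
    cat(sprintf("  concordant-subset BA = %.2f, MCC = %.2f\n",
                round_half_up(x$metrics$ba), round_half_up(x$metrics$mcc)))
  }
  invisible(x)
}
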