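## Feature-importance ranking (Gini impurity and permutation importance)
## and the subset-size sweep used to pick the optimal descriptor count.

#' Rank descriptors by importance
#'
#' Two ranking methods:
#'
#' * `"gini"` — mean decrease in Gini impurity of each descriptor across the
#'   trees of a random forest (balanced per-tree bootstraps when
#'   `balanced = TRUE`), normalized to sum to one.
#' * `"permutation"` — the drop in balanced accuracy when a single
#'   descriptor is shuffled. The forest is fitted on 75% of the supplied
#'   rows and scored on the held-out 25%; each column is permuted
#'   `n_repeats` times and the importance is the baseline BA minus the mean
#'   permuted BA. Held-out scoring is used because in-sample permutation
#'   importance of a deep forest is near zero for every feature.
#'
#' Ties are broken by stored column order, so rankings are deterministic
#' given the seed.
#'
#' @param x Numeric matrix (pruned, scaled descriptors).
#' @param y Binary activity vector.
#' @param method `"gini"` or `"permutation"`.
#' @param ntree Trees in the ranking forest.
#' @param balanced Use balanced per-tree bootstraps (match the downstream
#'   model when it is a balanced random forest).
#' @param n_repeats Permutations per column (permutation method).
#' @param holdout_fraction Held-out fraction for permutation scoring.
#' @param seed Integer seed.
#' @return Object of class `ranked_features`: data frame
#'   `rank,name,score,method` plus attributes.
#' @export
rank_features <- function(x, y, method = c("gini", "permutation"),
                          ntree = 500, balanced = FALSE, n_repeats = 10,
                          holdout_fraction = 0.25, seed = 1) {
  method <- match.arg(method)
  y <- as_activity(y)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (nlevels(droplevels(y)) < 2L) stop("degenerate labels: one class only")

  if (method == "gini") {
    set.seed(substream_seed(seed, "rank_gini"))
    args <- list(x = x, y = y, ntree = ntree, importance = FALSE)
    if (balanced) {
      nmin <- min(table(y))
      args$strata <- y
      args$sampsize <- c(nmin, nmin)
      args$replace <- TRUE
    }
    fit <- do.call(randomForest::randomForest, args)
    score <- fit$importance[, "MeanDecreaseGini"]
    score <- score / sum(score)
  } else {
    if (n_repeats < 1L) stop("n_repeats must be >= 1")
    hold <- stratified_split(y, test_fraction = holdout_fraction,
                             seed = substream_seed(seed, "rank_perm_split"))
    tr <- hold$split == "TrS"
    set.seed(substream_seed(seed, "rank_perm_fit"))
    args <- list(x = x[tr, , drop = FALSE], y = y[tr], ntree = ntree)
    if (balanced) {
      nmin <- min(table(y[tr]))
      args$strata <- y[tr]
      args$sampsize <- c(nmin, nmin)
      args$replace <- TRUE
    }
    fit <- do.call(randomForest::randomForest, args)
    xv <- x[!tr, , drop = FALSE]
    yv <- y[!tr]
    baseline <- balanced_accuracy(yv, stats::predict(fit, xv))
    set.seed(substream_seed(seed, "rank_perm_shuffle"))
    score <- vapply(seq_len(ncol(x)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- xv
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        baseline - balanced_accuracy(yv, stats::predict(fit, xp))
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    names(score) <- colnames(x)
    attr(score, "baseline") <- baseline
  }

  ord <- order(-score, seq_along(score))
  out <- data.frame(rank = seq_along(ord), name = colnames(x)[ord],
                    score = as.numeric(score[ord]), method = method,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_features", "data.frame"),
            method = method, seed = seed, n_repeats = n_repeats,
            estimator = list(algorithm = if (balanced) "brf" else "rf",
                             ntree = ntree))
}

#' Sweep feature-subset sizes by cross-validated balanced accuracy
#'
#' For each candidate size `s`, trains the supplied model on the top-`s`
#' ranked descriptors in stratified k-fold cross-validation and records the
#' mean and SD of the fold balanced accuracies. Sizes exceeding the number
#' of available descriptors are skipped with a warning. Folds are shared
#' across sizes (fixed per seed) so size comparisons are paired. The best
#' size maximizes mean CV BA; ties go to the smallest size.
#'
#' @param ranking A [rank_features()] result.
#' @param x,y Training descriptors and activities.
#' @param sizes Candidate subset sizes (default: the standard sweep grid
#'   20, 30, 50, 100, 120, 130, 150, 160, 170, 200, 250, 300).
#' @param fit_fun `function(x, y, seed)` returning a fitted model with a
#'   `predict(model, x)` method yielding labels. Defaults to a 250-tree
#'   balanced random forest.
#' @param nfolds Cross-validation folds.
#' @param seed Integer seed.
#' @return Object of class `subset_sweep`: data frame
#'   `size,cv_ba_mean,cv_ba_sd` with attribute `best_size`.
#' @export
sweep_subsets <- function(ranking, x, y,
                          sizes = c(20, 30, 50, 100, 120, 130, 150, 160,
                                    170, 200, 250, 300),
                          fit_fun = NULL, nfolds = 10, seed = 1) {
  stopifnot(inherits(ranking, "ranked_features"), nrow(ranking) > 0L)
  y <- as_activity(y)
  if (is.null(fit_fun)) {
    fit_fun <- function(x, y, seed) {
      set.seed(seed)
      nmin <- min(table(y))
      randomForest::randomForest(x, y, ntree = 250, strata = y,
                                 sampsize = c(nmin, nmin), replace = TRUE)
    }
  }
  feasible <- sizes[sizes <= nrow(ranking)]
  skipped <- setdiff(sizes, feasible)
  if (length(skipped)) {
    warning("subset size(s) beyond available descriptors skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (!length(feasible)) stop("no feasible subset size")
  fold <- stratified_folds(y, nfolds, substream_seed(seed, "sweep"))
  res <- lapply(feasible, function(s) {
    feats <- ranking$name[seq_len(s)]
    bas <- vapply(seq_len(nfolds), function(f) {
      tr <- fold != f
      fit <- fit_fun(x[tr, feats, drop = FALSE], y[tr],
                     substream_seed(seed, sprintf("sweep_s%d_f%d", s, f)))
      balanced_accuracy(y[!tr], stats::predict(fit, x[!tr, feats,
                                                      drop = FALSE]))
    }, numeric(1))
    c(mean = mean(bas), sd = stats::sd(bas))
  })
  out <- data.frame(size = feasible,
                    cv_ba_mean = vapply(res, `[[`, 0, "mean"),
                    cv_ba_sd = vapply(res, `[[`, 0, "sd"))
  best <- out$size[which.max(out$cv_ba_mean)]  # which.max: first = smallest
  structure(out, class = c("subset_sweep", "data.frame"),
            best_size = best, skipped = skipped)
}
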