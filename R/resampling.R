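## Class rebalancing: SMOTE oversampling of the minority class and balanced
## bootstrap index draws (one per tree of a balanced random forest).
## Only training data is ever resampled; test and external sets stay at
## their natural class ratio.

#' SMOTE: synthetic minority oversampling
#'
#' Grows the minority class with synthetic points interpolated between a
#' minority sample and one of its k nearest minority neighbours (Euclidean
#' metric, computed among minority samples only, in the scaled feature
#' space): `x_new = x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`.
#' Original samples are retained unchanged; synthetic points are appended
#' until the minority count reaches `target_ratio` times the majority
#' count.
#'
#' RNG contract (so an independent implementation can replay the stream):
#' after `set.seed(substream_seed(seed, "smote"))`, each synthetic point
#' consumes exactly three draws in this order — base index
#' `sample.int(n_minority, 1)`, neighbour slot `sample.int(k, 1)`,
#' interpolation weight `runif(1)`. Neighbour lists are the k smallest
#' Euclidean distances, ties broken by row order.
#'
#' @param x Numeric feature matrix.
#' @param y Binary activity vector.
#' @param k Number of nearest minority neighbours (reduced with a warning
#'   when fewer minority samples exist).
#' @param target_ratio Desired minority/majority ratio after oversampling.
#' @param seed Integer seed.
#' @return A list with `x`, `y` (originals first, synthetics appended) and
#'   `synthetic` (logical mask over the output rows).
#' @export
smote_oversample <- function(x, y, k = 5, target_ratio = 1, seed = 1) {
  y <- as_activity(y)
  stopifnot(is.matrix(x), nrow(x) == length(y), target_ratio > 0, k >= 1)
  counts <- table(y)
  if (any(counts == 0L)) stop("both classes must be present")
  min_cl <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min < 2L) stop("minority class must have at least 2 samples")
  if (k >= n_min) {
    warning(sprintf("k reduced from %d to %d (minority size)", k, n_min - 1L))
    k <- n_min - 1L
  }
  n_new <- max(0L, round(target_ratio * n_maj) - n_min)
  if (n_new == 0L) {
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  }
  idx_min <- which(y == min_cl)
  xm <- x[idx_min, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- matrix(apply(d, 1L, function(row) order(row)[seq_len(k)]),
               ncol = k, byrow = TRUE)

  set.seed(substream_seed(seed, "smote"))
  synth <- matrix(NA_real_, n_new, ncol(x))
  for (s in seq_len(n_new)) {
    i <- sample.int(n_min, 1L)
    j <- nn[i, sample.int(k, 1L)]
    u <- stats::runif(1L)
    synth[s, ] <- xm[i, ] + u * (xm[j, ] - xm[i, ])
  }
  colnames(synth) <- colnames(x)
  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(min_cl, n_new)),
                  levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, n_new)))
}

#' Balanced bootstrap indices for one tree
#'
#' Draws `n_min` samples with replacement from each class, where `n_min` is
#' the minority-class size: the per-tree undersampling of the majority
#' class that makes a forest a balanced random forest. Each call returns
#' the training multiset for a single tree.
#'
#' @param y Binary activity vector.
#' @param seed Integer seed.
#' @return Integer vector of `2 * n_min` row indices (minority draws first).
#' @export
balanced_bootstrap_indices <- function(y, seed = 1) {
  y <- as_activity(y)
  counts <- table(y)
  if (any(counts == 0L)) stop("both classes must be present")
  n_min <- min(counts)
  min_cl <- names(counts)[which.min(counts)]
  maj_cl <- setdiff(levels(y), min_cl)
  set.seed(substream_seed(seed, "balanced_bootstrap"))
  c(sample(which(y == min_cl), n_min, replace = TRUE),
    sample(which(y == maj_cl), n_min, replace = TRUE))
}
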