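## Descriptor-matrix preprocessing: missing-value / near-constancy /
## pairwise-correlation pruning, and z-scaling with statistics fitted on the
## training set only.

# population standard deviation (divisor N); the 0.01 near-constancy
# threshold is a screen, but the divisor convention must be fixed
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Prune a descriptor matrix
#'
#' Removes, in order: (1) descriptors with any missing value; (2) constant
#' or near-constant descriptors (population standard deviation below
#' `sd_min`); (3) one member of every highly correlated pair. The
#' correlation filter is greedy in stored column order: columns are scanned
#' left to right and a column is dropped when its absolute Pearson
#' correlation with any already-retained column exceeds `corr_max` (strict
#' inequality), so the earlier column of a correlated pair is always the one
#' kept. The rule is deterministic and documented because the retained set
#' depends on it.
#'
#' @param x Numeric matrix (compounds x descriptors) with column names.
#' @param sd_min Near-constancy threshold on the population SD.
#' @param corr_max Absolute pairwise-correlation threshold.
#' @return A list with `x` (pruned matrix) and `removed` (data frame
#'   `name,reason,detail`; reasons `missing`, `sd`, `correlation`).
#' @export
prune_descriptors <- function(x, sd_min = 0.01, corr_max = 0.95) {
  stopifnot(is.matrix(x), ncol(x) > 0L, !is.null(colnames(x)))
  if (anyDuplicated(colnames(x))) stop("duplicated descriptor names")
  removed <- data.frame(name = character(), reason = character(),
                        detail = character(), stringsAsFactors = FALSE)
  log_rm <- function(nm, reason, detail) {
    rbind(removed, data.frame(name = nm, reason = reason, detail = detail,
                              stringsAsFactors = FALSE))
  }
  miss <- colnames(x)[colSums(is.na(x)) > 0L]
  for (nm in miss) removed <- log_rm(nm, "missing", "contains missing values")
  x <- x[, setdiff(colnames(x), miss), drop = FALSE]

  if (ncol(x)) {
    sds <- apply(x, 2L, pop_sd)
    low <- colnames(x)[sds < sd_min]
    for (nm in low) {
      removed <- log_rm(nm, "sd", sprintf("sd = %.6g", sds[[nm]]))
    }
    x <- x[, setdiff(colnames(x), low), drop = FALSE]
  }

  if (ncol(x) > 1L) {
    keep <- 1L
    for (j in 2L:ncol(x)) {
      r <- abs(stats::cor(x[, keep, drop = FALSE], x[, j]))
      hit <- which(r > corr_max)
      if (length(hit)) {
        removed <- log_rm(colnames(x)[j], "correlation",
                          sprintf("|r| = %.4f with %s", max(r),
                                  colnames(x)[keep[hit[1L]]]))
      } else {
        keep <- c(keep, j)
      }
    }
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) == 0L) stop("no descriptors survive pruning")
  list(x = x, removed = removed)
}

#' Fit z-scaling statistics on training rows
#'
#' Column means and population standard deviations computed on the training
#' set only; test and external compounds are later transformed with these
#' training statistics, never their own.
#'
#' @param x Numeric matrix of training-set descriptor values.
#' @return Object of class `zscore_stats` (named means and sds).
#' @export
zscore_fit <- function(x) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  structure(list(mean = colMeans(x), sd = apply(x, 2L, pop_sd),
                 names = colnames(x)),
            class = "zscore_stats")
}

#' Apply fitted z-scaling statistics
#'
#' @param x Numeric matrix whose columns include the fitted descriptors.
#' @param stats A `zscore_stats` object from [zscore_fit()].
#' @return The matrix restricted to the fitted columns, centred and scaled
#'   with the training statistics.
#' @export
zscore_apply <- function(x, stats) {
  stopifnot(inherits(stats, "zscore_stats"))
  missing_cols <- setdiff(stats$names, colnames(x))
  if (length(missing_cols)) {
    stop("missing descriptor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(stats$sd == 0)) {
    stop("zero-variance column(s) in scaling statistics: ",
         paste(stats$names[stats$sd == 0], collapse = ", "),
         " (should have been pruned)")
  }
  x <- x[, stats$names, drop = FALSE]
  sweep(sweep(x, 2L, stats$mean, "-"), 2L, stats$sd, "/")
}

#' Read a descriptor CSV (first column `id`, remaining columns numeric)
#'
#' @param path File path.
#' @return Numeric matrix with compound ids as row names.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(df)[1L] == "id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$id)
  m
}

#' Write a descriptor matrix as CSV
#'
#' @param x Numeric matrix with compound ids as row names.
#' @param path Destination path.
#' @export
write_descriptors <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
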