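#' Derive a named RNG substream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so adding a new randomized operation never perturbs the draws
#' of existing ones. The substream seed is a deterministic 31-bit hash of the
#' master seed and the stream name.
#'
#' @param seed Integer master seed.
#' @param name Character stream name (e.g. `"smote"`, `"split"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

#' Round half away from zero
#'
#' Fixed-precision rounding used for reported statistics, matching the
#' convention of printed performance tables (0.005 rounds to 0.01). Base R's
#' `round()` rounds half to even, which disagrees on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Coerce a binary activity vector to the package's canonical factor
#'
#' Accepts a factor with two levels, a logical, a 0/1 numeric, or a character
#' vector with values `"inactive"`/`"active"`. Returns a factor with levels
#' `c("inactive", "active")`; the positive (active) class is always the
#' second level.
#'
#' @param y Binary class vector.
#' @return Factor with levels `inactive`, `active`.
#' @export
as_activity <- function(y) {
  lv <- c("inactive", "active")
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- ifelse(y, "active", "inactive")
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    y <- ifelse(y == 1, "active", "inactive")
  }
  y <- tolower(as.character(y))
  if (!all(y %in% lv)) {
    stop("activity labels must be binary (0/1, logical, or 'inactive'/'active')")
  }
  factor(y, levels = lv)
}

# internal: stratified fold assignment, deterministic given seed
stratified_folds <- function(y, nfolds, seed) {
  y <- as_activity(y)
  fold <- integer(length(y))
  set.seed(substream_seed(seed, "folds"))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  if (any(vapply(split(y, fold), function(v) length(unique(v)), 1L) < 2L)) {
    stop("a cross-validation fold contains a single class; reduce nfolds")
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
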