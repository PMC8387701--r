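# Confusion matrices, Cooper's statistics, MCC, Y-scrambling, domain
# curves and consensus.

test_that("confusion counts are correct and flip under label inversion", {
  cm <- confusion_matrix(c(1, 0, 1), c(1, 0, 1))
  expect_identical(unclass(cm)[c("tp", "tn", "fp", "fn")],
                   list(tp = 2L, tn = 1L, fp = 0L, fn = 0L))
  y_true <- c(1, 0, 1, 1, 0, 0, 1)
  y_pred <- c(1, 1, 0, 1, 0, 1, 0)
  a <- confusion_matrix(y_true, y_pred)
  b <- confusion_matrix(y_true, 1 - y_pred)
  expect_identical(b$tp, a$fn)
  expect_identical(b$fn, a$tp)
  expect_identical(b$tn, a$fp)
  expect_identical(b$fp, a$tn)
  expect_error(confusion_matrix(numeric(), numeric()), "empty")
  expect_error(confusion_matrix(c(1, 0), c(1)), "equal length")
})

test_that("cooper statistics and mcc reproduce published matrix columns", {
  for (nm in names(published_matrices())) {
    col <- published_matrices()[[nm]]
    cm <- confusion_from_counts(col$counts[["tn"]], col$counts[["fp"]],
                                col$counts[["tp"]], col$counts[["fn"]])
    cs <- cooper_stats(cm)
    got <- round_half_up(c(ba = cs[["ba"]], sen = cs[["sen"]],
                           spe = cs[["spe"]], mcc = mcc(cm)))
    expect_equal(got, col$stats, tolerance = 1e-12, label = nm)
  }
})

test_that("metric edge cases follow the documented conventions", {
  perfect <- confusion_from_counts(tn = 10, fp = 0, tp = 5, fn = 0)
  expect_equal(unname(cooper_stats(perfect)), c(1, 1, 1))
  expect_equal(mcc(perfect), 1)
  inverted <- confusion_from_counts(tn = 0, fp = 10, tp = 0, fn = 5)
  expect_equal(mcc(inverted), -1)
  # zero factor in the denominator -> MCC 0
  allneg <- confusion_from_counts(tn = 10, fp = 0, tp = 0, fn = 5)
  expect_identical(mcc(allneg), 0)
  expect_error(cooper_stats(confusion_from_counts(10, 2, 0, 0)),
               "no positive")
  expect_error(cooper_stats(confusion_from_counts(0, 0, 3, 1)),
               "no negative")
})

test_that("y-scrambling p-value follows (c+1)/(n+1) and is never zero", {
  d <- make_separable_data(n = 40, p = 3, seed = 1)
  fast_fit <- function(x, y, seed) {
    set.seed(seed)
    randomForest::randomForest(x, y, ntree = 20)
  }
  res <- y_scramble(d$x, d$y, fit_fun = fast_fit, n_permutations = 19,
                    nfolds = 4, seed = 1)
  expect_identical(res$p_value, (res$c + 1) / 20)
  expect_gt(res$p_value, res$c / 20)
  expect_lte(res$p_value, (res$c + 2) / 20)
  expect_gt(res$p_value, 0)
  # separable data: no permutation should beat the baseline
  expect_identical(res$c, 0L)
  expect_gt(res$baseline_score, mean(res$permuted_scores))
  expect_error(y_scramble(d$x, d$y, n_permutations = 0), "n_permutations")
})

test_that("domain curve is monotone and matches per-threshold recomputation", {
  set.seed(2)
  n <- 120
  y_true <- as_activity(rbinom(n, 1, 0.3))
  y_pred <- as_activity(rbinom(n, 1, 0.3))
  prob <- runif(n, 0.5, 1)
  th <- seq(0.5, 1, by = 0.05)
  dc <- domain_curve(prob, y_true, y_pred, th)
  expect_equal(dc$coverage[1], 1)
  expect_true(all(diff(dc$coverage) <= 1e-12))
  # brute-force oracle at every threshold
  for (i in seq_along(th)) {
    keep <- prob >= th[i]
    expect_equal(dc$coverage[i], mean(keep))
    if (any(keep) && length(unique(y_true[keep])) == 2) {
      expect_equal(dc$ba[i], balanced_accuracy(y_true[keep], y_pred[keep]),
                   label = sprintf("threshold %.2f", th[i]))
    }
  }
  # thresholds {0.5} equals the unfiltered report
  one <- domain_curve(prob, y_true, y_pred, 0.5)
  expect_equal(one$ba, classification_report(y_true, y_pred)$ba)
  # constant probabilities give constant coverage
  flat <- domain_curve(rep(1, n), y_true, y_pred, th)
  expect_true(all(flat$coverage == 1))
  expect_true(all(abs(flat$ba - flat$ba[1]) < 1e-12))
  expect_error(domain_curve(prob, y_true, y_pred, numeric()), "empty")
  expect_error(domain_curve(c(0.2, 0.8), c(0, 1), c(0, 1)), ">= 0.5")
})

test_that("consensus assigns labels to concordant compounds only", {
  # identical predictions: full coverage
  p <- as_activity(c(1, 0, 1, 0))
  full <- consensus(p, p)
  expect_equal(full$coverage, 1)
  # fully discordant: zero coverage, no metrics
  none <- consensus(p, as_activity(c(0, 1, 0, 1)), y_true = p)
  expect_equal(none$coverage, 0)
  expect_null(none$metrics)
  expect_true(all(is.na(none$label)))
  expect_error(consensus(p, p[1:2]), "aligned")
})

test_that("consensus metrics conserve the concordant count", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 80
    y <- as_activity(rbinom(n, 1, 0.25))
    a <- as_activity(rbinom(n, 1, 0.3))
    b <- as_activity(rbinom(n, 1, 0.3))
    cons <- consensus(a, b, y_true = y)
    n_conc <- sum(cons$status != "conflict")
    expect_equal(cons$coverage, n_conc / n)
    if (!is.null(cons$metrics)) {
      cm <- cons$metrics$confusion
      expect_identical(cm$tp + cm$tn + cm$fp + cm$fn, n_conc)
    }
    expect_identical(sum(cons$status == "concordant_correct"),
                     sum(!is.na(cons$label) & cons$label == y))
  }
})

test_that("the published consensus column is reproduced from its matrix", {
  cm <- confusion_from_counts(tn = 411, fp = 50, tp = 55, fn = 18)
  expect_equal(round_half_up(cooper_stats(cm)[["ba"]]), 0.82)
  expect_equal(round_half_up(mcc(cm)), 0.56)
  # concordance accounting: 534 of 631 external compounds concordant (~85%)
  expect_identical(411L + 50L + 55L + 18L, 534L)
  expect_equal(round_half_up(534 / 631), 0.85)
})
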