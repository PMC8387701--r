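# Classifier training, tuning and prediction.

test_that("a single grid point reduces to direct training with a CV report", {
  d <- make_separable_data(n = 60, p = 4, seed = 1)
  m <- qsar_train(d$x, d$y, "brf",
                  grid = data.frame(ntree = 50, mtry_rule = "sqrt"),
                  nfolds = 10, seed = 1)
  expect_s3_class(m, "qsar_model")
  expect_identical(nrow(m$cv_report), 10L)
  expect_identical(m$params$ntree, 50)
  expect_error(qsar_train(d$x, d$y, "brf", grid = data.frame()[0, ]),
               "empty")
})

test_that("every algorithm separates separable data at CV BA > 0.95", {
  d <- make_separable_data(n = 80, p = 4, seed = 2)
  grids <- list(
    brf = data.frame(ntree = 100, mtry_rule = "sqrt"),
    rf = data.frame(ntree = 100, mtry_rule = "sqrt"),
    knn = data.frame(k = 3, weighting = "uniform"),
    svm = data.frame(cost = 1, gamma = "scale"))
  for (alg in names(grids)) {
    m <- qsar_train(d$x, d$y, alg, grid = grids[[alg]], nfolds = 5,
                    seed = 2)
    expect_gt(mean(m$cv_report$ba), 0.95, label = alg)
    p <- predict(m, d$x, type = "prob")
    expect_true(all(p >= 0 & p <= 1), label = alg)
    # predicted-class probability is always >= 0.5
    both <- predict(m, d$x, type = "both")
    expect_true(all(both$probability_predicted_class >= 0.5), label = alg)
  }
})

test_that("training is deterministic given the seed", {
  d <- make_gaussian_data(n_inactive = 100, n_active = 25, n_features = 8,
                          seed = 3)
  for (alg in c("brf", "knn", "svm")) {
    g <- switch(alg,
                brf = data.frame(ntree = c(50, 100), mtry_rule = "sqrt"),
                knn = data.frame(k = c(3, 5), weighting = "uniform"),
                svm = data.frame(cost = c(1, 10), gamma = "scale"))
    a <- qsar_train(d$x, d$y, alg, grid = g, nfolds = 3, seed = 9)
    b <- qsar_train(d$x, d$y, alg, grid = g, nfolds = 3, seed = 9)
    expect_identical(a$params, b$params, label = alg)
    expect_identical(predict(a, d$x, "prob"), predict(b, d$x, "prob"),
                     label = alg)
  }
})

test_that("knn probabilities count neighbours; 0.5 ties go inactive", {
  # 4 active / 1 inactive among the 5 nearest of a probe point
  x <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(0.1, 0.1), c(0.05, 0.05),
             c(9, 9), c(10, 10), c(11, 11), c(10, 11), c(11, 10))
  colnames(x) <- c("a", "b")
  y <- rep(c("active", "inactive"), each = 5)
  y[5] <- "inactive"  # cluster 1 = 4 active + 1 inactive
  m <- qsar_train(x, y, "knn", grid = data.frame(k = 5,
                                                 weighting = "uniform"),
                  resample = "none", nfolds = 2, seed = 1)
  probe <- matrix(c(0.05, 0.04), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(m, probe, "prob"), 0.8)
  expect_identical(as.character(predict(m, probe)), "active")
  # an exact 0.5 probability yields the inactive label
  expect_identical(as.character(aurqsar:::prob_to_label(0.5)), "inactive")
  expect_identical(as.character(aurqsar:::prob_to_label(0.5 + 1e-9)), "active")
  # missing feature columns are named in the error
  expect_error(predict(m, probe[, 1, drop = FALSE]), "b")
})

test_that("brf refuses an external resampling plan", {
  d <- make_gaussian_data(n_inactive = 60, n_active = 20, seed = 4)
  expect_error(qsar_train(d$x, d$y, "brf", resample = "smote"),
               "not allowed")
})

test_that("brf balances sensitivity/specificity better than plain rf", {
  # tendency over seeds on 5:1 imbalanced data
  gaps <- vapply(1:10, function(s) {
    d <- make_gaussian_data(n_inactive = 150, n_active = 30,
                            n_features = 10, n_informative = 3,
                            effect = 1.0, seed = s)
    spl <- stratified_split(d$y, 0.25, seed = s)
    tr <- spl$split == "TrS"
    gap <- function(alg, resample) {
      m <- qsar_train(d$x[tr, ], d$y[tr], alg,
                      grid = data.frame(ntree = 100, mtry_rule = "sqrt"),
                      resample = resample, nfolds = 3, seed = s)
      cs <- cooper_stats(confusion_matrix(d$y[!tr],
                                          predict(m, d$x[!tr, ])))
      abs(cs[["sen"]] - cs[["spe"]])
    }
    c(brf = gap("brf", "none"), rf = gap("rf", "none"))
  }, numeric(2))
  expect_lt(mean(gaps["brf", ]), mean(gaps["rf", ]))
})

test_that("removing smote from knn reduces sensitivity on imbalanced data", {
  sens <- vapply(1:10, function(s) {
    d <- make_gaussian_data(n_inactive = 150, n_active = 30,
                            n_features = 10, n_informative = 3,
                            effect = 1.0, seed = 100 + s)
    spl <- stratified_split(d$y, 0.25, seed = s)
    tr <- spl$split == "TrS"
    sen <- function(resample) {
      m <- qsar_train(d$x[tr, ], d$y[tr], "knn",
                      grid = data.frame(k = 5, weighting = "uniform"),
                      resample = resample, nfolds = 3, seed = s)
      cooper_stats(confusion_matrix(d$y[!tr],
                                    predict(m, d$x[!tr, ])))[["sen"]]
    }
    c(with = sen("smote"), without = sen("none"))
  }, numeric(2))
  expect_gt(mean(sens["with", ]), mean(sens["without", ]))
})

test_that("prediction tables carry probabilities and the domain flag", {
  d <- make_separable_data(n = 40, p = 3, seed = 5)
  m <- qsar_train(d$x, d$y, "brf",
                  grid = data.frame(ntree = 50, mtry_rule = "sqrt"),
                  nfolds = 3, seed = 5)
  tab <- qsar_predict_table(m, d$x, ids = paste0("C", 1:40),
                            domain_threshold = 0.7)
  expect_identical(names(tab), c("id", "label", "probability_active",
                                 "probability_predicted_class",
                                 "in_domain"))
  expect_identical(tab$in_domain,
                   tab$probability_predicted_class >= 0.7)
  expect_equal(tab$probability_predicted_class,
               pmax(tab$probability_active, 1 - tab$probability_active))
})
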