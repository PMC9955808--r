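# well-separated three-class blobs in a handful of dimensions
make_blobs <- function(n_per_class = 15, d = 4, sep = 8, seed = 1) {
  set.seed(seed)
  centers <- diag(sep, 3, d)
  x <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(n_per_class * d, sd = 0.5), ncol = d), 2,
          centers[k, ], "+")
  }))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = as.data.frame(x),
       y = factor(rep(c("0", "1", "2"), each = n_per_class)))
}

test_that("classifier specifications carry the tuned defaults and reject typos", {
  svm <- classifier_spec("svm")
  expect_equal(svm$hyperparameters$C, 15)
  expect_identical(svm$hyperparameters$kernel, "RBF")
  expect_identical(svm$hyperparameters$gamma, "scale")
  rf <- classifier_spec("random_forest")
  expect_equal(rf$hyperparameters$n_estimators, 25)
  expect_equal(rf$hyperparameters$max_features, 3)
  expect_equal(classifier_spec("gaussian_nb")$hyperparameters$var_smoothing,
               0.1203)
  expect_identical(classifier_spec("decision_tree")$hyperparameters$criterion,
                   "entropy")
  expect_equal(classifier_spec("xgboost")$hyperparameters$n_estimators, 100)
  expect_error(classifier_spec("svm", kernle = "RBF"), "kernle")
})

test_that("every family trains, predicts its levels, and is seed-reproducible", {
  b <- make_blobs()
  for (fam in c("gaussian_nb", "decision_tree", "random_forest", "xgboost",
                "svm")) {
    spec <- classifier_spec(fam)
    m1 <- suppressWarnings(train_classifier(spec, b$x, b$y, seed = 7))
    m2 <- suppressWarnings(train_classifier(spec, b$x, b$y, seed = 7))
    p1 <- predict(m1, b$x)
    expect_s3_class(p1, "factor")
    expect_identical(levels(p1), c("0", "1", "2"))
    expect_gt(mean(p1 == b$y), 0.95)  # separable by construction
    expect_identical(p1, predict(m2, b$x))
  }
})

test_that("the built-in Gaussian naive Bayes matches a direct density computation", {
  b <- make_blobs(n_per_class = 10, d = 2)
  m <- train_classifier(classifier_spec("gaussian_nb", var_smoothing = 1e-9),
                        b$x, b$y, seed = 1)
  # independent oracle: per-class Gaussian log-likelihood + log prior
  x <- as.matrix(b$x)
  post <- sapply(levels(b$y), function(cl) {
    xc <- x[b$y == cl, ]
    mu <- colMeans(xc)
    va <- colMeans(sweep(xc, 2, mu)^2)
    rowSums(sapply(seq_len(ncol(x)), function(j) {
      dnorm(x[, j], mu[j], sqrt(va[j] + 1e-9 * max(apply(x, 2, function(cc)
        mean((cc - mean(cc))^2)))), log = TRUE)
    })) + log(mean(b$y == cl))
  })
  oracle <- levels(b$y)[apply(post, 1, which.max)]
  expect_identical(as.character(predict(m, b$x)), oracle)
})

test_that("cross-validated balanced accuracy is stratified and exact on separable data", {
  b <- make_blobs(n_per_class = 20)
  cv <- crossval_balanced_accuracy(classifier_spec("decision_tree"), b$x, b$y,
                                   k = 10, seed = 2)
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)
  expect_length(cv$per_fold, 10L)
  folds <- spastimas:::.stratified_folds(b$y, 5, seed = 1)
  for (cl in levels(b$y)) {
    expect_true(all(table(folds[b$y == cl]) == 4))
  }
  few <- c(1:5, 21:25, 41:45)  # five rows per class
  expect_error(crossval_balanced_accuracy(classifier_spec("svm"),
                                          b$x[few, ], b$y[few], k = 10),
               "smaller k")
})

test_that("grid search is exhaustive, deterministic and finds the better point", {
  b <- make_blobs(n_per_class = 12, d = 3)
  # one-point grid returns that point
  g1 <- grid_search("svm", b$x, b$y, grid = list(C = 2, kernel = "RBF",
                                                 gamma = "scale"),
                    k = 3, seed = 1)
  expect_equal(g1$best_spec$hyperparameters$C, 2)
  expect_identical(nrow(g1$scores), 1L)
  # score table has one row per grid point
  g2 <- grid_search("gaussian_nb", b$x, b$y,
                    grid = list(var_smoothing = c(1e-9, 1e-3, 1)), k = 3,
                    seed = 1)
  expect_identical(nrow(g2$scores), 3L)
  # tight, far-apart clusters: huge variance smoothing blurs the classes,
  # so minimal smoothing must win
  expect_equal(g2$best_spec$hyperparameters$var_smoothing, 1e-9)
  expect_error(grid_search("svm", b$x, b$y, grid = list()), "empty")
  # the published search ranges exist for every family
  for (fam in c("gaussian_nb", "decision_tree", "random_forest", "xgboost",
                "svm")) {
    expect_true(length(default_grid(fam)) >= 1)
  }
})

test_that("cascade training enforces its class contract and reproducibility", {
  tabs <- noisy_feature_table()
  fast <- select_fast(tabs$features)
  train <- suppressMessages(exclude_mas4(fast))
  model <- train_cascade(train, seed = 4)
  expect_s3_class(model, "cascade_model")
  probe <- fast[seq(1, nrow(fast), by = 7), ]
  p1 <- predict_cascade(model, probe[feature_names()], rom = probe$rom)
  model2 <- train_cascade(train, seed = 4)
  expect_identical(p1, predict_cascade(model2, probe[feature_names()],
                                       rom = probe$rom))

  expect_error(train_cascade(fast, seed = 1), "MAS 4")
  expect_error(train_cascade(train[train$mas_label != "3", ], seed = 1), "3")

  # archive round trip with schema check
  path <- withr::local_tempfile(fileext = ".rds")
  save_cascade(model, path)
  back <- load_cascade(path)
  expect_identical(predict_cascade(back, probe[feature_names()],
                                   rom = probe$rom), p1)
  broken <- model
  broken$schema_version <- "something-else"
  saveRDS(broken, path)
  expect_error(load_cascade(path), "schema")
})

test_that("cascade routing follows the ROM rule, SVM accept set and RF mask", {
  set.seed(1)
  casc <- stub_cascade(svm_label = "2", rf_probs = c(0.2, 0.5, 0.3))
  # limited ROM is grade 4 immediately, regardless of features
  expect_identical(as.character(predict_cascade(casc, one_feature_row(7.09))),
                   "4")
  # the rule is strict: exactly 10 degrees falls through to the models
  expect_identical(as.character(predict_cascade(casc, one_feature_row(10))),
                   "1+")  # stub SVM says "2" (not accepted) -> masked RF
  # SVM output accepted only for grades 1 and 3
  for (lab in c("1", "3")) {
    c2 <- stub_cascade(svm_label = lab)
    expect_identical(as.character(predict_cascade(c2, one_feature_row(90))),
                     lab)
  }
  for (lab in c("0", "1+", "2")) {
    c3 <- stub_cascade(svm_label = lab, rf_probs = c(0.1, 0.2, 0.7))
    expect_identical(as.character(predict_cascade(c3, one_feature_row(90))),
                     "2")
  }
  # RF probability ties break toward the lower grade
  c4 <- stub_cascade(svm_label = "0", rf_probs = c(0.4, 0.4, 0.2))
  expect_identical(as.character(predict_cascade(c4, one_feature_row(90))), "0")
  # NA features are rejected
  bad <- one_feature_row(90)
  bad$norm_avg_force <- NA
  expect_error(predict_cascade(casc, bad), "NA")
})

test_that("cascade label sets are invariant over random inputs", {
  set.seed(42)
  for (i in 1:25) {
    svm_lab <- sample(c("0", "1", "1+", "2", "3"), 1)
    probs <- runif(3)
    casc <- stub_cascade(svm_label = svm_lab, rf_probs = probs / sum(probs))
    rom <- runif(1, 0, 150)
    out <- as.character(predict_cascade(casc, one_feature_row(rom)))
    expect_true(out %in% mas_levels())
    if (rom >= 10) expect_false(out == "4")
    if (!svm_lab %in% c("1", "3")) {
      expect_true(out %in% c("0", "1+", "2"))
    }
  }
})
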