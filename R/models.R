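# Baseline classifiers with tuned hyperparameters, cross-validation with
# balanced accuracy, and exhaustive grid search.
#
# Hyperparameter names follow the common Python scikit-learn vocabulary so
# tuned settings transfer verbatim; each family maps them onto its R engine
# (rpart, randomForest, e1071, xgboost, plus a built-in Gaussian naive
# Bayes with variance smoothing). Engine-specific gaps are warned about and
# recorded on the model object.

.CLASSIFIER_FAMILIES <- c("gaussian_nb", "decision_tree", "random_forest",
                          "xgboost", "svm")

#' Tuned default hyperparameters per classifier family
#'
#' Defaults are the settings selected for the random-oversampled training
#' data during model development; see [classifier_spec()].
#'
#' @param family One of `"gaussian_nb"`, `"decision_tree"`,
#'   `"random_forest"`, `"xgboost"`, `"svm"`.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(family) {
  switch(match.arg(family, .CLASSIFIER_FAMILIES),
    gaussian_nb = list(var_smoothing = 0.1203),
    decision_tree = list(criterion = "entropy", min_samples_leaf = 3,
                         min_samples_split = 6, splitter = "best",
                         max_features = 8),
    random_forest = list(criterion = "gini", min_samples_leaf = 3,
                         min_samples_split = 6, max_features = 3,
                         n_estimators = 25),
    xgboost = list(booster = "gbtree", gamma = 0.1, learning_rate = 0.1,
                   min_child_weight = 5, n_estimators = 100,
                   objective = "multi:softprob"),
    svm = list(C = 15, kernel = "RBF", gamma = "scale"))
}

#' Specify a classifier configuration
#'
#' @param family Classifier family (see [default_hyperparameters()]).
#' @param ... Hyperparameter overrides; an unknown name is an error.
#' @return Object of class `classifier_spec`.
#' @export
#' @examples
#' classifier_spec("svm", C = 1)
classifier_spec <- function(family, ...) {
  family <- match.arg(family, .CLASSIFIER_FAMILIES)
  hp <- default_hyperparameters(family)
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(hp))
    if (length(unknown) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown hyperparameter(s) for ", family, ": ",
           paste(unknown, collapse = ", "))
    }
    hp[names(dots)] <- dots
  }
  structure(list(family = family, hyperparameters = hp),
            class = "classifier_spec")
}

# ---- Gaussian naive Bayes (with variance smoothing) ------------------------

.gnb_fit <- function(x, y, var_smoothing) {
  x <- as.matrix(x)
  lv <- levels(y)
  eps <- var_smoothing * max(apply(x, 2L, function(col) mean((col - mean(col))^2)))
  stats_by <- lapply(lv, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    va <- colMeans(sweep(xc, 2, mu)^2) + eps
    list(mu = mu, va = va, logprior = log(nrow(xc) / nrow(x)))
  })
  names(stats_by) <- lv
  list(levels = lv, stats = stats_by)
}

.gnb_predict <- function(fit, x, type = "label") {
  x <- as.matrix(x)
  ll <- vapply(fit$stats, function(s) {
    rowSums(dnorm(x, rep(s$mu, each = nrow(x)),
                  rep(sqrt(s$va), each = nrow(x)), log = TRUE)) + s$logprior
  }, numeric(nrow(x)))
  ll <- matrix(ll, nrow = nrow(x), dimnames = list(NULL, fit$levels))
  if (type == "prob") {
    p <- exp(ll - apply(ll, 1L, max))
    return(p / rowSums(p))
  }
  factor(fit$levels[max.col(ll, ties.method = "first")], levels = fit$levels)
}

# ---- training --------------------------------------------------------------

#' Train a classifier from a specification
#'
#' All stochastic components are seeded, so training is reproducible.
#' Hyperparameters without an equivalent in the R engine (`splitter` and
#' `max_features` for the single decision tree, non-default `criterion` or
#' `min_samples_split` for the random forest) trigger a warning and are
#' recorded in the returned object's `notes`.
#'
#' @param spec A [classifier_spec()].
#' @param x Feature data.frame/matrix (numeric).
#' @param y Class labels (factor or character).
#' @param seed Integer seed.
#' @return Object of class `mas_classifier` supporting
#'   `predict(object, newdata, type = c("label", "prob"))`.
#' @export
train_classifier <- function(spec, x, y, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- droplevels(as.factor(y))
  x <- as.data.frame(x)
  hp <- spec$hyperparameters
  notes <- character(0)
  set.seed(as.integer(seed))
  fit <- switch(spec$family,
    gaussian_nb = .gnb_fit(x, y, hp$var_smoothing),
    decision_tree = {
      if (!identical(hp$splitter, "best")) {
        warning("decision_tree: rpart has no random splitter; using best-split")
        notes <- c(notes, "splitter ignored")
      }
      notes <- c(notes, "max_features not supported by rpart; ignored")
      dat <- cbind(x, .y = y)
      rpart::rpart(.y ~ ., data = dat, method = "class",
                   parms = list(split = if (hp$criterion == "entropy")
                     "information" else "gini"),
                   control = rpart::rpart.control(
                     minsplit = hp$min_samples_split,
                     minbucket = hp$min_samples_leaf,
                     cp = 0, xval = 0, maxsurrogate = 0))
    },
    random_forest = {
      if (!identical(hp$criterion, "gini")) {
        warning("random_forest: randomForest supports Gini impurity only")
        notes <- c(notes, "criterion coerced to gini")
      }
      notes <- c(notes, "min_samples_split not supported by randomForest; ignored")
      randomForest::randomForest(
        x = x, y = y, ntree = hp$n_estimators,
        mtry = min(hp$max_features, ncol(x)),
        nodesize = hp$min_samples_leaf)
    },
    xgboost = {
      dm <- xgboost::xgb.DMatrix(data = as.matrix(x),
                                 label = as.integer(y) - 1L)
      params <- list(booster = hp$booster, objective = hp$objective,
                     num_class = nlevels(y), eta = hp$learning_rate,
                     gamma = hp$gamma, min_child_weight = hp$min_child_weight,
                     nthread = 1)
      xgboost::xgb.train(params = params, data = dm,
                         nrounds = hp$n_estimators, verbose = 0)
    },
    svm = {
      xm <- as.matrix(x)
      g <- if (identical(hp$gamma, "scale")) {
        v <- mean((xm - mean(xm))^2)
        1 / (ncol(xm) * max(v, 1e-12))
      } else if (identical(hp$gamma, "auto")) {
        1 / ncol(xm)
      } else as.numeric(hp$gamma)
      e1071::svm(x = xm, y = y, type = "C-classification",
                 kernel = if (hp$kernel == "RBF") "radial" else "linear",
                 cost = hp$C, gamma = g, scale = FALSE)
    })
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 features = colnames(x), notes = notes, seed = seed),
            class = "mas_classifier")
}

#' A classifier with caller-supplied decision functions
#'
#' Wraps fixed label/probability functions in the `mas_classifier`
#' interface. Useful for composing rule-based stages and for tracing the
#' cascade's routing logic with deterministic stand-ins.
#'
#' @param levels Class levels the classifier emits.
#' @param label_fun `function(x)` returning a label per row of `x`.
#' @param prob_fun `function(x)` returning a probability matrix (columns
#'   named by `levels`) per row of `x`.
#' @return Object of class `mas_classifier`.
#' @export
manual_classifier <- function(levels, label_fun = NULL, prob_fun = NULL) {
  structure(list(spec = list(family = "manual", hyperparameters = list()),
                 fit = list(label_fun = label_fun, prob_fun = prob_fun),
                 levels = levels, features = NULL, notes = character(0)),
            class = "mas_classifier")
}

#' Predict method for trained classifiers
#'
#' @param object A `mas_classifier`.
#' @param newdata Feature data.frame/matrix.
#' @param type `"label"` (default) for class labels, `"prob"` for a
#'   class-probability matrix.
#' @param ... Ignored.
#' @return Factor of labels, or a numeric matrix with one column per class.
#' @export
predict.mas_classifier <- function(object, newdata, type = c("label", "prob"),
                                   ...) {
  type <- match.arg(type)
  x <- as.data.frame(newdata)
  if (!is.null(object$features)) x <- x[object$features]
  lv <- object$levels
  fam <- object$spec$family
  if (fam == "manual") {
    if (type == "label") {
      if (is.null(object$fit$label_fun)) stop("manual classifier has no label_fun")
      return(factor(as.character(object$fit$label_fun(x)), levels = lv))
    }
    if (is.null(object$fit$prob_fun)) stop("manual classifier has no prob_fun")
    p <- object$fit$prob_fun(x)
    return(matrix(p, ncol = length(lv), dimnames = list(NULL, lv)))
  }
  if (fam == "gaussian_nb") return(.gnb_predict(object$fit, x, type))
  if (fam == "decision_tree") {
    p <- predict(object$fit, x, type = "prob")
    if (type == "prob") return(p[, lv, drop = FALSE])
    return(factor(lv[max.col(p[, lv, drop = FALSE], ties.method = "first")],
                  levels = lv))
  }
  if (fam == "random_forest") {
    if (type == "prob") {
      p <- predict(object$fit, x, type = "prob")
      return(p[, lv, drop = FALSE])
    }
    return(factor(as.character(predict(object$fit, x)), levels = lv))
  }
  if (fam == "xgboost") {
    p <- predict(object$fit, as.matrix(x))
    if (!is.matrix(p)) p <- matrix(p, ncol = length(lv), byrow = TRUE)
    colnames(p) <- lv
    if (type == "prob") return(p)
    return(factor(lv[max.col(p, ties.method = "first")], levels = lv))
  }
  if (fam == "svm") {
    if (type == "prob") stop("probability output not enabled for the SVM")
    return(factor(as.character(predict(object$fit, as.matrix(x))), levels = lv))
  }
  stop("unknown classifier family: ", fam)
}

# stratified fold assignment: per class, shuffled fold ids
.stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Cross-validated balanced accuracy
#'
#' Stratified k-fold cross-validation scored by balanced accuracy (the mean
#' of per-class recall, which equals plain accuracy when class counts are
#' equal, as after upsampling).
#'
#' @param spec A [classifier_spec()].
#' @param x,y Features and labels.
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and training.
#' @return List with `mean`, `sd` and `per_fold` balanced accuracies.
#' @export
crossval_balanced_accuracy <- function(spec, x, y, k = 10, seed = 1) {
  y <- droplevels(as.factor(y))
  x <- as.data.frame(x)
  counts <- table(y)
  if (any(counts < k)) {
    stop("class(es) ", paste(names(counts)[counts < k], collapse = ", "),
         " have fewer than k = ", k, " rows; use a smaller k")
  }
  folds <- .stratified_folds(y, k, seed)
  scores <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    model <- train_classifier(spec, x[tr, , drop = FALSE], y[tr],
                              seed = as.integer(seed) + f)
    pred <- predict(model, x[!tr, , drop = FALSE])
    balanced_accuracy(y[!tr], pred)
  }, numeric(1))
  list(mean = mean(scores), sd = sd(scores), per_fold = scores)
}

#' Default hyperparameter search grids
#'
#' The exhaustive search ranges used during model development. The single
#' decision tree keeps its `splitter` choice; the forest does not (no such
#' parameter exists for bagged ensembles).
#'
#' @inheritParams default_hyperparameters
#' @return Named list of candidate value vectors.
#' @export
default_grid <- function(family) {
  switch(match.arg(family, .CLASSIFIER_FAMILIES),
    gaussian_nb = list(var_smoothing = 10^seq(-9, 0)),
    decision_tree = list(criterion = c("gini", "entropy"),
                         min_samples_leaf = 2:20, min_samples_split = 2:20,
                         splitter = c("best", "random"), max_features = 2:10),
    random_forest = list(criterion = c("gini", "entropy"),
                         min_samples_leaf = 2:20, min_samples_split = 2:20,
                         max_features = 2:10,
                         n_estimators = c(25, 50, 75, 100)),
    xgboost = list(gamma = c(0.5, 1.5, 2, 5),
                   learning_rate = c(0.01, 0.05, 0.1, 0.5),
                   min_child_weight = c(5, 10),
                   n_estimators = c(50, 100, 200)),
    svm = list(kernel = c("linear", "RBF"), gamma = c("scale", "auto"),
               C = c(0.01, 0.1, 1, 10, 100)))
}

#' Exhaustive grid search with internal cross-validation
#'
#' Evaluates every grid point with [crossval_balanced_accuracy()] and
#' returns the best specification plus the full score table. Deterministic
#' given `seed`; ties keep the earliest grid point.
#'
#' @param family Classifier family.
#' @param x,y Training features and labels.
#' @param grid Named list of candidate values (default: [default_grid()]).
#' @param k Internal CV folds (default 5).
#' @param seed Integer seed.
#' @return List with `best_spec`, `best_score` and `scores` (one row per
#'   grid point, in grid order).
#' @export
grid_search <- function(family, x, y, grid = default_grid(family), k = 5,
                        seed = 1) {
  family <- match.arg(family, .CLASSIFIER_FAMILIES)
  if (!length(grid) || any(!lengths(grid))) stop("empty hyperparameter grid")
  tab <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  scores <- vapply(seq_len(nrow(tab)), function(i) {
    spec <- do.call(classifier_spec, c(list(family = family), as.list(tab[i, , drop = FALSE])))
    crossval_balanced_accuracy(spec, x, y, k = k, seed = seed)$mean
  }, numeric(1))
  best <- which.max(scores)
  list(best_spec = do.call(classifier_spec,
                           c(list(family = family), as.list(tab[best, , drop = FALSE]))),
       best_score = scores[best],
       scores = cbind(tab, balanced_accuracy = scores))
}
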