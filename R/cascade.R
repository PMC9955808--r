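# The Logical-SVM-RF classifier cascade.
#
# Routing (in order):
#   1. ROM rule: range of motion < rom_threshold (10 deg) -> MAS "4".
#   2. SVM stage: a 5-class SVM; its prediction is accepted only when it is
#      MAS "1" or "3" (the grades it separates best).
#   3. RF stage: a 5-class random forest whose class probabilities are
#      masked to {"0", "1+", "2"}, renormalised, and argmax-ed; probability
#      ties break toward the lower (clinically conservative) grade.

.CASCADE_TRAIN_CLASSES <- c("0", "1", "1+", "2", "3")
.CASCADE_SCHEMA <- "spastimas-cascade-1"

#' Train the Logical-SVM-RF cascade
#'
#' Fits the standard scaler on the training rows, balances classes by
#' random oversampling, and trains the tuned SVM and random-forest
#' specifications on all five learnable grades. MAS 4 is handled entirely
#' by the range-of-motion rule and must not appear in the training data.
#'
#' @param train Labelled feature table containing exactly the five grades
#'   `"0", "1", "1+", "2", "3"`.
#' @param seed Integer seed (scaling is deterministic; oversampling and the
#'   two model fits derive their seeds from it).
#' @param rom_threshold ROM rule threshold in degrees (default 10; a strict
#'   `<` comparison is used).
#' @param svm_spec,rf_spec Sub-model specifications; defaults are the tuned
#'   settings of [default_hyperparameters()].
#' @param feature_cols Feature columns used by the sub-models.
#' @return Object of class `cascade_model`.
#' @export
train_cascade <- function(train, seed = 1, rom_threshold = 10,
                          svm_spec = classifier_spec("svm"),
                          rf_spec = classifier_spec("random_forest"),
                          feature_cols = NULL) {
  lab <- as.character(train$mas_label)
  if (any(lab == "4", na.rm = TRUE)) {
    stop("training data contains MAS 4 rows; exclude them (exclude_mas4) ",
         "- MAS 4 is handled by the ROM rule")
  }
  missing <- setdiff(.CASCADE_TRAIN_CLASSES, unique(lab))
  if (length(missing)) {
    stop("training data is missing MAS class(es): ",
         paste(missing, collapse = ", "))
  }
  if (is.null(feature_cols)) feature_cols <- .dataset_features(train)
  seed <- as.integer(seed)
  scaler <- fit_scaler(train, feature_cols)
  scaled <- apply_scaler(scaler, train)
  up <- ros_upsample(scaled, seed = seed)
  y <- factor(as.character(up$mas_label), levels = .CASCADE_TRAIN_CLASSES)
  x <- up[feature_cols]
  svm <- train_classifier(svm_spec, x, y, seed = seed + 1L)
  rf <- train_classifier(rf_spec, x, y, seed = seed + 2L)
  structure(list(rom_threshold = rom_threshold, svm = svm, rf = rf,
                 scaler = scaler, svm_accept_set = c("1", "3"),
                 rf_allowed_set = c("0", "1+", "2"),
                 feature_cols = feature_cols, seed = seed,
                 schema_version = .CASCADE_SCHEMA),
            class = "cascade_model")
}

#' Predict MAS grades with the cascade
#'
#' Applies, per row: the ROM rule (strictly below the threshold means
#' MAS 4), then the SVM stage (accepted only for grades 1 and 3), then the
#' masked random-forest stage over grades 0, 1+ and 2. Features are scaled
#' internally with the model's stored scaler; they must be on the raw
#' (unscaled) feature scale.
#'
#' @param model A `cascade_model`.
#' @param features Feature table (one row per stretch) or a single named
#'   numeric vector.
#' @param rom Range of motion (deg) per row; defaults to the `rom` feature
#'   column.
#' @return Factor of MAS grades with levels [mas_levels()].
#' @export
predict_cascade <- function(model, features, rom = NULL) {
  stopifnot(inherits(model, "cascade_model"))
  if (is.numeric(features) && !is.null(names(features))) {
    features <- as.data.frame(as.list(features))
  }
  features <- as.data.frame(features)
  if (is.null(rom)) {
    if (!"rom" %in% names(features)) stop("rom not supplied and no rom column")
    rom <- features$rom
  }
  n <- nrow(features)
  if (length(rom) != n) stop("rom must have one value per feature row")
  x <- features[model$feature_cols]
  if (anyNA(x) || anyNA(rom)) stop("missing (NA) feature values")
  out <- character(n)
  is4 <- rom < model$rom_threshold
  out[is4] <- "4"
  rest <- which(!is4)
  if (length(rest)) {
    xs <- apply_scaler(model$scaler, x[rest, , drop = FALSE])
    svm_pred <- as.character(predict(model$svm, xs))
    accept <- svm_pred %in% model$svm_accept_set
    out[rest[accept]] <- svm_pred[accept]
    todo <- rest[!accept]
    if (length(todo)) {
      prob <- predict(model$rf, xs[!accept, , drop = FALSE], type = "prob")
      prob <- prob[, model$rf_allowed_set, drop = FALSE]
      denom <- rowSums(prob)
      prob[denom > 0, ] <- prob[denom > 0, , drop = FALSE] / denom[denom > 0]
      # ties (and an all-zero mask) resolve to the lowest grade: allowed-set
      # columns are in ascending MAS order and max.col takes the first max
      pick <- max.col(prob, ties.method = "first")
      out[todo] <- model$rf_allowed_set[pick]
    }
  }
  factor(out, levels = .MAS_LEVELS)
}

#' Save / load a trained cascade
#'
#' The archive bundles the scaler, both sub-models, the ROM threshold,
#' class-set metadata, the training seed and a schema version that is
#' checked on load.
#'
#' @param model A `cascade_model`.
#' @param path File path for the archive.
#' @return `save_cascade()`: `path` invisibly; `load_cascade()`: the model.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cascade_model") ||
      !identical(model$schema_version, .CASCADE_SCHEMA)) {
    stop("archive is not a compatible cascade model (schema mismatch)")
  }
  model
}
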