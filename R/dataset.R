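# Training/evaluation dataset preparation: fast-stretch selection, MAS-4
# exclusion, stratified splitting, standard scaling, upsampling.
#
# Canonical pipeline order (training path):
#   select_fast -> split -> exclude_mas4 on the train partition ->
#   fit_scaler on train -> apply_scaler -> ros_upsample/smote_upsample.
# The scaler is always fitted before upsampling, on training rows only.

.dataset_features <- function(df) intersect(feature_names(), names(df))

#' Keep only fast stretches
#'
#' Only fast passive stretches elicit the velocity-dependent catch, so slow
#' stretches are excluded from classifier datasets.
#'
#' @param df Feature table with a `speed` column.
#' @return Rows with `speed == "fast"`; warns if none remain.
#' @export
select_fast <- function(df) {
  out <- df[df$speed == "fast", , drop = FALSE]
  if (nrow(out) == 0L) warning("no fast stretches in dataset")
  rownames(out) <- NULL
  out
}

#' Remove MAS 4 rows from a training dataset
#'
#' MAS 4 (rigid limb) is diagnosed by the range-of-motion rule in the
#' cascade, not learned by the classifiers, so its rows are removed from
#' classifier training sets.
#'
#' @param df Feature table with a `mas_label` column.
#' @return Table without `"4"` rows; the removal count is reported via
#'   `message()`, and an all-`"4"` input warns.
#' @export
exclude_mas4 <- function(df) {
  drop <- !is.na(df$mas_label) & df$mas_label == "4"
  if (any(drop)) message("excluding ", sum(drop), " MAS 4 row(s) from training")
  out <- df[!drop, , drop = FALSE]
  if (nrow(out) == 0L) warning("no rows remain after MAS 4 exclusion")
  rownames(out) <- NULL
  out
}

# largest-remainder allocation of per-class test counts
.allocate_test <- function(counts, frac) {
  quota <- counts * frac
  base <- floor(quota)
  target <- round(sum(counts) * frac)
  extra <- target - sum(base)
  rem <- quota - base
  alloc <- base
  if (extra > 0) {
    ord <- order(-rem, seq_along(rem))  # ties break by class order
    alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1
  } else if (extra < 0) {
    elig <- which(alloc > 0)
    ord <- elig[order(rem[elig], seq_along(rem)[elig])]
    take <- ord[seq_len(min(-extra, length(ord)))]
    alloc[take] <- alloc[take] - 1
  }
  # every class with >= 2 rows gets at least one test row
  for (i in which(alloc == 0 & counts >= 2)) {
    donor <- which.max(alloc)
    if (alloc[donor] > 1) {
      alloc[donor] <- alloc[donor] - 1
      alloc[i] <- 1
    }
  }
  alloc[alloc > counts] <- counts[alloc > counts]
  as.integer(alloc)
}

#' Stratified train/test split
#'
#' Splits by stretch row, stratified on the MAS label. Per-class test counts
#' follow a largest-remainder allocation so the test total is
#' `round(n * test_frac)` and each class with at least two rows contributes
#' at least one test row; a single-row class goes entirely to train with a
#' warning. Deterministic given `seed`.
#'
#' @param df Feature table with a `mas_label` column.
#' @param test_frac Test-set fraction (default 0.1, i.e. a 90:10 split).
#' @param seed Integer RNG seed.
#' @param group_by_subject If `TRUE`, whole subjects are assigned to one
#'   partition (stricter, leakage-free at the subject level); the per-class
#'   allocation then applies to subject counts.
#' @return List with `train` and `test` data.frames (disjoint rows).
#' @export
stratified_split <- function(df, test_frac = 0.1, seed = 1,
                             group_by_subject = FALSE) {
  lab <- as.character(df$mas_label)
  if (anyNA(lab)) stop("stratified_split requires labels on every row")
  classes <- .MAS_LEVELS[.MAS_LEVELS %in% lab]
  set.seed(as.integer(seed))
  test_rows <- integer(0)
  if (group_by_subject) {
    units <- lapply(classes, function(cl) unique(df$subject_id[lab == cl]))
  } else {
    units <- lapply(classes, function(cl) which(lab == cl))
  }
  counts <- vapply(units, length, integer(1))
  singles <- classes[counts == 1L]
  if (length(singles)) {
    warning("class(es) with a single row kept entirely in train: ",
            paste(singles, collapse = ", "))
  }
  alloc <- .allocate_test(counts, test_frac)
  alloc[counts == 1L] <- 0L
  for (k in seq_along(classes)) {
    if (alloc[k] == 0L) next
    chosen <- sample(units[[k]], alloc[k])
    if (group_by_subject) {
      test_rows <- c(test_rows, which(df$subject_id %in% chosen & lab == classes[k]))
    } else {
      test_rows <- c(test_rows, chosen)
    }
  }
  test_rows <- sort(test_rows)
  list(train = `rownames<-`(df[setdiff(seq_len(nrow(df)), test_rows), , drop = FALSE], NULL),
       test = `rownames<-`(df[test_rows, , drop = FALSE], NULL))
}

#' Fit a standard scaler on training rows
#'
#' Per-feature mean removal and scaling to unit variance (population
#' standard deviation, matching the convention of the common Python
#' scikit-learn scaler). Constant features get unit scale with a warning
#' and are flagged.
#'
#' @param train Training feature table (or matrix of features).
#' @param feature_cols Feature columns to scale; defaults to the canonical
#'   17 present in `train`.
#' @return Object of class `scaler_params` with `mean`, `sd`, `constant`.
#' @export
fit_scaler <- function(train, feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- .dataset_features(train)
  x <- as.matrix(train[feature_cols])
  if (anyNA(x)) stop("missing feature values in training data")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))
  constant <- sdev <= 1e-12
  if (any(constant)) {
    warning("constant feature(s) scaled with unit variance: ",
            paste(feature_cols[constant], collapse = ", "))
    sdev[constant] <- 1
  }
  structure(list(feature = feature_cols, mean = mu, sd = sdev,
                 constant = constant),
            class = "scaler_params")
}

#' Apply fitted scaler parameters
#'
#' @param params A `scaler_params` from [fit_scaler()].
#' @param df Feature table containing the scaler's feature columns.
#' @return `df` with the feature columns standardised.
#' @export
apply_scaler <- function(params, df) {
  x <- as.matrix(df[params$feature])
  x <- sweep(sweep(x, 2, params$mean), 2, params$sd, "/")
  df[params$feature] <- as.data.frame(x)
  df
}

#' Serialise scaler parameters to/from JSON
#'
#' @param params A `scaler_params`.
#' @return `scaler_to_json()`: a JSON string mapping feature name to
#'   mean/sd; `scaler_from_json()`: the `scaler_params` object.
#' @export
scaler_to_json <- function(params) {
  obj <- stats::setNames(
    lapply(seq_along(params$feature), function(i) {
      list(mean = unname(params$mean[i]), sd = unname(params$sd[i]),
           constant = unname(params$constant[i]))
    }), params$feature)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' @rdname scaler_to_json
#' @param json JSON string produced by `scaler_to_json()`.
#' @export
scaler_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  feats <- names(obj)
  structure(list(
    feature = feats,
    mean = stats::setNames(vapply(obj, `[[`, numeric(1), "mean"), feats),
    sd = stats::setNames(vapply(obj, `[[`, numeric(1), "sd"), feats),
    constant = stats::setNames(vapply(obj, `[[`, logical(1), "constant"), feats)),
    class = "scaler_params")
}

#' Random oversampling (ROS) to balanced class counts
#'
#' Duplicates randomly chosen rows of each minority class until every class
#' count equals the majority count. Only exact duplicates are added.
#' Deterministic given `seed`.
#'
#' @param df Labelled feature table (`mas_label` column).
#' @param seed Integer RNG seed.
#' @return Upsampled table; class counts are exactly equal.
#' @export
ros_upsample <- function(df, seed = 1) {
  lab <- as.character(df$mas_label)
  if (anyNA(lab)) stop("ros_upsample requires labels on every row")
  counts <- table(lab)
  if (any(counts == 0)) stop("empty class in dataset")
  maj <- max(counts)
  set.seed(as.integer(seed))
  extra <- integer(0)
  for (cl in .MAS_LEVELS[.MAS_LEVELS %in% lab]) {
    idx <- which(lab == cl)
    need <- maj - length(idx)
    if (need > 0) extra <- c(extra, sample(idx, need, replace = TRUE))
  }
  out <- rbind(df, df[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' SMOTE upsampling to balanced class counts
#'
#' Synthetic-minority oversampling: each synthetic row is a convex
#' combination of a randomly chosen minority row and one of its
#' `k_neighbors` nearest same-class neighbours (Euclidean distance in
#' feature space). `k` is reduced with a warning for classes with too few
#' rows; a single-row class falls back to duplication. Deterministic given
#' `seed`.
#'
#' @param df Labelled feature table.
#' @param k_neighbors Number of nearest neighbours (default 5).
#' @param seed Integer RNG seed.
#' @return Upsampled table; class counts are exactly equal.
#' @export
smote_upsample <- function(df, k_neighbors = 5, seed = 1) {
  lab <- as.character(df$mas_label)
  if (anyNA(lab)) stop("smote_upsample requires labels on every row")
  counts <- table(lab)
  if (any(counts == 0)) stop("empty class in dataset")
  maj <- max(counts)
  feats <- .dataset_features(df)
  x <- as.matrix(df[feats])
  set.seed(as.integer(seed))
  synth <- list()
  for (cl in .MAS_LEVELS[.MAS_LEVELS %in% lab]) {
    idx <- which(lab == cl)
    need <- maj - length(idx)
    if (need <= 0) next
    if (length(idx) == 1L) {
      warning("class ", cl, " has a single row; SMOTE falls back to duplication")
      synth[[cl]] <- df[rep(idx, need), , drop = FALSE]
      next
    }
    k <- min(k_neighbors, length(idx) - 1L)
    if (k < k_neighbors) {
      warning("class ", cl, ": k_neighbors reduced to ", k)
    }
    dm <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
    diag(dm) <- Inf
    nn <- apply(dm, 1L, function(d) order(d)[seq_len(k)])
    nn <- matrix(nn, nrow = k)  # k x n_class
    base <- sample(seq_along(idx), need, replace = TRUE)
    pick <- vapply(base, function(b) nn[sample.int(k, 1L), b], integer(1))
    lam <- runif(need)
    new_x <- x[idx[base], , drop = FALSE] +
      lam * (x[idx[pick], , drop = FALSE] - x[idx[base], , drop = FALSE])
    rows <- df[idx[base], , drop = FALSE]
    rows[feats] <- as.data.frame(new_x)
    synth[[cl]] <- rows
  }
  out <- rbind(df, do.call(rbind, synth))
  rownames(out) <- NULL
  out
}
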