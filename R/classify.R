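## Stage models and cross-validation. Backends are the field's standard
## estimators (libsvm via e1071, randomForest); preprocessing (min-max
## ranges), optional MRMD selection, stratified fold assignment, and the
## pooled Sn/OA/AA evaluation are implemented here. Preprocessing and
## selection are always fitted on training folds only.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stratified fold assignment keyed on ids sorted before shuffling, so the
## id -> fold map is invariant to instance order. Classes are visited in
## sorted label order for the same reason.
make_folds <- function(labels, ids, folds, seed) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (min(counts) < folds) {
    folds <- max(2L, as.integer(min(counts)))
    warning("smallest class has ", min(counts),
            " instances; folds reduced to ", folds, call. = FALSE)
  }
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  fold <- integer(length(ids))
  with_seed(seed, {
    for (lvl in sort(unique(labels))) {
      members <- which(labels == lvl)
      members <- members[order(ids[members], method = "radix")]
      members <- members[sample.int(length(members))]
      fold[members] <- rep(seq_len(folds), length.out = length(members))
    }
  })
  list(fold = fold, folds = folds)
}

#' Train a single-stage classifier
#'
#' Fits per-feature min-max scaling on the training data, optionally an
#' MRMD feature selection, and then the backend estimator. Everything
#' needed to reapply the model exactly (ranges, selected feature names,
#' hyperparameters, class order) is captured in the returned object.
#'
#' @param x Instances-by-features numeric matrix (rownames = ids).
#' @param y Class labels (vector or factor).
#' @param backend `"random-forest"` (default) or `"svm-rbf"`.
#' @param params Backend hyperparameters: `ntree` and `seed` for the
#'   forest (defaults 100, 1); `cost` and `gamma` for the RBF SVM
#'   (defaults 1 and 1/n_features).
#' @param selection Optional list with element `m` (an integer or
#'   `"auto"`): MRMD selection applied to the scaled training matrix.
#' @param scale Fit min-max scaling (default TRUE). Disable only when the
#'   matrix is already on a common scale.
#' @return An `icp_stage` model.
#' @export
train_stage <- function(x, y, backend = c("random-forest", "svm-rbf"),
                        params = list(), selection = NULL, scale = TRUE) {
  backend <- match.arg(backend)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  yf <- if (is.factor(y)) droplevels(y) else factor(y, levels = unique(as.character(y)))
  counts <- table(yf)
  if (any(counts < 2L)) {
    stop("class(es) with fewer than 2 training instances: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  rmin <- apply(x, 2L, min)
  rmax <- apply(x, 2L, max)
  xs <- if (scale) scale_by_range(x, rmin, rmax) else x
  selected <- colnames(x)
  if (!is.null(selection)) {
    sel <- mrmd_select(xs, as.character(yf), m = selection$m %||% "auto",
                       weights = selection$weights %||% c(1, 1),
                       seed = params$seed %||% 1L)
    xs <- sel$matrix
    selected <- sel$features
  }
  seed <- params$seed %||% 1L
  fit <- switch(backend,
    `random-forest` = with_seed(seed,
      randomForest::randomForest(x = xs, y = yf,
                                 ntree = params$ntree %||% 100L)),
    `svm-rbf` = e1071::svm(x = xs, y = yf, kernel = "radial",
                           cost = params$cost %||% 1,
                           gamma = params$gamma %||% (1 / ncol(xs)),
                           scale = FALSE))
  structure(list(backend = backend, fit = fit,
                 input_features = colnames(x),
                 rmin = rmin, rmax = rmax, scale = scale,
                 selected = selected,
                 params = list(ntree = params$ntree %||% 100L,
                               cost = params$cost %||% 1,
                               gamma = params$gamma %||% (1 / ncol(xs)),
                               seed = seed),
                 classes = levels(yf)),
            class = "icp_stage")
}

scale_by_range <- function(x, rmin, rmax) {
  span <- rmax - rmin
  span[span == 0] <- 1
  sweep(sweep(x, 2L, rmin, "-"), 2L, span, "/")
}

#' Predict with a fitted stage model
#'
#' @param object An `icp_stage`.
#' @param newdata Numeric matrix (or single named vector) whose columns
#'   match the feature set the stage was trained on; a mismatch is an
#'   error, not a silent reorder of unknown columns.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.icp_stage <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, names(newdata)))
  if (ncol(newdata) != length(object$input_features) ||
      !setequal(colnames(newdata), object$input_features)) {
    stop("feature mismatch: model expects ", length(object$input_features),
         " features (", object$backend, " stage); got ", ncol(newdata),
         call. = FALSE)
  }
  newdata <- newdata[, object$input_features, drop = FALSE]
  xs <- if (object$scale) scale_by_range(newdata, object$rmin, object$rmax) else newdata
  xs <- xs[, object$selected, drop = FALSE]
  as.character(stats::predict(object$fit, xs))
}

#' Stratified k-fold cross-validation with pooled metrics
#'
#' Seeded stratified fold assignment (keyed on ids sorted before shuffling,
#' so the result is invariant to instance order); per fold, preprocessing,
#' optional MRMD selection, and the estimator are fitted on the other folds
#' only, and the held-out fold is predicted. Sn/OA/AA are computed from the
#' confusion matrix pooled over all folds. If the smallest class has fewer
#' instances than `folds`, the fold count is reduced with a warning.
#'
#' @inheritParams train_stage
#' @param folds Number of folds (default 10).
#' @param seed Seed for the fold assignment and seeded backends.
#' @return An `icp_cv` list: `confusion`, `metrics` (`sn`, `oa`, `aa`),
#'   `fold_oa` (per-fold OA), `fold` (assignment), `folds`, `seed`,
#'   `backend`, `params`.
#' @export
cross_validate <- function(x, y, folds = 10L, seed = 1L,
                           backend = c("random-forest", "svm-rbf"),
                           params = list(), selection = NULL, scale = TRUE) {
  backend <- match.arg(backend)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  y <- as.character(y)
  fa <- make_folds(y, ids, folds, seed)
  levels_sorted <- sort(unique(y))
  pred <- character(nrow(x))
  fold_oa <- numeric(fa$folds)
  for (f in seq_len(fa$folds)) {
    test <- fa$fold == f
    model <- train_stage(x[!test, , drop = FALSE],
                         factor(y[!test], levels = levels_sorted),
                         backend = backend,
                         params = c(params, list(seed = (params$seed %||% seed))),
                         selection = selection, scale = scale)
    pred[test] <- predict(model, x[test, , drop = FALSE])
    fold_oa[f] <- mean(pred[test] == y[test]) * 100
  }
  conf <- confusion_matrix(y, pred, levels = levels_sorted)
  structure(list(confusion = conf,
                 metrics = list(sn = suppressWarnings(sensitivity(conf)),
                                oa = overall_accuracy(conf),
                                aa = average_accuracy(conf)),
                 fold_oa = fold_oa, fold = fa$fold, folds = fa$folds,
                 seed = seed, backend = backend, params = params),
            class = "icp_cv")
}

#' Grid search for the RBF-SVM cost and gamma
#'
#' Exhaustive evaluation of the `cost x gamma` grid by seeded stratified
#' cross-validated overall accuracy; ties are broken by smaller cost, then
#' smaller gamma. Default grids follow the libsvm convention of
#' powers-of-two steps.
#'
#' @inheritParams cross_validate
#' @param cost_grid,gamma_grid Numeric grids (both non-empty).
#' @return List with `cost`, `gamma`, `oa` (the best pair and its CV OA),
#'   and `grid` (a data frame of all evaluated pairs).
#' @export
grid_search_svm <- function(x, y, cost_grid = 2^seq(-5, 15, by = 2),
                            gamma_grid = 2^seq(-15, 3, by = 2),
                            folds = 5L, seed = 1L) {
  if (length(cost_grid) == 0L || length(gamma_grid) == 0L) {
    stop("empty hyperparameter grid", call. = FALSE)
  }
  cost_grid <- sort(cost_grid)
  gamma_grid <- sort(gamma_grid)
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)[, c("cost", "gamma")]
  grid$oa <- NA_real_
  best <- list(oa = -Inf, cost = NA_real_, gamma = NA_real_)
  for (i in seq_len(nrow(grid))) {
    cv <- cross_validate(x, y, folds = folds, seed = seed, backend = "svm-rbf",
                         params = list(cost = grid$cost[i], gamma = grid$gamma[i]))
    grid$oa[i] <- cv$metrics$oa
    if (cv$metrics$oa > best$oa) {  # strict: earlier (smaller) pairs win ties
      best <- list(oa = cv$metrics$oa, cost = grid$cost[i], gamma = grid$gamma[i])
    }
  }
  c(best[c("cost", "gamma", "oa")], list(grid = grid))
}

#' Tabulate a cross-validation run as an evaluation-report row
#'
#' One row per (feature set, backend) combination with per-class Sn, OA,
#' and AA columns, mirroring how hierarchical channel classifiers are
#' conventionally reported.
#'
#' @param cv An `icp_cv`.
#' @param method Label for the row (e.g. `"random-forest (188D)"`).
#' @return A one-row data frame.
#' @export
evaluation_report <- function(cv, method) {
  sn <- cv$metrics$sn
  row <- data.frame(method = method, stringsAsFactors = FALSE)
  for (cls in names(sn)) row[[paste0("Sn.", cls)]] <- unname(sn[cls])
  row$OA <- cv$metrics$oa
  row$AA <- cv$metrics$aa
  row
}
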