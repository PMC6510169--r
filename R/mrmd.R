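## Maximum-relevance-maximum-distance (MRMD) feature ranking: relevance is
## the absolute Pearson correlation of a feature with the integer-encoded
## class label; non-redundancy is the mean distance of a feature to all
## other features under three distance functions (Euclidean, cosine,
## Tanimoto) computed on min-max-scaled columns.

## Min-max scale each column to [0, 1]; constant columns map to 0.
minmax_scale_columns <- function(mat) {
  rng <- apply(mat, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  sweep(sweep(mat, 2L, rng[1L, ], "-"), 2L, span, "/")
}

## Integer-encode labels 0..C-1 in first-seen order.
encode_labels <- function(labels) {
  match(labels, unique(labels)) - 1L
}

#' Per-feature relevance: absolute Pearson correlation with the class
#'
#' Labels are integer-encoded 0..C-1 in first-seen order; a constant
#' feature column (correlation undefined) gets relevance 0.
#'
#' @param mat Instances-by-features numeric matrix.
#' @param labels Class labels, at least two distinct values.
#' @return Named numeric vector in `[0, 1]`, one entry per feature.
#' @export
pearson_relevance <- function(mat, labels) {
  stopifnot(is.matrix(mat), nrow(mat) == length(labels), nrow(mat) >= 2L)
  if (length(unique(labels)) < 2L) {
    stop("relevance undefined: labels contain a single class", call. = FALSE)
  }
  y <- encode_labels(labels)
  r <- suppressWarnings(as.vector(stats::cor(mat, y)))
  r[is.na(r)] <- 0
  out <- abs(r)
  names(out) <- colnames(mat)
  out
}

#' Per-feature distance-based non-redundancy
#'
#' For each feature, the mean pairwise distance to every other feature
#' column under three distance functions, averaged: (a) Euclidean distance
#' on min-max-scaled columns divided by `sqrt(n_instances)`, (b) 1 - cosine
#' similarity, (c) 1 - Tanimoto coefficient. Larger values mean less
#' redundant. With a single feature the value is 0 by convention. Zero-norm
#' (constant-zero after scaling) columns: two zero columns are treated as
#' identical (similarity 1), a zero vs. a non-zero column as maximally
#' dissimilar (similarity 0).
#'
#' @param mat Instances-by-features numeric matrix with at least 2 rows.
#' @return Named numeric vector of non-negative distances.
#' @export
distance_redundancy <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2L)
  p <- ncol(mat)
  if (p == 1L) {
    out <- 0
    names(out) <- colnames(mat)
    return(out)
  }
  s <- minmax_scale_columns(mat)
  n <- nrow(s)
  d_euc <- as.matrix(stats::dist(t(s))) / sqrt(n)
  cp <- crossprod(s)
  sq <- diag(cp)
  norm_prod <- sqrt(outer(sq, sq))
  cos_sim <- ifelse(norm_prod > 0, cp / norm_prod,
                    ifelse(outer(sq, sq, "+") == 0, 1, 0))
  tani_den <- outer(sq, sq, "+") - cp
  tani_sim <- ifelse(tani_den > 0, cp / tani_den,
                     ifelse(outer(sq, sq, "+") == 0, 1, 0))
  md <- (rowSums(d_euc) + rowSums(1 - cos_sim) + rowSums(1 - tani_sim)) /
    (3 * (p - 1L))
  names(md) <- colnames(mat)
  md
}

#' Combine relevance and distance into an MRMD ranking
#'
#' Score = `w_r * MR + w_d * MD`; features are ordered by descending score
#' with ties broken by original column order (stable).
#'
#' @param mr Relevance vector from [pearson_relevance()].
#' @param md Distance vector from [distance_redundancy()].
#' @param weights Non-negative `(w_r, w_d)` pair, default `c(1, 1)`.
#' @return A data frame (`feature`, `mr`, `md`, `score`, `rank`) sorted by
#'   rank, of class `mrmd_ranking`.
#' @export
rank_features <- function(mr, md, weights = c(1, 1)) {
  stopifnot(length(mr) == length(md))
  if (any(weights < 0) || length(weights) != 2L) {
    stop("weights must be two non-negative numbers", call. = FALSE)
  }
  score <- weights[1] * mr + weights[2] * md
  ord <- order(-score, seq_along(score))
  out <- data.frame(
    feature = if (!is.null(names(mr))) names(mr) else as.character(seq_along(mr)),
    mr = as.numeric(mr), md = as.numeric(md), score = as.numeric(score),
    stringsAsFactors = FALSE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("mrmd_ranking", "data.frame")
  out
}

#' Rank all features of a labeled matrix by MRMD
#'
#' @inheritParams pearson_relevance
#' @inheritParams rank_features
#' @return An `mrmd_ranking` data frame.
#' @export
mrmd_rank <- function(mat, labels, weights = c(1, 1)) {
  rank_features(pearson_relevance(mat, labels), distance_redundancy(mat),
                weights = weights)
}

#' Select a top-m MRMD feature subset
#'
#' With an explicit `m`, keeps the `m` highest-ranked features. With
#' `m = "auto"`, nested prefixes of the ranking (sizes on a grid of every
#' 5% of the feature count) are scored by seeded stratified k-fold
#' cross-validated overall accuracy with the configured classifier, and the
#' smallest size within one standard error of the best is kept.
#'
#' @inheritParams pearson_relevance
#' @param m Subset size, or `"auto"`.
#' @param weights MRMD score weights.
#' @param backend,params,folds,seed Classifier settings for the auto rule
#'   (defaults: random forest, 60 trees, 5 folds).
#' @return List with `features` (selected names, rank order), `matrix` (the
#'   reduced matrix), `ranking` (full `mrmd_ranking`), and `m`.
#' @export
mrmd_select <- function(mat, labels, m = "auto", weights = c(1, 1),
                        backend = "random-forest",
                        params = list(ntree = 60L), folds = 5L, seed = 1L) {
  ranking <- mrmd_rank(mat, labels, weights = weights)
  p <- ncol(mat)
  if (identical(m, "auto")) {
    grid <- unique(pmax(1L, round(seq(0.05, 1, by = 0.05) * p)))
    oa <- se <- numeric(length(grid))
    for (i in seq_along(grid)) {
      sub <- mat[, ranking$feature[seq_len(grid[i])], drop = FALSE]
      cv <- cross_validate(sub, labels, folds = folds, seed = seed,
                           backend = backend, params = params)
      oa[i] <- cv$metrics$oa
      se[i] <- stats::sd(cv$fold_oa) / sqrt(length(cv$fold_oa))
    }
    best <- which.max(oa)
    m <- grid[min(which(oa >= oa[best] - se[best]))]
  } else {
    m <- as.integer(m)
    if (is.na(m) || m < 1L || m > p) {
      stop("m must be between 1 and the number of features (", p, ")",
           call. = FALSE)
    }
  }
  feats <- ranking$feature[seq_len(m)]
  list(features = feats, matrix = mat[, feats, drop = FALSE],
       ranking = ranking, m = m)
}

#' Write an MRMD ranking report as TSV
#'
#' @param ranking An `mrmd_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
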