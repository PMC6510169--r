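# Independent brute-force oracles and small data builders shared by the
# suite. The oracles deliberately use naive per-pair loops and share no
# code with the package internals.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_seq <- function(len, freqs = NULL) {
  paste(sample(AA, len, replace = TRUE, prob = freqs), collapse = "")
}

# Brute-force k-skip-gram: enumerate every ordered position pair (i, j),
# keep those whose gap j - i - 1 lies in the configured range, tally.
oracle_kskip <- function(residues, k, include_zero_gap = FALSE) {
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  counts <- setNames(numeric(400), kskip_feature_names())
  lo <- if (include_zero_gap) 0 else 1
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      gap <- j - i - 1
      if (j > i && gap >= lo && gap <= k) {
        nm <- paste0("KSG.", chars[i], chars[j])
        counts[nm] <- counts[nm] + 1
      }
    }
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# Straightforward MRMD: per-column relevance and per-pair distance loops.
oracle_mrmd <- function(mat, labels) {
  y <- match(labels, unique(labels)) - 1
  n <- nrow(mat)
  p <- ncol(mat)
  scaled <- apply(mat, 2, function(col) {
    r <- range(col)
    if (diff(r) == 0) rep(0, n) else (col - r[1]) / diff(r)
  })
  mr <- vapply(seq_len(p), function(j) {
    r <- suppressWarnings(cor(mat[, j], y))
    if (is.na(r)) 0 else abs(r)
  }, numeric(1))
  md <- vapply(seq_len(p), function(f) {
    if (p == 1) return(0)
    euc <- cosd <- tand <- numeric(0)
    for (g in setdiff(seq_len(p), f)) {
      x <- scaled[, f]
      z <- scaled[, g]
      euc <- c(euc, sqrt(sum((x - z)^2)) / sqrt(n))
      nx <- sqrt(sum(x^2)); nz <- sqrt(sum(z^2))
      cs <- if (nx == 0 && nz == 0) 1 else if (nx == 0 || nz == 0) 0 else
        sum(x * z) / (nx * nz)
      cosd <- c(cosd, 1 - cs)
      den <- sum(x^2) + sum(z^2) - sum(x * z)
      ts <- if (den == 0) 1 else sum(x * z) / den
      tand <- c(tand, 1 - ts)
    }
    (mean(euc) + mean(cosd) + mean(tand)) / 3
  }, numeric(1))
  list(mr = mr, md = md, score = mr + md)
}

# Two Gaussian blobs, linearly separable when the centers are far apart.
make_blobs <- function(n_per = 15, gap = 10, sd = 0.5, seed = 1, p = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * p, 0, sd), ncol = p),
             matrix(rnorm(n_per * p, gap, sd), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  rownames(x) <- sprintf("s%03d", seq_len(2 * n_per))
  list(x = x, y = rep(c("a", "b"), each = n_per))
}

# Small synthetic labeled dataset for cascade / CLI tests: six classes at
# reduced counts but the same high-separation profile structure.
small_six_class <- function(seed = 1, n_scale = 0.25) {
  profiles <- lapply(benchmark_profiles("high", length_range = c(50, 150)),
                     function(p) {
    class_profile(p$label, p$freqs, p$length_range,
                  count = max(12L, round(p$count * n_scale)))
  })
  generate_dataset(profiles, seed = seed)
}
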