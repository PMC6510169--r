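## 400-D k-skip-n-gram descriptor (n = 2): frequencies of ordered residue
## pairs taken over all gap sizes a in 1..k (optionally 0..k), normalized
## by the total number of extracted pairs.

#' k-skip-gram configuration
#'
#' @param k Maximum skip distance (gap size), a positive integer. The
#'   largest gap between the two residues of a pair. No canonical value
#'   exists; `k` is a required, logged experiment parameter (default 2).
#' @param n Gram length; only `n = 2` (20^2 = 400 ordered pairs) is
#'   supported.
#' @param include_zero_gap Whether gap `a = 0` (contiguous dipeptides)
#'   enters the union of extracted pairs. Off by default: the descriptor's
#'   defining union runs over gaps 1..k.
#' @return A `skipgram_config` list.
#' @export
skipgram_config <- function(k = 2L, n = 2L, include_zero_gap = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (n != 2L) {
    stop("only n = 2 (400 ordered-pair features) is supported", call. = FALSE)
  }
  structure(list(k = k, n = 2L, include_zero_gap = isTRUE(include_zero_gap)),
            class = "skipgram_config")
}

#' Ordered residue pairs at a fixed gap size
#'
#' All pairs (position i, position i + a + 1) with both positions inside
#' the sequence; the number of intervening residues between the paired
#' positions equals `a`.
#'
#' @param residues Sequence string.
#' @param a Gap size, a non-negative integer (`a = 0` gives contiguous
#'   dipeptides).
#' @return Character vector of two-letter pairs in position order (empty
#'   when the sequence is too short to host any pair at this gap).
#' @export
#' @examples
#' skip_pairs("ACA", 1)
#' skip_pairs("ACDE", 0)
skip_pairs <- function(residues, a) {
  a <- as.integer(a)
  stopifnot(a >= 0L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L <= a + 1L) return(character(0))
  i <- seq_len(L - a - 1L)
  paste0(chars[i], chars[i + a + 1L])
}

#' Names of the 400 ordered-pair features
#'
#' @param prefix Prefix prepended to each pair name (default `"KSG."`).
#' @return Character vector of length 400, row-major alphabetical order
#'   (`AA, AC, ..., AY, CA, ..., YY`).
#' @export
kskip_feature_names <- function(prefix = "KSG.") {
  paste0(prefix, rep(AA20, each = 20L), rep(AA20, 20L))
}

#' Extract the 400-D k-skip-n-gram descriptor
#'
#' Pools the ordered residue pairs from [skip_pairs()] over all gap sizes
#' in the configured range and reports each of the 400 possible ordered
#' pairs as a fraction of the pooled pair count. When the sequence is too
#' short to produce any pair, the vector is all zeros.
#'
#' @param residues Sequence string; must pass [validate_sequence()] (with
#'   `min_length` relaxed to 1: short sequences yield the all-zero vector).
#' @param config A [skipgram_config()].
#' @return Named numeric vector of length 400 summing to 1 (or all zeros).
#' @export
#' @examples
#' v <- extract_kskip("AAAA", skipgram_config(k = 2))
#' v[["KSG.AA"]]
extract_kskip <- function(residues, config = skipgram_config()) {
  stopifnot(inherits(config, "skipgram_config"))
  codes <- residue_codes(residues)
  if (anyNA(codes) || length(codes) < 1L) {
    stop("invalid sequence: contains non-standard residues or is empty",
         call. = FALSE)
  }
  L <- length(codes)
  gaps <- seq.int(if (config$include_zero_gap) 0L else 1L, config$k)
  counts <- numeric(400L)
  for (a in gaps) {
    if (L <= a + 1L) next
    i <- seq_len(L - a - 1L)
    idx <- (codes[i] - 1L) * 20L + codes[i + a + 1L]
    counts <- counts + tabulate(idx, nbins = 400L)
  }
  total <- sum(counts)
  out <- if (total > 0) counts / total else counts
  names(out) <- kskip_feature_names()
  out
}
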