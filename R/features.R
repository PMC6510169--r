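#' Encode a set of sequences as a feature matrix
#'
#' Applies one of the package's encoders to every sequence and stacks the
#' descriptors into an instances-by-features matrix. The fused encoder
#' concatenates the 188-D physicochemical descriptor with the 400-D
#' k-skip-n-gram descriptor (588 columns, 188-D block first).
#'
#' @param seqs Data frame with columns `id` and `residues` (e.g. an
#'   `icp_dataset` or [read_fasta()] output).
#' @param encoder One of `"ctd188"`, `"kskip"`, `"fused"`.
#' @param config A [skipgram_config()] for the k-skip encoder (ignored by
#'   `"ctd188"`).
#' @param min_length Minimum sequence length (validation rule).
#' @return Numeric matrix with `rownames = id` and feature-name columns.
#' @export
encode_sequences <- function(seqs, encoder = c("ctd188", "kskip", "fused"),
                             config = skipgram_config(), min_length = 10L) {
  encoder <- match.arg(encoder)
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  enc <- switch(encoder,
    ctd188 = function(s) extract_188(s, min_length = min_length),
    kskip  = function(s) extract_kskip(s, config = config),
    fused  = function(s) c(extract_188(s, min_length = min_length),
                           extract_kskip(s, config = config)))
  rows <- lapply(seqs$residues, enc)
  mat <- do.call(rbind, rows)
  rownames(mat) <- seqs$id
  mat
}

#' Write a feature matrix as tab-separated text
#'
#' Header row of feature names preceded by an `id` column; one row per
#' sequence. The same dialect is read back by [read_feature_matrix()] and
#' consumed by the MRMD and classification stages.
#'
#' @param mat Numeric matrix with rownames (ids) and colnames (features).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return Numeric matrix with rownames from the `id` column.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(df)[1] == "id")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (anyNA(mat)) stop("feature matrix contains missing values", call. = FALSE)
  rownames(mat) <- df$id
  mat
}
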