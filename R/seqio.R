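#' Read protein sequences from a FASTA file
#'
#' A permissive reader: records are returned in file order, sequences are
#' upper-cased, and the id is the header token before the first whitespace.
#' Duplicate ids and non-standard residues are *not* rejected here — the
#' strict checks live in [validate_sequence()] and [labeled_dataset()] so
#' that malformed records can be reported rather than silently lost.
#'
#' @param path Path to a FASTA file. Multi-line sequences are allowed.
#' @return A data frame with character columns `id` and `residues`, one row
#'   per record (zero rows for an empty file).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 some description", "ACDE", ">p2", "GGG", "HH"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  ids <- character(0)
  chunks <- list()
  current <- NULL
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      header <- trimws(sub("^>", "", line))
      ids <- c(ids, strsplit(header, "[[:space:]]+")[[1]][1])
      current <- length(ids)
      chunks[[current]] <- character(0)
    } else {
      if (is.null(current)) {
        stop("malformed FASTA: sequence line before any header at line ", i,
             " of '", path, "'", call. = FALSE)
      }
      chunks[[current]] <- c(chunks[[current]], gsub("[[:space:]]", "", line))
    }
  }
  residues <- toupper(vapply(chunks, paste, "", collapse = ""))
  if (length(ids) == 0L) {
    return(data.frame(id = character(0), residues = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(id = ids, residues = residues, stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Data frame with columns `id` and `residues` (as returned by
#'   [read_fasta()]), or an `icp_dataset`.
#' @param path Output file path.
#' @param width Line-wrap width for sequences (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs$residues[i]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Validate a candidate protein sequence
#'
#' Sequences containing ambiguity or non-standard codes (X, B, Z, and also
#' J, O, U — anything outside the 20-letter standard alphabet) are rejected,
#' as are empty sequences and sequences shorter than `min_length`. Short
#' sequences are excluded because the distribution descriptors (positions of
#' the 25/50/75% group occurrences) are degenerate on them.
#'
#' @param residues Candidate sequence string (single string).
#' @param min_length Minimum accepted length (default 10).
#' @return A list with logical `accept` and, when rejected, a `reason`
#'   string; never throws on bad sequence content.
#' @export
#' @examples
#' validate_sequence("ACDEFGHIKLMNPQRSTVWY")
#' validate_sequence("ACXDE")$reason
validate_sequence <- function(residues, min_length = 10L) {
  stopifnot(is.character(residues), length(residues) == 1L)
  if (is.na(residues) || !nzchar(residues)) {
    return(list(accept = FALSE, reason = "empty sequence"))
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad) > 0L) {
    return(list(accept = FALSE,
                reason = paste0("ambiguous residue ",
                                paste(sort(bad), collapse = ","))))
  }
  if (nchar(residues) < min_length) {
    return(list(accept = FALSE,
                reason = paste0("sequence shorter than ", min_length)))
  }
  list(accept = TRUE, reason = NA_character_)
}

#' Construct a labeled sequence dataset
#'
#' The strict constructor behind [load_labeled_dataset()]: enforces unique
#' ids and membership of every label in the declared scheme. It does *not*
#' validate residues — pass sequences through [validate_sequence()] first
#' (as `load_labeled_dataset()` does).
#'
#' @param ids,residues,labels Parallel character vectors.
#' @param scheme Character vector of allowed labels, or the name of a
#'   built-in scheme from [label_schemes()].
#' @return An `icp_dataset`: a data frame `(id, residues, label)` with a
#'   `scheme` attribute.
#' @export
labeled_dataset <- function(ids, residues, labels, scheme = "six-class") {
  if (is.character(scheme) && length(scheme) == 1L &&
      scheme %in% names(label_schemes())) {
    scheme <- label_schemes()[[scheme]]
  }
  stopifnot(length(ids) == length(residues), length(ids) == length(labels))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence ids in dataset: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(labels), scheme)
  if (length(unknown) > 0L) {
    stop("labels outside the declared scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = as.character(ids), residues = as.character(residues),
                    label = as.character(labels), stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme
  class(out) <- c("icp_dataset", "data.frame")
  out
}

#' Read a two-column tab-separated label map
#'
#' @param path TSV file with header `id<TAB>label`.
#' @return Data frame with columns `id` and `label`.
#' @export
read_label_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(map))) {
    stop("label map must have columns 'id' and 'label'", call. = FALSE)
  }
  map[, c("id", "label")]
}

#' Load a labeled dataset from FASTA input
#'
#' Labels come either from per-class FASTA files (a named vector of paths,
#' names = class labels) or from one FASTA plus a TSV label map. Sequences
#' failing [validate_sequence()] are dropped; kept/dropped counts per class
#' are reported via `message()`.
#'
#' @param fasta Either a named character vector of per-class FASTA paths, or
#'   a single unnamed FASTA path (then `label_map` is required).
#' @param label_map Optional path to a TSV with columns `id` and `label`.
#' @param scheme Allowed labels (vector or built-in scheme name).
#' @param min_length Passed to [validate_sequence()].
#' @return An `icp_dataset` containing only validated sequences.
#' @export
load_labeled_dataset <- function(fasta, label_map = NULL,
                                 scheme = "six-class", min_length = 10L) {
  scheme_vec <- if (is.character(scheme) && length(scheme) == 1L &&
                    scheme %in% names(label_schemes())) {
    label_schemes()[[scheme]]
  } else scheme
  if (!is.null(names(fasta)) && all(nzchar(names(fasta)))) {
    unknown <- setdiff(names(fasta), scheme_vec)
    if (length(unknown) > 0L) {
      stop("per-class FASTA label(s) not in scheme: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    parts <- lapply(names(fasta), function(lbl) {
      recs <- read_fasta(fasta[[lbl]])
      recs$label <- rep(lbl, nrow(recs))
      recs
    })
    recs <- do.call(rbind, parts)
  } else {
    stopifnot(length(fasta) == 1L, !is.null(label_map))
    recs <- read_fasta(fasta)
    map <- if (is.data.frame(label_map)) label_map else read_label_map(label_map)
    unknown <- setdiff(unique(map$label), scheme_vec)
    if (length(unknown) > 0L) {
      stop("label map contains label(s) not in scheme: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(recs$id, map$id)
    if (length(missing) > 0L) {
      stop("no label for sequence id(s): ",
           paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    }
    recs$label <- map$label[match(recs$id, map$id)]
  }
  verdicts <- lapply(recs$residues, validate_sequence, min_length = min_length)
  keep <- vapply(verdicts, `[[`, logical(1), "accept")
  for (lbl in unique(recs$label)) {
    in_class <- recs$label == lbl
    message(sprintf("class %s: kept %d, dropped %d",
                    lbl, sum(keep & in_class), sum(!keep & in_class)))
  }
  labeled_dataset(recs$id[keep], recs$residues[keep], recs$label[keep],
                  scheme = scheme_vec)
}
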