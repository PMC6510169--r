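## 188-D physicochemical descriptor: 20 amino-acid composition percentages
## followed, for each of 8 properties, by a 21-value CTD block
## (3 composition + 3 transition + 15 distribution).

.ctd_env <- new.env(parent = emptyenv())

#' Physicochemical three-group residue partitions
#'
#' The eight property groupings behind the CTD blocks of the 188-D
#' descriptor: hydrophobicity, normalized van der Waals volume, polarity,
#' polarizability, charge, surface tension, secondary-structure propensity,
#' and solvent accessibility. Each property partitions the 20 standard
#' residues into three ordered groups (the classical three-group
#' assignments of the CTD descriptor literature). The table is shipped as a
#' plain-text file (`extdata/ctd_property_groups.tsv`) so it is inspectable
#' and editable.
#'
#' @param path Optional path to an alternative grouping table with columns
#'   `property`, `group1`, `group2`, `group3` (residue strings).
#' @return A data frame with one row per property; each row's three groups
#'   are disjoint and jointly cover the 20-letter alphabet (checked).
#' @export
#' @examples
#' ctd_property_groups()$property
ctd_property_groups <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ctd_env$groups)) return(.ctd_env$groups)
    path <- system.file("extdata", "ctd_property_groups.tsv",
                        package = "icpred", mustWork = TRUE)
    cache <- TRUE
  } else cache <- FALSE
  g <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("property", "group1", "group2", "group3") %in% names(g)))
  for (i in seq_len(nrow(g))) {
    members <- sort(unname(unlist(
      strsplit(unlist(g[i, c("group1", "group2", "group3")]), "", fixed = TRUE))))
    if (!identical(members, sort(AA20))) {
      stop("grouping for property '", g$property[i],
           "' is not a partition of the 20 standard residues", call. = FALSE)
    }
  }
  if (cache) .ctd_env$groups <- g
  g
}

## 8 x 20 matrix of group indices (1..3): row = property, column = residue
## code. Cached; all group-based descriptors are lookups into this.
ctd_group_lookup <- function() {
  if (!is.null(.ctd_env$lookup)) return(.ctd_env$lookup)
  g <- ctd_property_groups()
  lookup <- matrix(NA_integer_, nrow = nrow(g), ncol = 20L,
                   dimnames = list(g$property, AA20))
  for (i in seq_len(nrow(g))) {
    for (k in 1:3) {
      members <- strsplit(g[i, paste0("group", k)], "", fixed = TRUE)[[1]]
      lookup[i, members] <- k
    }
  }
  .ctd_env$lookup <- lookup
  lookup
}

#' Amino-acid composition (20 percentages)
#'
#' Frequency of each standard residue as a percentage of sequence length,
#' in fixed alphabetical order `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param residues Sequence string over the standard alphabet.
#' @return Named numeric vector of length 20 summing to 100.
#' @export
#' @examples
#' aa_composition("ACDE")
aa_composition <- function(residues) {
  codes <- residue_codes(residues)
  stopifnot(!anyNA(codes), length(codes) >= 1L)
  out <- tabulate(codes, nbins = 20L) / length(codes) * 100
  names(out) <- AA20
  out
}

#' Per-property group composition (3 percentages)
#'
#' Percentage of residues falling in each of the property's three groups.
#'
#' @param residues Sequence string.
#' @param property Property name (a row of [ctd_property_groups()]).
#' @return Numeric vector of length 3 summing to 100.
#' @export
group_composition <- function(residues, property) {
  gcodes <- ctd_group_codes(residues, property)
  tabulate(gcodes, nbins = 3L) / length(gcodes) * 100
}

#' Per-property group transitions (3 percentages)
#'
#' For each unordered group pair (1,2), (1,3), (2,3): the number of adjacent
#' positions whose residues fall in the two groups (either order), divided
#' by L - 1, times 100. A length-1 sequence has no adjacent pairs and
#' returns zeros.
#'
#' @inheritParams group_composition
#' @return Numeric vector of length 3 (order: pairs 1-2, 1-3, 2-3).
#' @export
group_transition <- function(residues, property) {
  gcodes <- ctd_group_codes(residues, property)
  L <- length(gcodes)
  if (L < 2L) return(c(0, 0, 0))
  a <- gcodes[-L]
  b <- gcodes[-1L]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  c(sum(lo == 1L & hi == 2L),
    sum(lo == 1L & hi == 3L),
    sum(lo == 2L & hi == 3L)) / (L - 1L) * 100
}

#' Per-property group distribution (15 percentages)
#'
#' For each group: the 1-based positions of the first occurrence and of the
#' `ceil(0.25 m)`-th, `ceil(0.50 m)`-th, `ceil(0.75 m)`-th, and `m`-th
#' occurrences of that group's residues (`m` = total occurrences), each
#' scaled by sequence length and expressed as a percentage. A group with no
#' occurrences contributes five zeros.
#'
#' @inheritParams group_composition
#' @return Numeric vector of length 15 (5 values for group 1, then 2, then 3).
#' @export
group_distribution <- function(residues, property) {
  gcodes <- ctd_group_codes(residues, property)
  L <- length(gcodes)
  out <- numeric(15L)
  for (k in 1:3) {
    pos <- which(gcodes == k)
    m <- length(pos)
    if (m == 0L) next
    idx <- c(1L, ceiling(c(0.25, 0.50, 0.75) * m), m)
    out[(k - 1L) * 5L + 1:5] <- pos[idx] / L * 100
  }
  out
}

ctd_group_codes <- function(residues, property) {
  lookup <- ctd_group_lookup()
  if (!property %in% rownames(lookup)) {
    stop("unknown property '", property, "'; see ctd_property_groups()",
         call. = FALSE)
  }
  codes <- residue_codes(residues)
  stopifnot(!anyNA(codes), length(codes) >= 1L)
  lookup[property, ][codes]
}

#' Names of the 188 descriptor features, in canonical order
#'
#' @return Character vector of length 188: `AAC.<residue>` for the 20
#'   composition features, then per property `<prop>.C1..C3`,
#'   `<prop>.T12/T13/T23`, and `<prop>.D<g>.<first|q25|q50|q75|last>`.
#' @export
ctd188_feature_names <- function() {
  if (!is.null(.ctd_env$feature_names)) return(.ctd_env$feature_names)
  props <- ctd_property_groups()$property
  nm <- paste0("AAC.", AA20)
  for (p in props) {
    nm <- c(nm,
            paste0(p, ".C", 1:3),
            paste0(p, ".T", c("12", "13", "23")),
            paste0(p, ".D", rep(1:3, each = 5L), ".",
                   rep(c("first", "q25", "q50", "q75", "last"), 3L)))
  }
  .ctd_env$feature_names <- nm
  nm
}

#' Extract the 188-D physicochemical descriptor
#'
#' Concatenates the 20 amino-acid composition percentages with, for each of
#' the eight properties in table order, a 21-value CTD block: 3 group
#' compositions, 3 group transitions, and 15 distribution values
#' (20 + 8 x 21 = 188).
#'
#' @param residues Sequence string; must pass [validate_sequence()].
#' @param min_length Minimum sequence length accepted (default 10).
#' @return Named numeric vector of length 188.
#' @export
#' @examples
#' v <- extract_188(strrep("ACDEFGHIKL", 4))
#' length(v)
extract_188 <- function(residues, min_length = 10L) {
  verdict <- validate_sequence(residues, min_length = min_length)
  if (!verdict$accept) {
    stop("invalid sequence: ", verdict$reason, call. = FALSE)
  }
  codes <- residue_codes(residues)
  L <- length(codes)
  lookup <- ctd_group_lookup()
  props <- rownames(lookup)
  out <- numeric(188L)
  out[1:20] <- tabulate(codes, nbins = 20L) / L * 100
  offset <- 20L
  for (p in props) {
    gcodes <- lookup[p, ][codes]
    out[offset + 1:3] <- tabulate(gcodes, nbins = 3L) / L * 100
    a <- gcodes[-L]; b <- gcodes[-1L]
    lo <- pmin(a, b); hi <- pmax(a, b)
    out[offset + 4:6] <- c(sum(lo == 1L & hi == 2L),
                           sum(lo == 1L & hi == 3L),
                           sum(lo == 2L & hi == 3L)) / (L - 1L) * 100
    for (k in 1:3) {
      pos <- which(gcodes == k)
      m <- length(pos)
      if (m > 0L) {
        idx <- c(1L, ceiling(c(0.25, 0.50, 0.75) * m), m)
        out[offset + 6L + (k - 1L) * 5L + 1:5] <- pos[idx] / L * 100
      }
    }
    offset <- offset + 21L
  }
  names(out) <- ctd188_feature_names()
  out
}
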