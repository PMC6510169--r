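## Three-stage cascade: (1) ion vs. non-ion, (2) voltage- vs. ligand-gated,
## (3) voltage-gated subtype (K / Ca / Na / anion). Each stage carries its
## own feature configuration (encoder, optional MRMD selection, backend).

#' Per-stage feature/backend configuration for the cascade
#'
#' @param encoder `"ctd188"`, `"kskip"`, or `"fused"`.
#' @param k,include_zero_gap k-skip-gram settings (used by the `kskip` and
#'   `fused` encoders).
#' @param backend,params Estimator and its hyperparameters (see
#'   [train_stage()]).
#' @param selection Optional MRMD selection, e.g. `list(m = 100)` or
#'   `list(m = "auto")`.
#' @return A plain configuration list consumed by [train_cascade()].
#' @export
stage_encoder_config <- function(encoder = "ctd188", k = 2L,
                                 include_zero_gap = FALSE,
                                 backend = "random-forest",
                                 params = list(), selection = NULL) {
  list(encoder = encoder, k = k, include_zero_gap = include_zero_gap,
       backend = backend, params = params, selection = selection)
}

cascade_stage_labels <- function(labels) {
  list(stage1 = ifelse(labels == "non-ion", "non-ion", "ion"),
       stage2 = ifelse(labels == "ligand-gated", "ligand-gated", "voltage-gated"),
       stage3 = labels)
}

encode_for_config <- function(seqs, cfg, cache = NULL) {
  key <- paste(cfg$encoder, cfg$k, cfg$include_zero_gap, sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  mat <- encode_sequences(seqs, encoder = cfg$encoder,
                          config = skipgram_config(k = cfg$k,
                                                   include_zero_gap = cfg$include_zero_gap))
  if (!is.null(cache)) cache[[key]] <- mat
  mat
}

#' Train the three-stage cascade
#'
#' Stage 1 is trained on all sequences (ion vs. non-ion), stage 2 on the
#' ion channels only (voltage- vs. ligand-gated), stage 3 on the
#' voltage-gated channels only (K / Ca / Na / anion). Each stage may use a
#' different feature configuration.
#'
#' @param dataset An `icp_dataset` with six-class labels.
#' @param stage1,stage2,stage3 Per-stage configurations from
#'   [stage_encoder_config()] (encoder, backend, hyperparameters, optional
#'   MRMD selection).
#' @return An `icp_cascade` holding the three fitted `icp_stage` models and
#'   their configurations.
#' @export
train_cascade <- function(dataset,
                          stage1 = stage_encoder_config(),
                          stage2 = stage_encoder_config(),
                          stage3 = stage_encoder_config()) {
  stopifnot(inherits(dataset, "icp_dataset"))
  six <- label_schemes()[["six-class"]]
  if (!all(dataset$label %in% six)) {
    stop("cascade training needs six-class labels", call. = FALSE)
  }
  ys <- cascade_stage_labels(dataset$label)
  cache <- new.env(parent = emptyenv())
  configs <- list(stage1 = stage1, stage2 = stage2, stage3 = stage3)
  ion <- ys$stage1 == "ion"
  voltage <- ion & ys$stage2 == "voltage-gated"
  subsets <- list(stage1 = rep(TRUE, nrow(dataset)), stage2 = ion,
                  stage3 = voltage)
  stage_levels <- list(stage1 = label_schemes()$ion,
                       stage2 = label_schemes()$gating,
                       stage3 = label_schemes()$subtype)
  models <- lapply(names(configs), function(s) {
    cfg <- configs[[s]]
    mat <- encode_for_config(dataset, cfg, cache)[subsets[[s]], , drop = FALSE]
    y <- factor(ys[[s]][subsets[[s]]], levels = stage_levels[[s]])
    train_stage(mat, y, backend = cfg$backend, params = cfg$params,
                selection = cfg$selection)
  })
  names(models) <- names(configs)
  structure(list(stages = models, configs = configs,
                 version = as.character(utils::packageVersion("icpred"))),
            class = "icp_cascade")
}

#' Predict with the cascade
#'
#' Applies the three-step decision procedure to each sequence: stage 1
#' decides ion vs. non-ion (non-ion terminates); stage 2 decides voltage-
#' vs. ligand-gated (ligand-gated terminates); stage 3 assigns the
#' voltage-gated subtype. The per-stage decision trail is returned along
#' with the final label.
#'
#' @param cascade An `icp_cascade`.
#' @param seqs Data frame with columns `id` and `residues`.
#' @return Data frame with columns `id`, `stage1`, `stage2`, `stage3`
#'   (`NA` for stages not reached), and `final` (one of the six labels).
#' @export
predict_cascade <- function(cascade, seqs) {
  stopifnot(inherits(cascade, "icp_cascade"),
            all(c("id", "residues") %in% names(seqs)))
  n <- nrow(seqs)
  out <- data.frame(id = seqs$id,
                    stage1 = NA_character_, stage2 = NA_character_,
                    stage3 = NA_character_, final = NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  cache <- new.env(parent = emptyenv())
  m1 <- encode_for_config(seqs, cascade$configs$stage1, cache)
  out$stage1 <- predict(cascade$stages$stage1, m1)
  out$final[out$stage1 == "non-ion"] <- "non-ion"
  go2 <- out$stage1 == "ion"
  if (any(go2)) {
    m2 <- encode_for_config(seqs, cascade$configs$stage2, cache)
    out$stage2[go2] <- predict(cascade$stages$stage2, m2[go2, , drop = FALSE])
    out$final[go2 & out$stage2 == "ligand-gated"] <- "ligand-gated"
    go3 <- go2 & !is.na(out$stage2) & out$stage2 == "voltage-gated"
    if (any(go3)) {
      m3 <- encode_for_config(seqs, cascade$configs$stage3, cache)
      out$stage3[go3] <- predict(cascade$stages$stage3, m3[go3, , drop = FALSE])
      out$final[go3] <- out$stage3[go3]
    }
  }
  out
}

#' Save / load a trained cascade bundle
#'
#' The bundle is a single serialized archive holding the three fitted
#' stage models, their preprocessing state and feature configurations, and
#' the package version. Loading refuses a bundle written by a different
#' major version.
#'
#' @param cascade An `icp_cascade`.
#' @param path Bundle path (`.rds`).
#' @return `path` invisibly (save); the `icp_cascade` (load).
#' @export
save_cascade <- function(cascade, path) {
  stopifnot(inherits(cascade, "icp_cascade"))
  saveRDS(cascade, path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  cascade <- readRDS(path)
  if (!inherits(cascade, "icp_cascade")) {
    stop("not a cascade model bundle: ", path, call. = FALSE)
  }
  major <- function(v) strsplit(v, ".", fixed = TRUE)[[1]][1]
  here <- as.character(utils::packageVersion("icpred"))
  if (!identical(major(cascade$version), major(here))) {
    stop("model bundle was written by icpred ", cascade$version,
         "; this is ", here, " (incompatible major version)", call. = FALSE)
  }
  cascade
}
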