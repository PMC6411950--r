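## Model bundles on disk: a directory holding JSON metadata plus the weights.
## Deep models and ensembles are fully text-serialised (JSON at full double
## precision); forests keep their fitted ranger state in an RDS file alongside
## the JSON metadata.

.bundle_version <- 1L

params_to_json <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), values = as.vector(p))
    else list(dim = length(p), values = as.vector(p))
  })
}

params_from_json <- function(pj) {
  lapply(pj, function(p) {
    v <- as.numeric(p$values)
    if (length(p$dim) == 2L) matrix(v, p$dim[1], p$dim[2]) else v
  })
}

#' Save a trained model as a bundle directory
#'
#' Writes `metadata.json` (model kind, architecture, alphabet order, seeds,
#' bundle version, optional decision threshold) plus the weights:
#' `weights.json` for deep models and ensembles (full-precision text),
#' `forest.rds` for random forests.
#'
#' @param model A `lemp_deep_model`, `lemp_forest_model` or `lemp_ensemble`.
#' @param dir Bundle directory (created if missing).
#' @param threshold Optional decision threshold stored with the model.
#' @return The bundle directory, invisibly.
#' @export
save_model <- function(model, dir, threshold = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta_path <- file.path(dir, "metadata.json")
  if (inherits(model, "lemp_deep_model")) {
    meta <- list(kind = "deep", version = .bundle_version, arch = model$arch,
                 input_mode = model$input_mode, spec = unclass(model$spec),
                 n_filters = model$n_filters,
                 kernel_size = model$kernel_size,
                 n_conv_layers = model$n_conv_layers,
                 trained = model$trained, history = model$history,
                 metadata = model$metadata, threshold = threshold)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    jsonlite::write_json(params_to_json(model$params),
                         file.path(dir, "weights.json"), digits = NA)
  } else if (inherits(model, "lemp_forest_model")) {
    meta <- list(kind = "forest", version = .bundle_version,
                 feature_names = model$feature_names,
                 score_type = model$score_type, metadata = model$metadata,
                 threshold = threshold)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    saveRDS(model$fit, file.path(dir, "forest.rds"))
  } else if (inherits(model, "lemp_ensemble")) {
    meta <- list(kind = "ensemble", version = .bundle_version,
                 w1 = model$w1, w2 = model$w2, b = model$b,
                 components = model$components, threshold = threshold)
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  } else stop("unknown model type: ", paste(class(model), collapse = "/"))
  invisible(dir)
}

#' Load a model bundle written by [save_model()]
#'
#' @param dir Bundle directory.
#' @return The model object; any stored threshold is attached as attribute
#'   `"threshold"`.
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  model <- switch(meta$kind,
    deep = {
      spec <- do.call(deep_model_spec, meta$spec[c("vocab_size", "embed_dim",
                                                   "lstm_units", "dense_units",
                                                   "dropout_rate",
                                                   "input_length")])
      m <- list(arch = meta$arch, input_mode = meta$input_mode, spec = spec,
                params = params_from_json(
                  jsonlite::read_json(file.path(dir, "weights.json"),
                                      simplifyVector = TRUE)),
                trained = isTRUE(meta$trained),
                history = as.numeric(meta$history),
                metadata = meta$metadata)
      if (meta$arch == "cnn") {
        m$n_filters <- meta$n_filters
        m$kernel_size <- meta$kernel_size
        m$n_conv_layers <- meta$n_conv_layers
      }
      structure(m, class = "lemp_deep_model")
    },
    forest = structure(list(fit = readRDS(file.path(dir, "forest.rds")),
                            feature_names = meta$feature_names,
                            score_type = meta$score_type,
                            metadata = meta$metadata),
                       class = "lemp_forest_model"),
    ensemble = structure(list(w1 = meta$w1, w2 = meta$w2, b = meta$b,
                              fit = NULL, components = meta$components),
                         class = "lemp_ensemble"),
    stop("unknown bundle kind: ", meta$kind))
  attr(model, "threshold") <- meta$threshold
  model
}

#' Write run metadata (config echo, seed, versions) next to an output
#'
#' Every pipeline output is accompanied by a metadata record sufficient to
#' reproduce it.
#'
#' @param path Output JSON path.
#' @param seed Seed used for the run.
#' @param params Named list of run parameters.
#' @return The path, invisibly.
#' @export
write_run_metadata <- function(path, seed, params = list()) {
  meta <- list(seed = seed, params = params,
               package = "lemp",
               package_version = as.character(utils::packageVersion("lemp")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a prediction table
#'
#' Columns: `protein_id`, `position`, `window`, `score_lstm`, `score_rf`,
#' `score_lemp`, `predicted_label_at_threshold` (empty strings for scores a
#' model was not supplied for).
#'
#' @param predictions Data.frame with the columns above.
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
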