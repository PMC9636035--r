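#' Save a model checkpoint
#'
#' Serialized weights in one file plus a JSON sidecar carrying the
#' backbone spec, class names, lambda and the training configuration.
#'
#' @param model an `advcs_model`.
#' @param path checkpoint file path (`.rds`); the sidecar is written next
#'   to it as `<path>.json`.
#' @return `path`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "advcs_model"))
  saveRDS(model, path)
  sidecar <- list(architecture = model$spec$architecture,
                  input_px = model$spec$input_px,
                  n_filters = model$spec$n_filters,
                  representation_dim = model$spec$representation_dim,
                  task_levels = model$task_levels,
                  n_confounder_classes = model$n_confounder_classes,
                  lambda = model$lambda,
                  trained = isTRUE(model$trained))
  if (!is.null(model$config)) {
    cfg <- unclass(model$config)
    sidecar$training_config <- cfg
    key <- paste(names(cfg),
                 vapply(cfg, function(v) paste(format(v, digits = 15),
                                               collapse = ","), character(1)),
                 sep = "=", collapse = "|")
    ints <- utf8ToInt(key)
    sidecar$config_hash <- sprintf("%08x",
                                   sum(ints * seq_along(ints)) %% 2^31)
  }
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  path
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file path.
#' @return an `advcs_model`.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "advcs_model"))
    stop("file does not contain an advcs_model checkpoint", call. = FALSE)
  model
}
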