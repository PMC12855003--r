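# Single-file JSON checkpoints: config plus every layer's arrays (including
# batch-norm running statistics), loadable without the original dataset.

serialize_layers <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
      dense = list(type = "dense", dims = dim(l$W), W = as.numeric(l$W), b = l$b),
      bn = list(type = "bn", gamma = l$gamma, beta = l$beta, rmean = l$rmean,
                rvar = l$rvar, momentum = l$momentum, eps = l$eps),
      l)
  })
}

deserialize_layers <- function(raw) {
  lapply(raw, function(l) {
    l$type <- as.character(l$type)
    if (l$type == "dense") {
      W <- matrix(as.numeric(l$W), l$dims[1], l$dims[2])
      list(type = "dense", W = W, b = as.numeric(l$b))
    } else if (l$type == "bn") {
      list(type = "bn", gamma = as.numeric(l$gamma), beta = as.numeric(l$beta),
           rmean = as.numeric(l$rmean), rvar = as.numeric(l$rvar),
           momentum = l$momentum, eps = l$eps)
    } else if (l$type == "alpha_dropout") {
      list(type = "alpha_dropout", p = l$p)
    } else list(type = l$type)
  })
}

#' Save / load a model checkpoint
#'
#' @param model A `scouter_model`.
#' @param path Checkpoint file path (JSON).
#' @return `path` (save) or the restored `scouter_model` (load).
#' @export
save_scouter <- function(model, path) {
  payload <- list(config = unclass(model$config),
                  compressor = serialize_layers(model$compressor),
                  generator = serialize_layers(model$generator),
                  trained = model$trained,
                  best_epoch = model$best_epoch,
                  history = model$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_scouter
#' @export
load_scouter <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cfgraw <- raw$config
  cfgraw$activation <- NULL; cfgraw$layer_norm <- NULL
  cfgraw <- lapply(cfgraw, unlist)
  config <- do.call(scouter_config, cfgraw)
  hist <- if (!is.null(raw$history)) as.data.frame(lapply(raw$history, unlist)) else NULL
  structure(list(config = config,
                 compressor = deserialize_layers(lapply(raw$compressor, lapply, unlist)),
                 generator = deserialize_layers(lapply(raw$generator, lapply, unlist)),
                 trained = isTRUE(raw$trained),
                 history = hist,
                 best_epoch = raw$best_epoch %||% NA_integer_),
            class = "scouter_model")
}
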