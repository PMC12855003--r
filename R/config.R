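#' Model and training configuration
#'
#' Collects every architecture and optimization hyperparameter. Defaults are
#' the published configuration: compressor hidden layers 2048 and 512 with a
#' 64-unit bottleneck, a 2048-unit generator hidden layer, SELU activations,
#' batch normalization after each hidden layer, dropout disabled; Adam with
#' exponential learning-rate decay 0.9 per epoch, batch size 256, at most 40
#' epochs, early stopping with patience 5 and minimal improvement 0.001,
#' gradient norm clipped at 1.0, and K = 300 control cells per prediction.
#'
#' Two distinct exponents both written gamma in the source material are
#' disambiguated here: `gamma_loss` is the autofocus exponent (error is
#' penalized as |x - xhat|^(2+gamma_loss)) and `lr_decay` is the per-epoch
#' learning-rate decay factor.
#'
#' @param n_genes Number of genes (input and output width).
#' @param embedding_dim Length of the gene embedding vectors.
#' @param compressor_hidden Integer vector of compressor hidden widths.
#' @param bottleneck Width of the compressed cell state.
#' @param generator_hidden Integer vector of generator hidden widths.
#' @param batch_norm Apply batch normalization after each hidden layer.
#' @param dropout Alpha-dropout rate in `[0, 1)`; 0 disables (default).
#' @param gamma_loss Autofocus exponent, >= 0.
#' @param lambda_dir Weight of the direction-aware loss term, >= 0.
#' @param dir_smooth_alpha If > 0, use a smooth tanh(alpha * delta) surrogate
#'   for the sign of the predicted change when computing gradients; 0 (the
#'   default) keeps the exact sign form, whose gradient is zero almost
#'   everywhere so training gradients flow through the autofocus term only.
#' @param lr Initial Adam learning rate.
#' @param lr_decay Per-epoch exponential decay factor in `(0, 1]`.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience, in epochs.
#' @param min_delta Minimal validation-loss improvement to reset patience.
#' @param grad_clip Global gradient L2-norm clip.
#' @param K_predict Number of control cells sampled per prediction.
#' @param seed Integer seed governing initialization and pairing.
#' @return A `scouter_config` list.
#' @export
scouter_config <- function(n_genes, embedding_dim,
                           compressor_hidden = c(2048L, 512L),
                           bottleneck = 64L,
                           generator_hidden = 2048L,
                           batch_norm = TRUE,
                           dropout = 0,
                           gamma_loss = 0,
                           lambda_dir = 0.05,
                           dir_smooth_alpha = 0,
                           lr = 0.001,
                           lr_decay = 0.9,
                           batch_size = 256L,
                           max_epochs = 40L,
                           patience = 5L,
                           min_delta = 0.001,
                           grad_clip = 1.0,
                           K_predict = 300L,
                           seed = 1L) {
  stopifnot(is_count(n_genes), is_count(embedding_dim), is_count(bottleneck),
            all(vapply(compressor_hidden, is_count, logical(1))),
            all(vapply(generator_hidden, is_count, logical(1))),
            is_count(batch_size), is_count(max_epochs), is_count(patience),
            is_count(K_predict))
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (gamma_loss < 0 || lambda_dir < 0) stopf("gamma_loss and lambda_dir must be >= 0")
  if (lr <= 0) stopf("lr must be positive")
  if (lr_decay <= 0 || lr_decay > 1) stopf("lr_decay must be in (0, 1]")
  structure(list(
    n_genes = as.integer(n_genes), embedding_dim = as.integer(embedding_dim),
    compressor_hidden = as.integer(compressor_hidden),
    bottleneck = as.integer(bottleneck),
    generator_hidden = as.integer(generator_hidden),
    activation = "SELU", batch_norm = isTRUE(batch_norm), layer_norm = FALSE,
    dropout = dropout, gamma_loss = gamma_loss, lambda_dir = lambda_dir,
    dir_smooth_alpha = dir_smooth_alpha,
    lr = lr, lr_decay = lr_decay, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    min_delta = min_delta, grad_clip = grad_clip,
    K_predict = as.integer(K_predict), seed = as.integer(seed)),
    class = "scouter_config")
}

#' Per-dataset hyperparameter presets
#'
#' The tuned (gamma_loss, lambda_dir, lr) triples selected by grid search on
#' the five published Perturb-seq datasets, plus a `"sim"` preset sized for
#' the package's synthetic data (smaller layers, same training protocol, lr
#' from the same grid).
#'
#' @param name One of `"dixit"`, `"adamson"`, `"norman"`, `"replogle_k562"`,
#'   `"replogle_rpe1"`, `"sim"`.
#' @param n_genes,embedding_dim Passed through to [scouter_config()].
#' @param ... Further overrides for [scouter_config()].
#' @return A `scouter_config`.
#' @export
scouter_preset <- function(name, n_genes, embedding_dim, ...) {
  presets <- list(
    dixit         = list(gamma_loss = 0, lambda_dir = 0.05, lr = 0.01),
    adamson       = list(gamma_loss = 0, lambda_dir = 0.01, lr = 0.001),
    norman        = list(gamma_loss = 0, lambda_dir = 0.05, lr = 0.001),
    replogle_k562 = list(gamma_loss = 0, lambda_dir = 0.5,  lr = 0.001),
    replogle_rpe1 = list(gamma_loss = 0, lambda_dir = 0.5,  lr = 0.001),
    sim           = list(gamma_loss = 0, lambda_dir = 0.05, lr = 0.005,
                         compressor_hidden = c(256L, 64L), bottleneck = 32L,
                         generator_hidden = 256L))
  if (!name %in% names(presets))
    stopf("unknown preset %s; available: %s", dQuote(name),
          paste(names(presets), collapse = ", "))
  args <- utils::modifyList(presets[[name]],
                            list(n_genes = n_genes, embedding_dim = embedding_dim, ...))
  do.call(scouter_config, args)
}

#' Read / write a configuration as JSON
#' @param config A `scouter_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$activation <- NULL; raw$layer_norm <- NULL
  do.call(scouter_config, raw)
}
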