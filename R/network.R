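# Compressor-generator network: plain-matrix MLP layers with hand-written
# forward/backward passes. Layers are lists; a module is a list of layers.
# All matrices are batch x features.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

# LeCun-normal initialization (the self-normalizing-network default for SELU).
init_dense <- function(fan_in, fan_out) {
  list(type = "dense",
       W = matrix(stats::rnorm(fan_in * fan_out, sd = 1 / sqrt(fan_in)), fan_in, fan_out),
       b = numeric(fan_out))
}

init_bn <- function(width, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, width), beta = numeric(width),
       rmean = numeric(width), rvar = rep(1, width),
       momentum = momentum, eps = eps)
}

# hidden stack: dense -> [bn] -> selu -> [alpha dropout], then linear head
make_mlp <- function(n_in, hidden, n_out, batch_norm, dropout) {
  layers <- list()
  prev <- n_in
  for (h in hidden) {
    layers <- c(layers, list(init_dense(prev, h)))
    if (batch_norm) layers <- c(layers, list(init_bn(h)))
    layers <- c(layers, list(list(type = "selu")))
    if (dropout > 0) layers <- c(layers, list(list(type = "alpha_dropout", p = dropout)))
    prev <- h
  }
  c(layers, list(init_dense(prev, n_out)))
}

#' Build an untrained compressor-generator model
#'
#' The compressor maps a control cell's expression vector (length `n_genes`)
#' through SELU hidden layers (batch-normalized when enabled) to a linear
#' bottleneck state. The generator takes the concatenation (state, embedding)
#' through its own SELU hidden stack to a linear output of length `n_genes`.
#' The perturbation embedding enters as an external frozen vector; there is no
#' trainable embedding lookup.
#'
#' @param config A [scouter_config()].
#' @return A `scouter_model` (untrained) holding the layer parameters.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "scouter_config"))
  with_seed(derive_seed(config$seed, 0), {
    compressor <- make_mlp(config$n_genes, config$compressor_hidden,
                           config$bottleneck, config$batch_norm, config$dropout)
    generator <- make_mlp(config$bottleneck + config$embedding_dim,
                          config$generator_hidden, config$n_genes,
                          config$batch_norm, config$dropout)
  })
  structure(list(config = config, compressor = compressor, generator = generator,
                 trained = FALSE, history = NULL, best_epoch = NA_integer_),
            class = "scouter_model")
}

#' @export
print.scouter_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("scouter_model: compressor %s; generator %s; %s; %d parameters\n",
              paste(c(cfg$n_genes, cfg$compressor_hidden, cfg$bottleneck), collapse = "-"),
              paste(c(cfg$bottleneck + cfg$embedding_dim, cfg$generator_hidden, cfg$n_genes),
                    collapse = "-"),
              if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch) else "untrained",
              count_parameters(x)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Weights and biases of every affine layer plus the scale/shift pair of every
#' batch-normalization layer (running statistics are not trainable).
#'
#' @param model A `scouter_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  one <- function(layers) sum(vapply(layers, function(l) {
    switch(l$type,
           dense = length(l$W) + length(l$b),
           bn = length(l$gamma) + length(l$beta),
           0L)
  }, numeric(1)))
  as.integer(one(model$compressor) + one(model$generator))
}

forward_layers <- function(layers, X, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "dense") {
      caches[[i]] <- list(X = X)
      X <- X %*% l$W
      X <- sweep(X, 2, l$b, `+`)
    } else if (l$type == "bn") {
      if (training) {
        mu <- colMeans(X)
        xc <- sweep(X, 2, mu)
        v <- colMeans(xc * xc)
        inv <- 1 / sqrt(v + l$eps)
        xhat <- sweep(xc, 2, inv, `*`)
        caches[[i]] <- list(xhat = xhat, inv = inv, mu = mu, v = v)
        X <- sweep(sweep(xhat, 2, l$gamma, `*`), 2, l$beta, `+`)
      } else {
        inv <- 1 / sqrt(l$rvar + l$eps)
        xhat <- sweep(sweep(X, 2, l$rmean), 2, inv, `*`)
        caches[[i]] <- list(eval = TRUE)
        X <- sweep(sweep(xhat, 2, l$gamma, `*`), 2, l$beta, `+`)
      }
    } else if (l$type == "selu") {
      caches[[i]] <- list(X = X)
      pos <- X > 0
      out <- SELU_LAMBDA * X
      out[!pos] <- SELU_LAMBDA * SELU_ALPHA * (exp(X[!pos]) - 1)
      X <- out
    } else if (l$type == "alpha_dropout") {
      if (training && l$p > 0) {
        ap <- -SELU_LAMBDA * SELU_ALPHA
        q <- 1 - l$p
        a <- (q + ap^2 * q * l$p)^(-0.5)
        b <- -a * ap * l$p
        mask <- matrix(stats::runif(length(X)) < q, nrow(X), ncol(X))
        caches[[i]] <- list(mask = mask, a = a)
        X <- a * (X * mask + ap * !mask) + b
      } else caches[[i]] <- list(identity = TRUE)
    }
  }
  list(out = X, caches = caches)
}

# Returns gradient wrt the module input plus per-layer parameter gradients.
backward_layers <- function(layers, caches, dY) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]; cache <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = crossprod(cache$X, dY), b = colSums(dY))
      dY <- tcrossprod(dY, l$W)
    } else if (l$type == "bn") {
      if (isTRUE(cache$eval)) stopf("cannot backpropagate through an eval-mode pass")
      xhat <- cache$xhat
      grads[[i]] <- list(gamma = colSums(dY * xhat), beta = colSums(dY))
      dxhat <- sweep(dY, 2, l$gamma, `*`)
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * xhat)
      dY <- sweep(sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`), 2, cache$inv, `*`)
    } else if (l$type == "selu") {
      X <- cache$X
      d <- matrix(SELU_LAMBDA, nrow(X), ncol(X))
      neg <- X <= 0
      d[neg] <- SELU_LAMBDA * SELU_ALPHA * exp(X[neg])
      dY <- dY * d
    } else if (l$type == "alpha_dropout") {
      if (!isTRUE(cache$identity)) dY <- dY * cache$a * cache$mask
    }
  }
  list(dX = dY, grads = grads)
}

# Update batch-norm running statistics after a training-mode forward pass.
update_bn_stats <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn" && !isTRUE(caches[[i]]$eval)) {
      m <- layers[[i]]$momentum
      layers[[i]]$rmean <- (1 - m) * layers[[i]]$rmean + m * caches[[i]]$mu
      layers[[i]]$rvar <- (1 - m) * layers[[i]]$rvar + m * caches[[i]]$v
    }
  }
  layers
}

#' Run the network forward
#'
#' @param model A `scouter_model`.
#' @param control Numeric matrix (cells x genes) of control profiles, or a
#'   single profile vector.
#' @param embedding Numeric matrix (cells x embedding_dim) of perturbation
#'   embeddings, or a single vector recycled across the batch.
#' @param mode `"eval"` (deterministic: batch-norm uses accumulated running
#'   statistics, no dropout sampling) or `"train"`.
#' @return Numeric matrix (cells x genes) of predicted perturbed profiles.
#' @export
forward <- function(model, control, embedding, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  fp <- forward_pass(model, control, embedding, training = mode == "train")
  fp$xhat
}

# Internal forward keeping caches for the backward pass.
forward_pass <- function(model, control, embedding, training) {
  cfg <- model$config
  if (is.null(dim(control))) control <- matrix(control, nrow = 1)
  if (is.null(dim(embedding))) embedding <- matrix(embedding, nrow(control), length(embedding), byrow = TRUE)
  if (ncol(control) != cfg$n_genes)
    stopf("control has %d genes, model expects %d", ncol(control), cfg$n_genes)
  if (ncol(embedding) != cfg$embedding_dim)
    stopf("embedding has dim %d, model expects %d", ncol(embedding), cfg$embedding_dim)
  if (nrow(embedding) != nrow(control))
    stopf("control (%d rows) and embedding (%d rows) batches differ", nrow(control), nrow(embedding))
  comp <- forward_layers(model$compressor, control, training)
  gen_in <- cbind(comp$out, embedding)  # concatenation order fixed: (state, embedding)
  gen <- forward_layers(model$generator, gen_in, training)
  list(xhat = gen$out, comp_caches = comp$caches, gen_caches = gen$caches,
       state = comp$out)
}

# Backward through generator then compressor; the embedding block of the
# concatenated input receives gradient too, but it is discarded: the embedding
# table is frozen by construction.
backward_pass <- function(model, fp, dXhat) {
  gen_b <- backward_layers(model$generator, fp$gen_caches, dXhat)
  dS <- gen_b$dX[, seq_len(model$config$bottleneck), drop = FALSE]
  comp_b <- backward_layers(model$compressor, fp$comp_caches, dS)
  list(comp = comp_b$grads, gen = gen_b$grads)
}
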