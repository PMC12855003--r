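# Training: each epoch pairs every perturbed cell of the phase with one
# control cell drawn uniformly with replacement, re-drawn every epoch for
# training and fixed once for validation. With n0 control cells and n_k cells
# perturbed for gene k, the sampler's support is the full n0 * sum_k(n_k)
# space of (control, perturbed) pairs.

#' Draw the control-perturbed pairing for one epoch
#'
#' @param dataset A `perturb_dataset`.
#' @param phase_perturbations Canonical perturbation strings of the phase.
#' @param epoch Epoch number (alters the draw deterministically).
#' @param seed Base seed.
#' @return List with `perturbed` (cell indices, each exactly once), `control`
#'   (paired control cell indices, uniform with replacement), `labels`.
#' @export
make_pairing <- function(dataset, phase_perturbations, epoch = 1, seed = 1) {
  perturbed <- which(dataset$labels %in% setdiff(phase_perturbations, "ctrl"))
  controls <- which(dataset$is_control)
  if (!length(perturbed)) stopf("phase has no perturbed cells")
  if (!length(controls)) stopf("phase has no control cells")
  paired <- with_seed(derive_seed(seed, epoch),
                      controls[sample.int(length(controls), length(perturbed), replace = TRUE)])
  list(perturbed = perturbed, control = paired, labels = dataset$labels[perturbed])
}

# Flat list of trainable arrays for one module, used by Adam and clipping.
adam_init <- function(layers) {
  lapply(layers, function(l) {
    switch(l$type,
           dense = list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0),
           bn = list(mg = l$gamma * 0, vg = l$gamma * 0, mb = l$beta * 0, vb = l$beta * 0),
           NULL)
  })
}

grad_sq_norm <- function(grads) {
  sum(vapply(grads, function(g) {
    if (is.null(g)) return(0)
    sum(vapply(g, function(a) sum(a * a), numeric(1)))
  }, numeric(1)))
}

scale_grads <- function(grads, s) {
  lapply(grads, function(g) if (is.null(g)) NULL else lapply(g, `*`, s))
}

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    l <- layers[[i]]; s <- state[[i]]
    if (l$type == "dense") {
      uW <- upd(l$W, grads[[i]]$W, s$mW, s$vW)
      ub <- upd(l$b, grads[[i]]$b, s$mb, s$vb)
      layers[[i]]$W <- uW$p; state[[i]]$mW <- uW$m; state[[i]]$vW <- uW$v
      layers[[i]]$b <- ub$p; state[[i]]$mb <- ub$m; state[[i]]$vb <- ub$v
    } else if (l$type == "bn") {
      ug <- upd(l$gamma, grads[[i]]$gamma, s$mg, s$vg)
      ub <- upd(l$beta, grads[[i]]$beta, s$mb, s$vb)
      layers[[i]]$gamma <- ug$p; state[[i]]$mg <- ug$m; state[[i]]$vg <- ug$v
      layers[[i]]$beta <- ub$p; state[[i]]$mb <- ub$m; state[[i]]$vb <- ub$v
    }
  }
  list(layers = layers, state = state)
}

# Embedding rows for a vector of canonical perturbation labels.
label_embedding_matrix <- function(labels, embeddings) {
  uniq <- unique(labels)
  emb <- t(vapply(uniq, function(p) embed_perturbation(embeddings, parse_label(p)),
                  numeric(embeddings$dim)))
  emb[match(labels, uniq), , drop = FALSE]
}

check_coverage <- function(embeddings, perts) {
  genes <- unique(unlist(lapply(perts, parse_label)))
  absent <- genes[!genes %in% embeddings$symbols]
  if (length(absent))
    stopf("missing embedding: %s", paste(sort(absent), collapse = ", "))
}

# Eval-mode loss over a fixed pairing, in batches to bound memory.
phase_loss <- function(model, dataset, pairing, emb_rows, cfg) {
  # the loss averages within each perturbation group before averaging groups;
  # accumulate per-perturbation means across chunks so chunking is exact
  ord <- order(pairing$labels)
  idx_chunks <- split(ord, ceiling(seq_along(ord) / max(cfg$batch_size, 1024L)))
  acc <- list()
  for (chunk in idx_chunks) {
    rows <- pairing$perturbed[chunk]
    ctrl <- dataset$expression[pairing$control[chunk], , drop = FALSE]
    xhat <- forward(model, ctrl, emb_rows[chunk, , drop = FALSE], mode = "eval")
    x <- dataset$expression[rows, , drop = FALSE]
    af <- rowSums(abs(x - xhat)^(2 + cfg$gamma_loss))
    dir <- rowSums((sign(x - ctrl) - sign(xhat - ctrl))^2)
    contrib <- (af + cfg$lambda_dir * dir) / ncol(x)
    for (lab in unique(pairing$labels[chunk])) {
      sel <- pairing$labels[chunk] == lab
      if (is.null(acc[[lab]])) acc[[lab]] <- c(0, 0)
      acc[[lab]] <- acc[[lab]] + c(sum(contrib[sel]), sum(sel))
    }
  }
  means <- vapply(acc, function(a) a[1] / a[2], numeric(1))
  mean(means)
}

#' Train a compressor-generator model
#'
#' Implements the full training protocol: per-epoch random control pairing,
#' shuffled minibatches (size `config$batch_size`, last partial batch kept),
#' Adam with the learning rate decayed by `config$lr_decay` each epoch,
#' global gradient-norm clipping at `config$grad_clip`, early stopping on the
#' validation loss (`config$patience` consecutive epochs with improvement
#' below `config$min_delta`), and restoration of the best-validation-loss
#' model state at the end. The validation pairing is drawn once per run so
#' the stopping criterion compares like with like.
#'
#' @param model An untrained `scouter_model` from [build_model()].
#' @param dataset A `perturb_dataset` with log-normalized expression.
#' @param split A split plan from [make_splits()] (uses `train` and `val`).
#' @param embeddings An [embedding_table()] covering all train/val targets.
#' @param config Optional [scouter_config()] override; defaults to the
#'   model's own config.
#' @param verbose Print per-epoch progress.
#' @return The trained `scouter_model` with `history` (data frame: epoch, lr,
#'   train_loss, val_loss) and `best_epoch` filled in.
#' @export
train <- function(model, dataset, split, embeddings, config = NULL, verbose = FALSE) {
  cfg <- config %||% model$config
  check_coverage(embeddings, c(split$train, split$val))
  val_pairing <- make_pairing(dataset, split$val, epoch = 0, seed = derive_seed(cfg$seed, 900001))
  val_emb <- label_embedding_matrix(val_pairing$labels, embeddings)

  comp_state <- adam_init(model$compressor)
  gen_state <- adam_init(model$generator)
  step <- 0
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  best_val <- Inf; best_epoch <- NA_integer_; best_state <- NULL
  stall <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    lr_e <- cfg$lr * cfg$lr_decay^(epoch - 1)
    pairing <- make_pairing(dataset, split$train, epoch = epoch, seed = cfg$seed)
    emb_rows <- label_embedding_matrix(pairing$labels, embeddings)
    n_tr <- length(pairing$perturbed)
    ord <- with_seed(derive_seed(cfg$seed, 100000 + epoch), sample.int(n_tr))
    batch_starts <- seq(1, n_tr, by = cfg$batch_size)
    epoch_loss <- 0
    for (b in batch_starts) {
      sel <- ord[b:min(b + cfg$batch_size - 1, n_tr)]
      x <- dataset$expression[pairing$perturbed[sel], , drop = FALSE]
      ctrl <- dataset$expression[pairing$control[sel], , drop = FALSE]
      emb <- emb_rows[sel, , drop = FALSE]
      batch <- triplet_batch(x, ctrl, pairing$labels[sel], emb)
      fp <- forward_pass(model, ctrl, emb, training = TRUE)
      loss <- total_loss(batch, fp$xhat, cfg$gamma_loss, cfg$lambda_dir)
      if (!is.finite(loss))
        stopf("training diverged: non-finite loss at epoch %d (try a lower lr)", epoch)
      dXhat <- loss_gradient(batch, fp$xhat, cfg$gamma_loss, cfg$lambda_dir,
                             cfg$dir_smooth_alpha)
      grads <- backward_pass(model, fp, dXhat)
      gnorm <- sqrt(grad_sq_norm(grads$comp) + grad_sq_norm(grads$gen))
      if (is.finite(gnorm) && gnorm > cfg$grad_clip) {
        s <- cfg$grad_clip / gnorm
        grads$comp <- scale_grads(grads$comp, s)
        grads$gen <- scale_grads(grads$gen, s)
      }
      step <- step + 1
      up <- adam_step(model$compressor, grads$comp, comp_state, lr_e, step)
      model$compressor <- update_bn_stats(up$layers, fp$comp_caches)
      comp_state <- up$state
      up <- adam_step(model$generator, grads$gen, gen_state, lr_e, step)
      model$generator <- update_bn_stats(up$layers, fp$gen_caches)
      gen_state <- up$state
      epoch_loss <- epoch_loss + loss * length(sel)
    }
    train_loss <- epoch_loss / n_tr
    val_loss <- phase_loss(model, dataset, val_pairing, val_emb, cfg)
    history <- rbind(history, data.frame(epoch = epoch, lr = lr_e,
                                         train_loss = train_loss, val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %2d  lr %.5f  train %.5f  val %.5f", epoch, lr_e,
                      train_loss, val_loss))
    if (best_val - val_loss > cfg$min_delta) {
      best_val <- val_loss; best_epoch <- epoch
      best_state <- list(compressor = model$compressor, generator = model$generator)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  if (!is.null(best_state)) {
    model$compressor <- best_state$compressor
    model$generator <- best_state$generator
  }
  model$trained <- TRUE
  model$history <- history
  model$best_epoch <- best_epoch
  model$best_val_loss <- best_val
  model$config <- cfg
  model
}

#' Validation loss of a model on a split
#'
#' Recomputes the (fixed-pairing) validation loss used during training; handy
#' for checking that the restored best state reproduces the recorded optimum.
#'
#' @inheritParams train
#' @return Scalar validation loss.
#' @export
validation_loss <- function(model, dataset, split, embeddings) {
  cfg <- model$config
  val_pairing <- make_pairing(dataset, split$val, epoch = 0, seed = derive_seed(cfg$seed, 900001))
  phase_loss(model, dataset, val_pairing, label_embedding_matrix(val_pairing$labels, embeddings), cfg)
}

#' Hyperparameter grid search
#'
#' Trains one model per (grid point x split) and returns the base
#' configuration updated with the grid point whose mean best validation loss
#' across splits is lowest. The default grids are the published tuning grids:
#' gamma_loss in {0, 2}, lambda_dir in {0.01, 0.05, 0.1, 0.5}, lr in
#' {0.001, 0.005, 0.01}.
#'
#' @param dataset A `perturb_dataset`.
#' @param splits List of split plans.
#' @param embeddings An [embedding_table()].
#' @param base_config A [scouter_config()].
#' @param gamma_loss_grid,lambda_grid,lr_grid Candidate values.
#' @param verbose Print per-point results.
#' @return `base_config` with the winning `gamma_loss`, `lambda_dir`, `lr`.
#' @export
grid_search <- function(dataset, splits, embeddings, base_config,
                        gamma_loss_grid = c(0, 2),
                        lambda_grid = c(0.01, 0.05, 0.1, 0.5),
                        lr_grid = c(0.001, 0.005, 0.01),
                        verbose = FALSE) {
  stopifnot(length(splits) >= 1, length(gamma_loss_grid) >= 1,
            length(lambda_grid) >= 1, length(lr_grid) >= 1)
  grid <- expand.grid(gamma_loss = gamma_loss_grid, lambda_dir = lambda_grid,
                      lr = lr_grid, KEEP.OUT.ATTRS = FALSE)
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$gamma_loss <- grid$gamma_loss[i]
    cfg$lambda_dir <- grid$lambda_dir[i]
    cfg$lr <- grid$lr[i]
    vals <- vapply(splits, function(sp) {
      fit <- tryCatch(train(build_model(cfg), dataset, sp, embeddings, cfg),
                      error = function(e) stopf("grid point (gamma=%g, lambda=%g, lr=%g): %s",
                                                cfg$gamma_loss, cfg$lambda_dir, cfg$lr,
                                                conditionMessage(e)))
      fit$best_val_loss
    }, numeric(1))
    scores[i] <- mean(vals)
    if (verbose)
      message(sprintf("gamma=%g lambda=%g lr=%g -> mean val %.5f",
                      grid$gamma_loss[i], grid$lambda_dir[i], grid$lr[i], scores[i]))
  }
  best <- which.min(scores)
  out <- base_config
  out$gamma_loss <- grid$gamma_loss[best]
  out$lambda_dir <- grid$lambda_dir[best]
  out$lr <- grid$lr[best]
  out
}
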