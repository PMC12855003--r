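test_that("pairing covers every perturbed cell once with controls drawn uniformly", {
  ds <- toy_dataset()
  p <- make_pairing(ds, c("A", "B"), epoch = 1, seed = 3)
  expect_setequal(p$perturbed, which(!ds$is_control))
  expect_length(p$control, 3)
  expect_true(all(p$control %in% which(ds$is_control)))
  expect_identical(make_pairing(ds, c("A", "B"), epoch = 1, seed = 3), p)
  expect_false(identical(make_pairing(ds, c("A", "B"), epoch = 2, seed = 3)$control,
                         p$control) &&
               identical(make_pairing(ds, c("A", "B"), epoch = 3, seed = 3)$control,
                         p$control))
  p_sub <- make_pairing(ds, "A", epoch = 1, seed = 3)
  expect_length(p_sub$perturbed, 2)
  expect_error(make_pairing(ds, character(0), 1, 1), "no perturbed cells")
})

test_that("the pairing sampler's support is the full n0 x sum(nk) pair space", {
  # 2 controls x 3 perturbed cells -> 6 distinct pairs
  expr <- matrix(rnorm(10), 5, 2)
  ds <- perturb_dataset(expr, c("g1", "g2"), c("ctrl", "ctrl", "A", "A", "B"))
  seen <- table(factor(character(), levels = outer(3:5, 1:2, paste)))
  for (epoch in 1:2000) {
    p <- make_pairing(ds, c("A", "B"), epoch = epoch, seed = 17)
    keys <- paste(p$perturbed, p$control)
    seen[keys] <- seen[keys] + 1
  }
  expect_identical(sum(seen == 0), 0L)          # support enumerates all 6 pairs
  ctrl_counts <- c(sum(seen[c(1, 2, 3)]), sum(seen[c(4, 5, 6)]))
  expect_gt(stats::chisq.test(ctrl_counts)$p.value, 0.01)
})

test_that("training follows the decayed LR schedule and records history", {
  sim <- tiny_sim()
  sp <- make_splits(sim$dataset, seed = 7)[[1]]
  cfg <- tiny_config(max_epochs = 6L)
  fit <- train(build_model(cfg), sim$dataset, sp, sim$embeddings)
  expect_equal(fit$history$lr, cfg$lr * cfg$lr_decay^(fit$history$epoch - 1),
               tolerance = 1e-12)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(fit$trained)
})

test_that("two runs with the same config and seed are identical", {
  sim <- tiny_sim()
  sp <- make_splits(sim$dataset, seed = 7)[[1]]
  cfg <- tiny_config(max_epochs = 4L)
  fit1 <- train(build_model(cfg), sim$dataset, sp, sim$embeddings)
  fit2 <- train(build_model(cfg), sim$dataset, sp, sim$embeddings)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$compressor, fit2$compressor)
})

test_that("early stopping fires after `patience` non-improving epochs on a plateau", {
  sim <- tiny_sim()
  sp <- make_splits(sim$dataset, seed = 7)[[1]]
  # an unreachable improvement threshold makes every epoch after the first a stall
  cfg <- tiny_config(max_epochs = 30L, patience = 3L, min_delta = 1e9)
  fit <- train(build_model(cfg), sim$dataset, sp, sim$embeddings)
  expect_identical(nrow(fit$history), 1L + 3L)
  expect_identical(fit$best_epoch, 1L)
})

test_that("the restored best state reproduces the recorded best validation loss", {
  sim <- tiny_sim()
  sp <- make_splits(sim$dataset, seed = 7)[[1]]
  fit <- train(build_model(tiny_config(max_epochs = 6L)), sim$dataset, sp, sim$embeddings)
  expect_equal(validation_loss(fit, sim$dataset, sp, sim$embeddings),
               min(fit$history$val_loss), tolerance = 1e-12)
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("the embedding table is bit-identical after a full training run", {
  sim <- tiny_sim()
  sp <- make_splits(sim$dataset, seed = 7)[[1]]
  before <- sim$embeddings$matrix
  checksum_before <- scouter:::embedding_checksum(sim$embeddings)
  invisible(train(build_model(tiny_config(max_epochs = 3L)), sim$dataset, sp, sim$embeddings))
  expect_identical(sim$embeddings$matrix, before)
  expect_identical(scouter:::embedding_checksum(sim$embeddings), checksum_before)
})

test_that("training aborts with context when embeddings are missing", {
  sim <- tiny_sim()
  sp <- make_splits(sim$dataset, seed = 7)[[1]]
  reduced <- embedding_table(
    sim$embeddings$matrix[setdiff(sim$embeddings$symbols, sp$train[1]), ])
  expect_error(train(build_model(tiny_config()), sim$dataset, sp, reduced),
               paste0("missing embedding.*", sp$train[1]))
})

test_that("grid search returns the dominant point and passes through 1x1x1 grids", {
  sim <- tiny_sim()
  sp <- make_splits(sim$dataset, seed = 7)
  base <- tiny_config(max_epochs = 3L)
  single <- grid_search(sim$dataset, sp, sim$embeddings, base,
                        gamma_loss_grid = 0, lambda_grid = 0.05, lr_grid = 0.005)
  expect_identical(single$lambda_dir, 0.05)
  expect_identical(single$lr, 0.005)
  # an adversarially huge direction weight loses on validation loss
  won <- grid_search(sim$dataset, sp, sim$embeddings, base,
                     gamma_loss_grid = 0, lambda_grid = c(0.05, 1e6),
                     lr_grid = 0.005)
  expect_identical(won$lambda_dir, 0.05)
})

test_that("shipped presets carry the published hyperparameter values", {
  cases <- list(dixit = c(0.05, 0.01), adamson = c(0.01, 0.001),
                norman = c(0.05, 0.001), replogle_k562 = c(0.5, 0.001),
                replogle_rpe1 = c(0.5, 0.001))
  for (nm in names(cases)) {
    cfg <- scouter_preset(nm, n_genes = 100, embedding_dim = 16)
    expect_identical(cfg$gamma_loss, 0)
    expect_identical(cfg$lambda_dir, cases[[nm]][1])
    expect_identical(cfg$lr, cases[[nm]][2])
    expect_identical(cfg$batch_size, 256L)
    expect_identical(cfg$max_epochs, 40L)
    expect_identical(cfg$patience, 5L)
    expect_identical(cfg$min_delta, 0.001)
    expect_identical(cfg$grad_clip, 1)
    expect_identical(cfg$K_predict, 300L)
  }
})
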