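toy_net_config <- function(...) {
  scouter_config(n_genes = 10, embedding_dim = 3,
                 compressor_hidden = c(4L, 3L), bottleneck = 2L,
                 generator_hidden = 4L, seed = 7, ...)
}

test_that("parameter count matches the hand-computed affine + batch-norm total", {
  model <- build_model(toy_net_config())
  # compressor: 10->4 (44) + bn4 (8) + 4->3 (15) + bn3 (6) + 3->2 (8) = 81
  # generator: (2+3)=5->4 (24) + bn4 (8) + 4->10 (50) = 82
  expect_identical(count_parameters(model), 163L)
  no_bn <- build_model(toy_net_config(batch_norm = FALSE))
  expect_identical(count_parameters(no_bn), 163L - 8L - 6L - 8L)
})

test_that("default-scale architecture wires 5000-2048-512-64 and 1600-2048-5000", {
  cfg <- scouter_config(n_genes = 5000, embedding_dim = 1536)
  model <- build_model(cfg)
  dense_dims <- function(layers)
    lapply(Filter(function(l) l$type == "dense", layers), function(l) dim(l$W))
  expect_identical(dense_dims(model$compressor),
                   list(c(5000L, 2048L), c(2048L, 512L), c(512L, 64L)))
  expect_identical(dense_dims(model$generator),
                   list(c(1600L, 2048L), c(2048L, 5000L)))
  # dropout defaults to 0: no dropout layers anywhere
  types <- vapply(c(model$compressor, model$generator), `[[`, character(1), "type")
  expect_false("alpha_dropout" %in% types)
})

test_that("eval-mode forward is deterministic and batch rows are independent", {
  model <- build_model(toy_net_config())
  ctrl <- with_seed2(1, matrix(rnorm(50), 5, 10))
  emb <- with_seed2(2, matrix(rnorm(15), 5, 3))
  out1 <- forward(model, ctrl, emb, mode = "eval")
  out2 <- forward(model, ctrl, emb, mode = "eval")
  expect_identical(out1, out2)
  # row i of a batched call equals the single-row call
  for (i in c(1, 4))
    expect_equal(forward(model, ctrl[i, ], emb[i, ], mode = "eval"),
                 out1[i, , drop = FALSE], tolerance = 1e-12)
})

test_that("the output is conditioned on the embedding input", {
  model <- build_model(toy_net_config())
  ctrl <- with_seed2(3, rnorm(10))
  emb <- with_seed2(4, rnorm(3))
  base <- forward(model, ctrl, emb)
  bumped <- emb; bumped[2] <- bumped[2] + 1
  expect_gt(max(abs(forward(model, ctrl, bumped) - base)), 0)
})

test_that("model shape mismatches are reported", {
  model <- build_model(toy_net_config())
  expect_error(forward(model, rnorm(9), rnorm(3)), "genes")
  expect_error(forward(model, rnorm(10), rnorm(2)), "dim")
})

test_that("network gradients agree with finite differences through BN and SELU", {
  cfg <- toy_net_config()
  model <- build_model(cfg)
  ctrl <- with_seed2(5, matrix(rnorm(40), 4, 10))
  emb <- with_seed2(6, matrix(rnorm(12), 4, 3))
  x <- with_seed2(7, matrix(rnorm(40), 4, 10))
  labels <- c("a", "a", "b", "b")
  batch <- triplet_batch(x, ctrl, labels)
  loss_at <- function(m) {
    fp <- scouter:::forward_pass(m, ctrl, emb, training = TRUE)
    total_loss(batch, fp$xhat, 0, 0)
  }
  fp <- scouter:::forward_pass(model, ctrl, emb, training = TRUE)
  grads <- scouter:::backward_pass(model, fp,
    scouter:::loss_gradient(batch, fp$xhat, 0, 0))
  eps <- 1e-6
  # probe a few weights in each module and layer kind
  probes <- list(list("compressor", 1, "W", 5), list("compressor", 2, "gamma", 2),
                 list("compressor", 4, "W", 1), list("generator", 1, "b", 3),
                 list("generator", 2, "beta", 4), list("generator", 4, "W", 17))
  for (p in probes) {
    mod <- p[[1]]; li <- p[[2]]; par <- p[[3]]; k <- p[[4]]
    up <- model; up[[mod]][[li]][[par]][k] <- up[[mod]][[li]][[par]][k] + eps
    dn <- model; dn[[mod]][[li]][[par]][k] <- dn[[mod]][[li]][[par]][k] - eps
    fd <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    an <- grads[[if (mod == "compressor") "comp" else "gen"]][[li]][[par]][k]
    expect_equal(an, fd, tolerance = 1e-5)
  }
})

test_that("a checkpoint restores config, weights and eval outputs", {
  model <- build_model(toy_net_config())
  ctrl <- with_seed2(8, matrix(rnorm(30), 3, 10))
  emb <- with_seed2(9, matrix(rnorm(9), 3, 3))
  path <- tempfile(fileext = ".json")
  save_scouter(model, path)
  back <- load_scouter(path)
  expect_equal(forward(back, ctrl, emb), forward(model, ctrl, emb), tolerance = 1e-12)
  expect_identical(back$config$compressor_hidden, model$config$compressor_hidden)
})

test_that("the network can memorize a single noise-free perturbation", {
  sim <- tiny_sim(seed = 21, n_genes = 20, n_perts = 3, n_cells = 15,
                  n_controls = 40, dim = 6, noise_sd = 1e-4)
  # constant learning rate and generous epochs: a pure capacity check
  cfg <- tiny_config(n_genes = 20, dim = 6, max_epochs = 60L, batch_size = 8L,
                     lambda_dir = 0, patience = 60L, lr = 0.01, lr_decay = 1)
  sp <- list(train = perturbations(sim$dataset)[1:2],
             val = perturbations(sim$dataset)[3], scheme = "manual", seed = 1)
  fit <- train(build_model(cfg), sim$dataset, sp, sim$embeddings)
  expect_lt(tail(fit$history$train_loss, 1), 0.05 * fit$history$train_loss[1])
  expect_lt(tail(fit$history$train_loss, 1), 0.1)
})
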