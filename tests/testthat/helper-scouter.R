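# Shared fixtures, all generated in code.

# A hand-sized labeled dataset: 4 controls, 2 cells of "A", 1 of "B", genes g1..g3.
toy_dataset <- function() {
  expr <- rbind(
    c(1.0, 2.0, 3.0), c(1.1, 1.9, 3.1), c(0.9, 2.1, 2.9), c(1.0, 2.0, 3.0),
    c(2.0, 2.0, 3.0), c(2.2, 2.1, 3.0),
    c(1.0, 0.5, 3.5))
  perturb_dataset(expr, c("g1", "g2", "g3"),
                  c("ctrl", "ctrl", "ctrl", "ctrl", "A", "A", "B"))
}

# Small embedding table over the given symbols.
toy_embeddings <- function(symbols = c("A", "B", "C"), dim = 4, seed = 1) {
  mat <- with_seed2(seed, matrix(rnorm(length(symbols) * dim), length(symbols), dim))
  rownames(mat) <- symbols
  embedding_table(mat)
}

# Seed helper mirroring the package-internal one for test-side draws.
with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Small simulated study + matching desk-scale config for fast training tests.
tiny_sim <- function(seed = 3, n_genes = 30, n_perts = 8, n_cells = 20,
                     n_controls = 100, dim = 8, ...) {
  simulate_dataset(sim_config(n_genes = n_genes, n_perts = n_perts,
                              n_cells_per_pert = n_cells, n_controls = n_controls,
                              embedding_dim = dim, seed = seed, ...))
}

tiny_config <- function(n_genes = 30, dim = 8, seed = 5, batch_size = 64L,
                        max_epochs = 8L, ...) {
  scouter_preset("sim", n_genes = n_genes, embedding_dim = dim,
                 compressor_hidden = c(32L, 16L), bottleneck = 8L,
                 generator_hidden = 32L, batch_size = batch_size,
                 max_epochs = max_epochs, seed = seed, ...)
}

# Naive triple-loop oracles for the loss terms (kept deliberately independent
# of the vectorized implementation).
naive_autofocus <- function(X, C, P, Xhat, gamma) {
  perts <- unique(P)
  total <- 0
  for (t in perts) {
    idx <- which(P == t)
    s <- 0
    for (i in idx) for (g in seq_len(ncol(X)))
      s <- s + abs(X[i, g] - Xhat[i, g])^(2 + gamma)
    total <- total + s / (length(idx) * ncol(X))
  }
  total / length(perts)
}

naive_direction <- function(X, C, P, Xhat) {
  perts <- unique(P)
  total <- 0
  for (t in perts) {
    idx <- which(P == t)
    s <- 0
    for (i in idx) for (g in seq_len(ncol(X)))
      s <- s + (sign(X[i, g] - C[i, g]) - sign(Xhat[i, g] - C[i, g]))^2
    total <- total + s / (length(idx) * ncol(X))
  }
  total / length(perts)
}

random_batch <- function(seed, N_max = 10, G_max = 8) {
  with_seed2(seed, {
    N <- sample(1:N_max, 1)
    G <- sample(2:G_max, 1)
    M <- sample(1:N, 1)
    list(X = matrix(rnorm(N * G), N, G),
         C = matrix(rnorm(N * G), N, G),
         P = paste0("p", sample(seq_len(M), N, replace = TRUE)),
         Xhat = matrix(rnorm(N * G), N, G))
  })
}
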