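# Synthetic Perturb-seq-like data with embedding-linked ground truth. Control
# cells are noisy draws around a baseline profile; a perturbation's effect
# vector is a linear function of its gene embedding (delta = W %*% E(g)),
# which is exactly the structure that makes extrapolation to unseen
# perturbations possible; two-gene effects are additive plus an optional
# interaction term. Values live in log-normalized expression space.

#' Simulation configuration
#'
#' Defaults define the package's reference synthetic study: 200 genes, 40
#' single-gene perturbations with 100 cells each, 2,000 control cells, 32-dim
#' embeddings, per-gene effect standard deviation 1.0 against measurement
#' noise 0.2 (effects about 5x noise), fully dense effects, no two-gene
#' combos, purely additive doubles when present.
#'
#' @param n_genes Number of genes in the panel.
#' @param n_perts Number of single-gene perturbations.
#' @param n_cells_per_pert Cells per perturbation.
#' @param n_controls Control cells.
#' @param embedding_dim Embedding length.
#' @param effect_scale Per-gene effect standard deviation (log-expression
#'   units); entries of the effect map W are N(0, effect_scale^2) and
#'   embeddings are scaled to unit expected norm, so a typical per-gene
#'   effect has sd ~ effect_scale.
#' @param noise_sd Per-gene Gaussian noise standard deviation.
#' @param sparsity Fraction of genes affected per perturbation, in (0, 1].
#'   When < 1, the affected set is the top `ceiling(sparsity * n_genes)` genes
#'   by |W E(g)| — deterministic given the embedding, so effects remain a
#'   function of the embedding.
#' @param n_double Number of two-gene combinations (targets drawn from the
#'   single-perturbation genes).
#' @param interaction_sd Standard deviation of the extra per-gene interaction
#'   effect for doubles; 0 means purely additive.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200, n_perts = 40, n_cells_per_pert = 100,
                       n_controls = 2000, embedding_dim = 32,
                       effect_scale = 1.0, noise_sd = 0.2, sparsity = 1.0,
                       n_double = 0, interaction_sd = 0, seed = 1) {
  stopifnot(is_count(n_genes), is_count(n_perts), is_count(n_cells_per_pert),
            is_count(n_controls), is_count(embedding_dim))
  if (noise_sd <= 0) stopf("noise_sd must be positive")
  if (sparsity <= 0 || sparsity > 1) stopf("sparsity must be in (0, 1]")
  if (interaction_sd < 0) stopf("interaction_sd must be >= 0")
  if (n_double > choose(n_perts, 2)) stopf("n_double exceeds available gene pairs")
  structure(list(n_genes = as.integer(n_genes), n_perts = as.integer(n_perts),
                 n_cells_per_pert = as.integer(n_cells_per_pert),
                 n_controls = as.integer(n_controls),
                 embedding_dim = as.integer(embedding_dim),
                 effect_scale = effect_scale, noise_sd = noise_sd,
                 sparsity = sparsity, n_double = as.integer(n_double),
                 interaction_sd = interaction_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a Perturb-seq-like dataset with ground truth
#'
#' @param cfg A [sim_config()].
#' @return List with `dataset` (a [perturb_dataset()]), `embeddings` (an
#'   [embedding_table()] over all panel genes), and `truth` (baseline `mu`,
#'   linear map `W`, `effect_map` of true per-perturbation effect vectors,
#'   `interactions`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    mu <- stats::runif(cfg$n_genes, 0.5, 5)
    # embeddings ~ N(0, 1/dim) entries: expected unit squared norm
    emb_mat <- matrix(stats::rnorm(cfg$n_genes * cfg$embedding_dim,
                                   sd = 1 / sqrt(cfg$embedding_dim)),
                      cfg$n_genes, cfg$embedding_dim, dimnames = list(genes, NULL))
    W <- matrix(stats::rnorm(cfg$n_genes * cfg$embedding_dim, sd = cfg$effect_scale),
                cfg$n_genes, cfg$embedding_dim)

    pert_genes <- sample(genes, cfg$n_perts)
    effect_of <- function(e) {
      delta <- as.numeric(W %*% e)
      if (cfg$sparsity < 1) {
        keep <- order(-abs(delta))[seq_len(ceiling(cfg$sparsity * cfg$n_genes))]
        delta[-keep] <- 0
      }
      delta
    }
    effect_map <- lapply(stats::setNames(nm = pert_genes),
                         function(g) effect_of(emb_mat[g, ]))

    doubles <- character(0); interactions <- list()
    if (cfg$n_double > 0) {
      pairs <- t(utils::combn(pert_genes, 2))
      pick <- pairs[sample.int(nrow(pairs), cfg$n_double), , drop = FALSE]
      doubles <- apply(pick, 1, function(r) canonical_label(r))
      for (i in seq_len(nrow(pick))) {
        inter <- if (cfg$interaction_sd > 0)
          stats::rnorm(cfg$n_genes, sd = cfg$interaction_sd) else numeric(cfg$n_genes)
        interactions[[doubles[i]]] <- inter
        effect_map[[doubles[i]]] <- effect_map[[pick[i, 1]]] + effect_map[[pick[i, 2]]] + inter
      }
    }

    all_perts <- c(pert_genes, doubles)
    n_pert_cells <- length(all_perts) * cfg$n_cells_per_pert
    labels <- c(rep("ctrl", cfg$n_controls), rep(all_perts, each = cfg$n_cells_per_pert))
    n_cells <- cfg$n_controls + n_pert_cells
    noise <- matrix(stats::rnorm(n_cells * cfg$n_genes, sd = cfg$noise_sd),
                    n_cells, cfg$n_genes)
    expr <- matrix(mu, n_cells, cfg$n_genes, byrow = TRUE) + noise
    row <- cfg$n_controls
    for (p in all_perts) {
      idx <- row + seq_len(cfg$n_cells_per_pert)
      expr[idx, ] <- expr[idx, ] + matrix(effect_map[[p]], cfg$n_cells_per_pert,
                                          cfg$n_genes, byrow = TRUE)
      row <- row + cfg$n_cells_per_pert
    }
  })
  list(dataset = perturb_dataset(expr, genes, labels),
       embeddings = embedding_table(emb_mat),
       truth = list(mu = mu, W = W, effect_map = effect_map,
                    interactions = interactions, config = cfg))
}

#' Score predictions against the noise-free ground truth
#'
#' Evaluates each prediction against the true perturbed profile `mu + delta`
#' with control profile `mu` and DEGs ranked by the true |delta| — an upper
#' bound on what any predictor can achieve on the simulated study.
#'
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @param predictions List of `prediction_result` objects.
#' @param top_k DEG-set size.
#' @return Data frame with per-perturbation `normalized_mse`, `one_minus_pcc`.
#' @export
oracle_metrics <- function(truth, predictions, top_k = 20) {
  rows <- lapply(predictions, function(pred) {
    p <- pred$perturbation
    delta <- truth$effect_map[[p]]
    if (is.null(delta)) stopf("unknown perturbation %s in ground truth", dQuote(p))
    degs <- order(-abs(delta), seq_along(delta))[seq_len(top_k)]
    x <- (truth$mu + delta)[degs]
    cc <- truth$mu[degs]
    data.frame(perturbation = p,
               normalized_mse = normalized_mse(x, pred$mean_profile[degs], cc),
               one_minus_pcc = one_minus_pcc(x, pred$mean_profile[degs], cc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated study to disk
#'
#' Dataset as MTX + sidecars, embeddings as CSV, ground truth as JSON
#' (baseline, effect map, config and seed).
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_dataset(sim$dataset, dir)
  write_embeddings(sim$embeddings, file.path(dir, "embeddings.csv"))
  jsonlite::write_json(
    list(mu = sim$truth$mu, effect_map = sim$truth$effect_map,
         interactions = sim$truth$interactions, config = unclass(sim$truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
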