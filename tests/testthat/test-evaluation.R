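test_that("DEG ranking by absolute mean shift matches a per-gene loop, ties by index", {
  sim <- tiny_sim(seed = 6, n_genes = 15, n_perts = 3, n_cells = 10, n_controls = 30, dim = 4)
  ds <- sim$dataset
  p <- perturbations(ds)[1]
  got <- top_degs(ds, p, top_k = 5)
  # brute-force oracle
  shifts <- numeric(15)
  for (g in 1:15)
    shifts[g] <- abs(mean(ds$expression[ds$labels == p, g]) -
                       mean(ds$expression[ds$is_control, g]))
  expect_identical(got$genes, order(-shifts, 1:15)[1:5])
  expect_identical(got$source, "computed")

  # all-tied ranking falls back to index order
  flat <- perturb_dataset(matrix(1, 4, 5), paste0("g", 1:5), c("ctrl", "ctrl", "A", "A"))
  expect_identical(top_degs(flat, "A", 3)$genes, 1:3)

  # constructed shifts occupy the top ranks
  expr <- matrix(2, 6, 6)
  expr[5:6, c(2, 4, 6)] <- expr[5:6, c(2, 4, 6)] + c(3, -4, 5)
  shifted <- perturb_dataset(expr, paste0("g", 1:6),
                             c("ctrl", "ctrl", "ctrl", "ctrl", "A", "A"))
  expect_setequal(top_degs(shifted, "A", 3)$genes, c(2, 4, 6))

  # provided DEG lists take precedence
  expect_identical(top_degs(ds, p, 3, provided = c(9L, 2L, 7L))$source, "provided")
  expect_identical(top_degs(ds, p, 3, provided = c(9L, 2L, 7L))$genes, c(9L, 2L, 7L))
})

test_that("normalized MSE anchors the no-change baseline at exactly 1", {
  for (seed in 1:5) {
    x <- with_seed2(seed, rnorm(20))
    c0 <- with_seed2(seed + 100, rnorm(20))
    expect_identical(normalized_mse(x, c0, c0), 1)
    expect_identical(normalized_mse(x, x, c0), 0)
  }
  expect_equal(normalized_mse(c(1, 0), c(0.5, 0), c(0, 0)), 0.25, tolerance = 1e-15)
  expect_warning(expect_true(is.na(normalized_mse(c(1, 1), c(1, 2), c(1, 1)))),
                 "undefined")
})

test_that("1 - PCC matches a textbook computation and spans [0, 2]", {
  x <- with_seed2(31, rnorm(20)); xhat <- with_seed2(32, rnorm(20))
  c0 <- with_seed2(33, rnorm(20))
  dx <- x - c0; dh <- xhat - c0
  pcc <- sum((dx - mean(dx)) * (dh - mean(dh))) /
    sqrt(sum((dx - mean(dx))^2) * sum((dh - mean(dh))^2))
  expect_equal(one_minus_pcc(x, xhat, c0), 1 - pcc, tolerance = 1e-12)
  expect_equal(one_minus_pcc(x, c0 + 3 * dx, c0), 0, tolerance = 1e-12)
  expect_equal(one_minus_pcc(x, c0 - dx, c0), 2, tolerance = 1e-12)
  expect_warning(expect_true(is.na(one_minus_pcc(x, c0, c0))), "undefined")
})

test_that("both metrics are invariant to joint rescaling", {
  x <- with_seed2(41, rnorm(20)); xhat <- with_seed2(42, rnorm(20))
  c0 <- with_seed2(43, rnorm(20))
  for (s in c(0.01, 7)) {
    expect_equal(normalized_mse(s * x, s * xhat, s * c0),
                 normalized_mse(x, xhat, c0), tolerance = 1e-12)
    expect_equal(one_minus_pcc(s * x, s * xhat, s * c0),
                 one_minus_pcc(x, xhat, c0), tolerance = 1e-12)
  }
})

test_that("evaluate stratifies by subgroup and aggregates medians with bootstrap CIs", {
  sim <- tiny_sim(seed = 8, n_genes = 25, n_perts = 6, n_cells = 10,
                  n_controls = 40, dim = 6, n_double = 3)
  ds <- sim$dataset
  perts <- perturbations(ds)
  singles <- perts[!grepl("\\+", perts)]
  doubles <- perts[grepl("\\+", perts)]
  train_perts <- singles[1:3]
  eval_perts <- c(singles[4:6], doubles)
  preds <- baseline_predictions(ds, eval_perts)
  # baseline 1 - PCC is undefined (zero predicted change); expected warnings
  rep <- suppressWarnings(evaluate(ds, preds, train_perts, top_k = 10,
                                   n_bootstrap = 50, seed = 2))
  per <- rep$per_perturbation
  expect_identical(sort(per$perturbation), sort(eval_perts))
  expect_true(all(per$normalized_mse == 1))
  expect_true(all(per$subgroup[per$perturbation %in% singles[4:6]] == "single"))
  expect_true(all(per$subgroup %in% c("single", "seen0", "seen1", "seen2")))
  overall <- rep$aggregates[rep$aggregates$subgroup == "overall", ]
  expect_identical(overall$median_mse, 1)
  expect_identical(c(overall$mse_ci_lo, overall$mse_ci_hi), c(1, 1))
  # subgroup rows partition the perturbations
  sub_n <- rep$aggregates$n[rep$aggregates$subgroup != "overall"]
  expect_identical(sum(sub_n), nrow(per))
})

test_that("a perfect predictor scores 0 on both metrics", {
  sim <- tiny_sim(seed = 12, n_genes = 20, n_perts = 4, n_cells = 15,
                  n_controls = 30, dim = 4)
  ds <- sim$dataset
  perts <- perturbations(ds)
  ctrl_mean <- colMeans(ds$expression[ds$is_control, , drop = FALSE])
  preds <- lapply(perts, function(p) {
    mp <- colMeans(ds$expression[ds$labels == p, , drop = FALSE])
    structure(list(perturbation = p, per_control = matrix(mp, 1),
                   mean_profile = mp, K = 1L, control_indices = integer()),
              class = "prediction_result")
  })
  names(preds) <- perts
  rep <- evaluate(ds, preds, perts[1:2], n_bootstrap = 50, seed = 1)
  expect_true(all(abs(rep$per_perturbation$normalized_mse) < 1e-20))
  expect_true(all(abs(rep$per_perturbation$one_minus_pcc) < 1e-12))
})

test_that("bootstrap CI of the median matches a naive resampling loop", {
  vals <- c(0.3, 0.5, 0.8, 1.1, 0.2)
  got <- scouter:::bootstrap_median_ci(vals, n_bootstrap = 400, seed = 77)
  # independent loop replaying the same RNG stream
  naive <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(77)
    m <- numeric(400)
    for (i in 1:400) m[i] <- median(vals[sample.int(5, 5, replace = TRUE)])
    quantile(m, c(0.25, 0.75), names = FALSE)
  })
  expect_equal(got, naive, tolerance = 1e-12)
  # single-perturbation report degenerates to its own metric
  expect_identical(scouter:::bootstrap_median_ci(0.4, 100, 1), c(0.4, 0.4))
})

test_that("report files are written for per-perturbation and aggregate results", {
  sim <- tiny_sim(seed = 14, n_genes = 15, n_perts = 4, n_cells = 5, n_controls = 20, dim = 4)
  ds <- sim$dataset
  perts <- perturbations(ds)
  rep <- suppressWarnings(evaluate(ds, baseline_predictions(ds, perts[3:4]),
                                   perts[1:2], n_bootstrap = 20, seed = 1))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_report(rep, csv, js)
  expect_identical(nrow(utils::read.csv(csv)), 2L)
  expect_identical(jsonlite::read_json(js)$top_k, 20L)
})
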