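# Top-DEG metrics: most genes do not respond to a given perturbation, so
# accuracy is scored over the top differentially expressed genes only. The
# normalized MSE divides by the no-change baseline's MSE, anchoring 1.0 as
# "no better than predicting the control profile"; 1 - PCC of the change
# vectors scores direction/shape agreement (0 perfect, 2 anti-correlated).

#' Top differentially expressed genes for a perturbation
#'
#' Default ranking: absolute difference between the mean expression in the
#' perturbation's cells and the mean control expression, descending, ties
#' broken by gene index ascending. A precomputed gene list (e.g. shipped with
#' a preprocessed dataset) may be supplied instead and takes precedence.
#'
#' @param dataset A `perturb_dataset`.
#' @param perturbation Canonical perturbation string.
#' @param top_k Number of genes (default 20).
#' @param provided Optional integer vector of gene indices to use verbatim.
#' @return List with `perturbation`, `genes` (indices, length `top_k`),
#'   `source` (`"computed"` or `"provided"`).
#' @export
top_degs <- function(dataset, perturbation, top_k = 20, provided = NULL) {
  if (!is.null(provided)) {
    provided <- as.integer(provided)
    if (anyDuplicated(provided) || any(provided < 1 | provided > length(dataset$gene_names)))
      stopf("provided DEG indices must be unique and within 1..%d", length(dataset$gene_names))
    return(list(perturbation = perturbation, genes = provided[seq_len(min(top_k, length(provided)))],
                source = "provided"))
  }
  sel <- dataset$labels == perturbation
  if (!any(sel)) stopf("perturbation %s absent from dataset", dQuote(perturbation))
  delta <- colMeans(dataset$expression[sel, , drop = FALSE]) -
    colMeans(dataset$expression[dataset$is_control, , drop = FALSE])
  ord <- order(-abs(delta), seq_along(delta))
  list(perturbation = perturbation, genes = ord[seq_len(min(top_k, length(delta)))],
       source = "computed")
}

#' Normalized mean squared error over a DEG set
#'
#' `MSE(x, xhat) / MSE(x, c)`: prediction error relative to the no-change
#' baseline that predicts the control profile. Exactly 1 when `xhat == c`,
#' 0 for a perfect prediction.
#'
#' @param x True (mean) perturbed expression over the DEGs.
#' @param xhat Predicted expression over the DEGs.
#' @param c Control (mean) expression over the DEGs.
#' @return Scalar >= 0, or `NA` with a warning when the baseline MSE is zero
#'   (no DEG truly changed; the metric is undefined).
#' @export
normalized_mse <- function(x, xhat, c) {
  denom <- mean((x - c)^2)
  if (denom == 0) {
    warnf("normalized MSE undefined: no expression change over the DEG set")
    return(NA_real_)
  }
  mean((x - xhat)^2) / denom
}

#' One minus the normalized Pearson correlation
#'
#' `1 - PCC(x - c, xhat - c)` over the DEG set: 0 when the predicted change is
#' perfectly proportional to the true change, 2 when anti-correlated.
#'
#' @inheritParams normalized_mse
#' @return Scalar in `[0, 2]`, or `NA` with a warning when either change
#'   vector has zero variance.
#' @export
one_minus_pcc <- function(x, xhat, c) {
  dx <- x - c; dh <- xhat - c
  if (stats::sd(dx) == 0 || stats::sd(dh) == 0) {
    warnf("1 - PCC undefined: a change vector has zero variance over the DEG set")
    return(NA_real_)
  }
  1 - stats::cor(dx, dh)
}

bootstrap_median_ci <- function(values, n_bootstrap, seed, probs = c(0.25, 0.75)) {
  values <- values[!is.na(values)]
  if (!length(values)) return(c(NA_real_, NA_real_))
  meds <- with_seed(seed, vapply(seq_len(n_bootstrap), function(i)
    stats::median(values[sample.int(length(values), length(values), replace = TRUE)]),
    numeric(1)))
  stats::quantile(meds, probs, names = FALSE)
}

#' Score predictions against held-out cells
#'
#' For every prediction, compares the mean observed profile of the
#' perturbation's held-out cells with the prediction's mean profile and the
#' mean control profile over that perturbation's top-`top_k` DEGs, computing
#' the normalized MSE and 1 - PCC. Perturbations are stratified by subgroup
#' relative to `train_perts` (single / seen0 / seen1 / seen2); aggregates are
#' medians with 50% bootstrap confidence intervals (25th-75th percentile of
#' the bootstrap distribution of the median across perturbations).
#'
#' Perturbations whose metric is undefined (zero baseline MSE or zero change
#' variance) are kept in the per-perturbation table with `NA` metrics and
#' excluded from the aggregates.
#'
#' @param dataset A `perturb_dataset` holding the observed (held-out) cells.
#' @param predictions List of `prediction_result` objects (see [predict_all()]).
#' @param train_perts Canonical perturbations of the training set, for
#'   subgroup assignment.
#' @param top_k DEG-set size (default 20).
#' @param n_bootstrap Bootstrap resamples for the CIs (default 1000).
#' @param seed Bootstrap seed.
#' @param deg_sets Optional named list of precomputed DEG index vectors.
#' @return An `eval_report`: `per_perturbation` data frame and `aggregates`
#'   data frame (one row per subgroup plus `"overall"`).
#' @export
evaluate <- function(dataset, predictions, train_perts, top_k = 20,
                     n_bootstrap = 1000, seed = 1, deg_sets = NULL) {
  if (!length(predictions)) stopf("empty prediction list")
  ctrl_mean <- colMeans(dataset$expression[dataset$is_control, , drop = FALSE])
  rows <- lapply(predictions, function(pred) {
    p <- pred$perturbation
    sel <- dataset$labels == p
    if (!any(sel)) stopf("no held-out cells for predicted perturbation %s", dQuote(p))
    degs <- top_degs(dataset, p, top_k, provided = deg_sets[[p]])$genes
    x <- colMeans(dataset$expression[sel, , drop = FALSE])[degs]
    xhat <- pred$mean_profile[degs]
    cc <- ctrl_mean[degs]
    data.frame(perturbation = p,
               subgroup = assign_subgroup(parse_label(p), train_perts),
               normalized_mse = normalized_mse(x, xhat, cc),
               one_minus_pcc = one_minus_pcc(x, xhat, cc))
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  groups <- c(sort(unique(per$subgroup)), "overall")
  agg <- do.call(rbind, lapply(groups, function(gname) {
    sub <- if (gname == "overall") per else per[per$subgroup == gname, ]
    ci_mse <- bootstrap_median_ci(sub$normalized_mse, n_bootstrap, derive_seed(seed, string_stream(gname)))
    ci_pcc <- bootstrap_median_ci(sub$one_minus_pcc, n_bootstrap, derive_seed(seed, string_stream(gname) + 1))
    data.frame(subgroup = gname, n = sum(!is.na(sub$normalized_mse)),
               median_mse = stats::median(sub$normalized_mse, na.rm = TRUE),
               mse_ci_lo = ci_mse[1], mse_ci_hi = ci_mse[2],
               median_one_minus_pcc = stats::median(sub$one_minus_pcc, na.rm = TRUE),
               pcc_ci_lo = ci_pcc[1], pcc_ci_hi = ci_pcc[2])
  }))
  rownames(agg) <- NULL
  structure(list(per_perturbation = per, aggregates = agg, top_k = top_k,
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d perturbations, top-%d DEGs\n",
              nrow(x$per_perturbation), x$top_k))
  print(x$aggregates, row.names = FALSE)
  invisible(x)
}

#' No-change baseline predictions
#'
#' Builds `prediction_result`-shaped objects whose mean profile is the mean
#' control profile, i.e. the predictor that says nothing changes. Its
#' normalized MSE is exactly 1 on every perturbation, anchoring the scale.
#'
#' @param dataset A `perturb_dataset`.
#' @param perturbations Canonical perturbation strings.
#' @return Named list of baseline `prediction_result` objects.
#' @export
baseline_predictions <- function(dataset, perturbations) {
  ctrl_mean <- colMeans(dataset$expression[dataset$is_control, , drop = FALSE])
  stats::setNames(lapply(perturbations, function(p) {
    structure(list(perturbation = p, per_control = matrix(ctrl_mean, 1),
                   mean_profile = ctrl_mean, K = 1L, control_indices = integer()),
              class = "prediction_result")
  }), perturbations)
}

#' Write an evaluation report to disk
#'
#' Per-perturbation rows as CSV; aggregates as JSON.
#'
#' @param report An `eval_report`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(report$per_perturbation, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(aggregates = report$aggregates, top_k = report$top_k,
                              n_bootstrap = report$n_bootstrap, seed = report$seed),
                         json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
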