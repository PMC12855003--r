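#' Predict the transcriptional response to a perturbation
#'
#' Samples `K` control cells uniformly with replacement (K = 300 by default),
#' runs each through the network in eval mode conditioned on the perturbation
#' embedding (the elementwise sum of the two gene embeddings for a two-gene
#' perturbation), and returns all K predicted profiles plus their mean as the
#' point estimate. The perturbation need not occur in the dataset: this is the
#' unseen-perturbation path.
#'
#' @param model A trained `scouter_model`.
#' @param dataset A `perturb_dataset` supplying the control-cell pool.
#' @param perturbation Canonical perturbation string or parsed target vector.
#' @param embeddings An [embedding_table()] covering the targets.
#' @param K Number of control cells to sample (default from the model config).
#' @param seed Integer seed for the control sample.
#' @return A `prediction_result`: `perturbation`, `per_control` (K x genes),
#'   `mean_profile`, `K`, `control_indices`.
#' @export
predict_perturbation <- function(model, dataset, perturbation, embeddings,
                                 K = NULL, seed = 1) {
  K <- as.integer(K %||% model$config$K_predict)
  if (K < 1) stopf("K must be >= 1")
  targets <- if (is.character(perturbation) && length(perturbation) == 1)
    parse_label(perturbation) else as.character(perturbation)
  if (!length(targets)) stopf("cannot predict the control condition")
  emb <- embed_perturbation(embeddings, targets)
  controls <- which(dataset$is_control)
  if (!length(controls)) stopf("no control cells in dataset")
  idx <- with_seed(seed, controls[sample.int(length(controls), K, replace = TRUE)])
  ctrl <- dataset$expression[idx, , drop = FALSE]
  per_control <- forward(model, ctrl, emb, mode = "eval")
  structure(list(perturbation = canonical_label(targets),
                 per_control = per_control,
                 mean_profile = colMeans(per_control),
                 K = K, control_indices = idx),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: %s; K = %d controls; %d genes\n",
              x$perturbation, x$K, length(x$mean_profile)))
  invisible(x)
}

#' Predict responses for a list of perturbations
#'
#' Each perturbation gets its own seed derived from the master seed and its
#' canonical name, so results are independent of list order.
#'
#' @inheritParams predict_perturbation
#' @param perturbations Character vector of canonical perturbation strings.
#' @return Named list of `prediction_result` objects.
#' @export
predict_all <- function(model, dataset, perturbations, embeddings, K = NULL, seed = 1) {
  out <- list(); failures <- character()
  for (p in perturbations) {
    canon <- canonical_label(parse_label(p))
    res <- tryCatch(
      predict_perturbation(model, dataset, canon, embeddings, K = K,
                           seed = derive_seed(seed, string_stream(canon))),
      error = function(e) e)
    if (inherits(res, "error")) failures <- c(failures, sprintf("%s (%s)", canon, conditionMessage(res)))
    else out[[canon]] <- res
  }
  if (length(failures))
    warnf("%d perturbation(s) failed: %s", length(failures), paste(failures, collapse = "; "))
  out
}

#' Write prediction mean profiles to CSV
#'
#' One row per perturbation, genes as columns.
#'
#' @param predictions List of `prediction_result` objects.
#' @param path Output CSV path.
#' @param gene_names Optional column names.
#' @export
write_predictions <- function(predictions, path, gene_names = NULL) {
  mat <- do.call(rbind, lapply(predictions, `[[`, "mean_profile"))
  df <- data.frame(perturbation = vapply(predictions, `[[`, character(1), "perturbation"),
                   mat, check.names = FALSE)
  if (!is.null(gene_names)) colnames(df) <- c("perturbation", gene_names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
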