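#' Construct a gene embedding table
#'
#' Fixed-length numeric vectors, one per gene symbol, produced upstream by a
#' language model from gene text descriptions (1,536-long vectors in the
#' published tables). The table conditions the generator network and is frozen:
#' it is never modified by training.
#'
#' @param matrix Numeric matrix, genes in rows, embedding dimensions in
#'   columns; rownames are gene symbols.
#' @return An `embedding_table` with elements `matrix`, `dim`, `symbols`.
#' @export
embedding_table <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix))) stopf("embedding matrix needs gene symbols as rownames")
  if (!is.numeric(matrix) || any(!is.finite(matrix)))
    stopf("embeddings must be finite numeric values")
  dup <- unique(rownames(matrix)[duplicated(rownames(matrix))])
  if (length(dup)) stopf("duplicate gene symbols in embeddings: %s", paste(dup, collapse = ", "))
  structure(list(matrix = matrix, dim = ncol(matrix), symbols = rownames(matrix)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d genes x dim %d\n", length(x$symbols), x$dim))
  invisible(x)
}

#' Load gene embeddings from CSV
#'
#' Expected layout: first column the gene symbol, remaining columns the
#' numeric embedding entries (header `gene,e1,...,edim` or similar). The
#' embedding dimension is inferred from the data.
#'
#' @param path CSV file path.
#' @return An [embedding_table()].
#' @export
load_embeddings <- function(path) {
  if (grepl("\\.npz$", path, ignore.case = TRUE))
    stopf("NPZ embeddings are not supported here; export to CSV (gene,e1,...,edim)")
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stopf("embedding CSV needs a symbol column plus >= 1 numeric column")
  symbols <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric embedding entries in %s", path)
  rownames(mat) <- symbols
  embedding_table(mat)
}

#' Write an embedding table to CSV
#' @param table An `embedding_table`.
#' @param path Output CSV path.
#' @export
write_embeddings <- function(table, path) {
  df <- data.frame(gene = table$symbols, table$matrix, check.names = FALSE)
  colnames(df) <- c("gene", paste0("e", seq_len(table$dim)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Embedding vector for a perturbation
#'
#' One target gene maps to its embedding; a two-gene perturbation maps to the
#' elementwise sum of the two gene embeddings, so the composition is symmetric
#' and linear in the single-gene embeddings.
#'
#' @param table An `embedding_table`.
#' @param targets Parsed target vector (length 1 or 2), or a raw label string.
#' @param case_insensitive Fall back to case-insensitive symbol matching.
#' @return Numeric vector of length `table$dim`.
#' @export
embed_perturbation <- function(table, targets, case_insensitive = FALSE) {
  if (is.character(targets) && length(targets) == 1 && grepl("\\+|^ctrl$", targets))
    targets <- parse_label(targets)
  if (length(targets) < 1) stopf("cannot embed the control condition")
  idx <- match(targets, table$symbols)
  if (case_insensitive && anyNA(idx))
    idx[is.na(idx)] <- match(tolower(targets[is.na(idx)]), tolower(table$symbols))
  if (anyNA(idx))
    stopf("missing embedding: %s", paste(targets[is.na(idx)], collapse = ", "))
  if (length(idx) == 1) return(as.numeric(table$matrix[idx, ]))
  as.numeric(table$matrix[idx[1], ] + table$matrix[idx[2], ])
}

#' Check embedding coverage of a dataset's perturbations
#'
#' @param table An `embedding_table`.
#' @param dataset A `perturb_dataset`.
#' @return Data frame with columns `perturbation`, `covered`, `missing` (comma
#'   separated absent symbols, `""` when covered).
#' @export
coverage_report <- function(table, dataset) {
  perts <- perturbations(dataset)
  rows <- lapply(perts, function(p) {
    targets <- parse_label(p)
    absent <- targets[!targets %in% table$symbols]
    data.frame(perturbation = p, covered = length(absent) == 0,
               missing = paste(absent, collapse = ","))
  })
  if (!length(rows))
    return(data.frame(perturbation = character(), covered = logical(), missing = character()))
  do.call(rbind, rows)
}

# Stable content checksum used by the frozen-embedding tests.
embedding_checksum <- function(table) {
  v <- as.numeric(table$matrix)
  sum(v * seq_along(v) %% 97) + sum(utf8ToInt(paste(table$symbols, collapse = "|")))
}
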