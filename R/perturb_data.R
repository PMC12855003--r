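#' Parse a perturbation label into its target genes
#'
#' Perturb-seq datasets label each cell with the perturbation it received:
#' `"ctrl"` for unperturbed control cells, a single gene symbol (optionally
#' written `"GENE+ctrl"` or `"ctrl+GENE"`), or two symbols joined by `"+"` for
#' a two-gene perturbation. The two single-gene spellings both occur in
#' published datasets and are accepted interchangeably.
#'
#' @param raw A single non-empty label string.
#' @return Character vector of 0, 1 or 2 target gene symbols, sorted
#'   lexicographically for pairs. Length 0 means control.
#' @examples
#' parse_label("ctrl")          # character(0)
#' parse_label("CDKN1A+ctrl")   # "CDKN1A"
#' parse_label("B+A")           # c("A", "B")
#' @export
parse_label <- function(raw) {
  if (!is.character(raw) || length(raw) != 1 || is.na(raw) || !nzchar(raw))
    stopf("label must be a single non-empty string")
  parts <- strsplit(raw, "+", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (any(!nzchar(parts))) stopf("malformed label %s: empty component", dQuote(raw))
  targets <- parts[parts != "ctrl"]
  if (length(targets) > 2)
    stopf("label %s has %d targets; at most two genes may be perturbed",
          dQuote(raw), length(targets))
  if (length(targets) == 2) {
    if (targets[1] == targets[2])
      stopf("label %s repeats the same gene twice", dQuote(raw))
    targets <- sort(targets)
  }
  targets
}

#' Canonical string form of a perturbation
#'
#' @param targets Character vector of 0, 1 or 2 gene symbols (as returned by
#'   [parse_label()]).
#' @return `"ctrl"`, `"GENE"`, or `"G1+G2"` with the pair sorted, so that
#'   `"A+B"` and `"B+A"` share one canonical form.
#' @export
canonical_label <- function(targets) {
  if (length(targets) == 0) return("ctrl")
  paste(sort(targets), collapse = "+")
}

#' Construct a labeled perturbation expression dataset
#'
#' The core data container: a cells x genes matrix of log-normalized
#' expression with one perturbation label per cell. Labels are canonicalized
#' at construction.
#'
#' @param expression Numeric matrix, cells in rows, genes in columns. No
#'   missing values.
#' @param gene_names Character vector of unique gene symbols, one per column.
#' @param labels Character vector of raw per-cell labels (see [parse_label()]).
#' @return An object of class `perturb_dataset` with elements `expression`,
#'   `gene_names`, `labels` (canonical strings), `targets` (list of parsed
#'   target vectors), `is_control` (logical), `n`, `n0`.
#' @export
perturb_dataset <- function(expression, gene_names, labels) {
  expression <- as.matrix(expression)
  if (!is.numeric(expression) || anyNA(expression) || any(!is.finite(expression)))
    stopf("expression must be a numeric matrix with no missing or non-finite values")
  if (length(gene_names) != ncol(expression))
    stopf("gene_names length (%d) != number of genes (%d)",
          length(gene_names), ncol(expression))
  gene_names <- as.character(gene_names)
  if (anyDuplicated(gene_names))
    stopf("duplicate gene names: %s",
          paste(unique(gene_names[duplicated(gene_names)]), collapse = ", "))
  if (length(labels) != nrow(expression))
    stopf("labels length (%d) != number of cells (%d)",
          length(labels), nrow(expression))
  targets <- lapply(as.character(labels), parse_label)
  canon <- vapply(targets, canonical_label, character(1))
  is_control <- canon == "ctrl"
  n0 <- sum(is_control)
  if (n0 < 1) stopf("no control cells")
  if (n0 == length(canon)) stopf("no perturbed cells")
  looks_raw <- max(expression) > 50 && all(expression == round(expression))
  if (looks_raw)
    warnf("expression looks like raw counts (integer-valued, max > 50); expected log-normalized values")
  dimnames(expression) <- list(NULL, gene_names)
  structure(
    list(expression = expression, gene_names = gene_names, labels = canon,
         targets = targets, is_control = is_control,
         n = nrow(expression), n0 = n0),
    class = "perturb_dataset")
}

#' @export
print.perturb_dataset <- function(x, ...) {
  cat(sprintf("perturb_dataset: %d cells x %d genes; %d control cells; %d perturbations\n",
              x$n, length(x$gene_names), x$n0, length(perturbations(x))))
  invisible(x)
}

#' Unique non-control perturbations of a dataset
#'
#' @param dataset A `perturb_dataset`.
#' @return Sorted character vector of canonical perturbation strings.
#' @export
perturbations <- function(dataset) {
  sort(unique(dataset$labels[!dataset$is_control]))
}

#' Write a dataset to disk as plain-text files
#'
#' Writes `matrix.mtx` (sparse MatrixMarket) or `expression.csv` (dense, genes
#' as header) plus sidecars `genes.tsv` and `labels.tsv`, one entry per line.
#'
#' @param dataset A `perturb_dataset`.
#' @param dir Output directory (created if needed).
#' @param format `"mtx"` (default) or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(dataset$expression, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
  } else {
    utils::write.csv(as.data.frame(dataset$expression),
                     file.path(dir, "expression.csv"), row.names = FALSE)
  }
  writeLines(dataset$gene_names, file.path(dir, "genes.tsv"))
  writeLines(dataset$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Load a labeled perturbation dataset from disk
#'
#' Accepts a directory produced by [write_dataset()] (or laid out the same
#' way): `matrix.mtx` or `expression.csv`, with `genes.tsv` and `labels.tsv`
#' sidecars. H5AD containers are not readable in this installation (no R HDF5
#' bindings); export such data to MTX/CSV plus sidecars first, e.g. with
#' Python's anndata.
#'
#' @param path Directory containing the matrix and sidecar files, or the path
#'   of the matrix file itself.
#' @param label_key Name of the per-cell label column in an H5AD file; unused
#'   for sidecar layouts (labels come from `labels.tsv`). Kept for interface
#'   stability.
#' @return A validated [perturb_dataset()].
#' @export
load_dataset <- function(path, label_key = "condition") {
  if (grepl("\\.h5ad$", path, ignore.case = TRUE))
    stopf("H5AD input is not supported here (no R HDF5 reader installed); convert %s to MTX/CSV + genes.tsv/labels.tsv sidecars", path)
  if (dir.exists(path)) {
    dir <- path
    mat_file <- if (file.exists(file.path(dir, "matrix.mtx"))) file.path(dir, "matrix.mtx")
                else if (file.exists(file.path(dir, "expression.csv"))) file.path(dir, "expression.csv")
                else stopf("no matrix.mtx or expression.csv found in %s", dir)
  } else {
    if (!file.exists(path)) stopf("cannot read %s", path)
    mat_file <- path
    dir <- dirname(path)
  }
  genes_file <- file.path(dir, "genes.tsv")
  labels_file <- file.path(dir, "labels.tsv")
  if (!file.exists(labels_file)) stopf("missing sidecar %s", labels_file)
  if (grepl("\\.mtx$", mat_file)) {
    expr <- as.matrix(Matrix::readMM(mat_file))
    if (!file.exists(genes_file)) stopf("missing sidecar %s", genes_file)
    genes <- readLines(genes_file)
  } else {
    df <- utils::read.csv(mat_file, check.names = FALSE)
    expr <- as.matrix(df)
    genes <- if (file.exists(genes_file)) readLines(genes_file) else colnames(df)
  }
  labels <- readLines(labels_file)
  perturb_dataset(expr, genes, labels)
}

#' Perturbation-level train/validation/test splits
#'
#' Splits are over perturbations, never over cells: all cells of a
#' perturbation travel together, so test-set responses are genuinely unseen
#' during training. Control cells belong to no split and are available to
#' every phase.
#'
#' Two schemes are provided. `test20_val10` sets aside 20% of perturbations
#' for testing and splits the remaining 80% into 90% training / 10%
#' validation. `dixit_801010` uses an 80:10:10 ratio, suited to datasets with
#' few perturbations. Sizes are rounded with floor for test, ceiling for
#' validation, remainder to train, with every set kept non-empty.
#'
#' @param dataset A `perturb_dataset`.
#' @param scheme `"test20_val10"` or `"dixit_801010"`.
#' @param n_splits Number of independent split plans.
#' @param seed Integer seed; plans are deterministic given the seed.
#' @return List of `n_splits` plans, each a list with `scheme`, `seed`,
#'   `train`, `val`, `test` (character vectors of canonical perturbations).
#' @export
make_splits <- function(dataset, scheme = c("test20_val10", "dixit_801010"),
                        n_splits = 1, seed = 1) {
  scheme <- match.arg(scheme)
  perts <- perturbations(dataset)
  P <- length(perts)
  if (P < 3) stopf("need at least 3 non-control perturbations to split, got %d", P)
  sizes <- split_sizes(P, scheme)
  lapply(seq_len(n_splits), function(i) {
    perm <- with_seed(derive_seed(seed, i), sample(perts))
    test <- perm[seq_len(sizes$test)]
    val <- perm[sizes$test + seq_len(sizes$val)]
    train <- perm[-seq_len(sizes$test + sizes$val)]
    list(scheme = scheme, seed = seed, split_index = i,
         train = sort(train), val = sort(val), test = sort(test))
  })
}

split_sizes <- function(P, scheme) {
  if (scheme == "test20_val10") {
    n_test <- max(1L, floor(0.2 * P))
    n_val <- max(1L, ceiling(0.1 * (P - n_test)))
  } else {
    n_test <- max(1L, floor(0.1 * P))
    n_val <- max(1L, ceiling(0.1 * P))
  }
  n_train <- P - n_test - n_val
  if (n_train < 1) stopf("too few perturbations (%d) to populate train/val/test", P)
  list(train = n_train, val = n_val, test = n_test)
}

#' Write / read a split plan as JSON
#' @param plan A split plan from [make_splits()].
#' @param path JSON file path.
#' @return `path` (write) or the plan (read).
#' @export
write_split <- function(plan, path) {
  jsonlite::write_json(plan, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  plan <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("train", "val", "test")) plan[[k]] <- as.character(plan[[k]])
  plan
}

#' Classify a test perturbation relative to a training set
#'
#' Single-gene perturbations are labeled `"single"`. Two-gene perturbations
#' are labeled by how many of the pair's genes were perturbed (alone or in
#' any combination) in training: `"seen2"` (both, though never together),
#' `"seen1"`, or `"seen0"`.
#'
#' @param targets Parsed target vector (length 1 or 2).
#' @param train_perts Character vector of canonical training perturbations.
#' @return One of `"single"`, `"seen0"`, `"seen1"`, `"seen2"`.
#' @export
assign_subgroup <- function(targets, train_perts) {
  if (length(targets) == 0) stopf("subgroups are defined for non-control perturbations only")
  if (length(targets) == 1) return("single")
  train_genes <- unique(unlist(lapply(train_perts, parse_label)))
  k <- sum(targets %in% train_genes)
  c("seen0", "seen1", "seen2")[k + 1]
}
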