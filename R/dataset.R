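#' Dataset conventions
#'
#' Throughout the package a labelled expression dataset is an ordinary tibble
#' (or data frame) holding one row per sample:
#'
#' * `sample_id` — unique sample identifier (character);
#' * `label`     — class label (character or factor), required by supervised
#'   operations;
#' * every remaining column — one gene, numeric and non-negative on the raw
#'   count/intensity scale.
#'
#' These helpers extract the pieces and enforce the invariants (no negative
#' entries, no missing or non-finite values, duplicate-free identifiers).
#'
#' @param data A dataset tibble as described above.
#' @param require_label Error when no `label` column is present.
#'
#' @return `expr_matrix()` returns the numeric samples-by-genes matrix with
#'   `sample_id` rownames; `gene_names()` the gene column names;
#'   `dataset_labels()` the label vector (factor).
#' @examples
#' ds <- generate_dataset(n_per_class = c(5, 5), d = 20, n_informative = 2,
#'                        seed = 1)$data
#' dim(expr_matrix(ds))
#' head(gene_names(ds))
#' @name dataset-helpers
NULL

meta_cols <- function(data) intersect(c("sample_id", "label"), names(data))

#' @rdname dataset-helpers
#' @export
gene_names <- function(data) setdiff(names(data), c("sample_id", "label"))

#' @rdname dataset-helpers
#' @export
expr_matrix <- function(data) {
  genes <- gene_names(data)
  if (length(genes) == 0L) abort("dataset has no gene columns")
  x <- as.matrix(as.data.frame(data)[, genes, drop = FALSE])
  if (!is.numeric(x)) abort("gene columns must be numeric")
  storage.mode(x) <- "double"
  if ("sample_id" %in% names(data)) rownames(x) <- as.character(data$sample_id)
  x
}

#' @rdname dataset-helpers
#' @export
dataset_labels <- function(data, require_label = TRUE) {
  if (!"label" %in% names(data)) {
    if (require_label) abort("dataset has no `label` column")
    return(NULL)
  }
  y <- data$label
  if (is.factor(y)) factor(y) else factor(y, levels = unique(y))
}

# Validate the full dataset contract; returns the data invisibly.
# Non-negativity is the raw-scale (IO) contract; supervised operations on
# transformed scales (log, standardised, PCA scores) relax it.
validate_dataset <- function(data, require_label = FALSE,
                             allow_negative = FALSE) {
  if (!is.data.frame(data)) abort("dataset must be a data frame")
  x <- expr_matrix(data)
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("non-finite expression value at sample %s, gene %s",
                  rownames(x)[bad[1, 1]] %||% bad[1, 1],
                  colnames(x)[bad[1, 2]]))
  }
  neg <- if (allow_negative) matrix(nrow = 0, ncol = 2) else
    which(x < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    abort(sprintf(
      "expression values must be non-negative; found %g at sample %s, gene %s",
      x[neg[1, 1], neg[1, 2]],
      rownames(x)[neg[1, 1]] %||% neg[1, 1], colnames(x)[neg[1, 2]]))
  }
  if ("sample_id" %in% names(data) && anyDuplicated(data$sample_id)) {
    abort(sprintf("duplicate sample_id: %s",
                  data$sample_id[duplicated(data$sample_id)][1]))
  }
  if (anyDuplicated(gene_names(data))) {
    abort(sprintf("duplicate gene id: %s",
                  gene_names(data)[duplicated(gene_names(data))][1]))
  }
  if (require_label) {
    y <- dataset_labels(data)
    if (nlevels(y) < 2L) abort("supervised operations need at least 2 classes")
  }
  invisible(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeded evaluation that never disturbs the caller's RNG state.
with_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)
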