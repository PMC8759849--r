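#' Log2 transform of expression counts
#'
#' Applies the elementwise transform `x = log2(y + 1)` to every gene column.
#' The transform is monotone and zero-preserving, and compresses the dynamic
#' range of read counts / intensities ahead of filtering and PCA.
#'
#' @param data Dataset tibble (raw non-negative scale).
#' @return The dataset with gene columns log2(y+1)-transformed.
#' @examples
#' ds <- tibble::tibble(sample_id = "s1", g1 = 0, g2 = 1, g3 = 3)
#' log_transform(ds)  # 0, 1, 2
#' @export
log_transform <- function(data) {
  validate_dataset(data)
  genes <- gene_names(data)
  dplyr::mutate(data, across(all_of(genes), ~ log2(.x + 1)))
}

#' Low-expression gene filter
#'
#' Removes genes whose summary statistic across all samples does not exceed
#' `threshold`. Intended to run on log2-transformed values, where the default
#' threshold 1.19 drops genes expressed near the noise floor. A gene is kept
#' iff `statistic(gene) > threshold`; surviving gene order is preserved.
#'
#' @param data Dataset tibble (log scale).
#' @param threshold Non-negative filter threshold (default 1.19, log2 units).
#' @param statistic Per-gene summary: `"mean"` (default) or `"max"`.
#' @return A list: `data` (filtered dataset) and `removed` (character vector
#'   of removed gene ids).
#' @export
filter_genes <- function(data, threshold = 1.19,
                         statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(threshold >= 0)
  x <- expr_matrix(data)
  stat <- if (statistic == "mean") colMeans(x) else apply(x, 2, max)
  keep <- stat > threshold
  if (!any(keep)) {
    abort(sprintf(
      "all %d genes fall at or below threshold %g; lower the threshold",
      ncol(x), threshold))
  }
  removed <- colnames(x)[!keep]
  list(data = data[, c(meta_cols(data), colnames(x)[keep]), drop = FALSE],
       removed = removed)
}

#' PCA dimensionality reduction
#'
#' Centers (and by default unit-variance scales) the gene columns and
#' projects onto the leading principal components. The requested number of
#' components is capped at `min(m - 1, d)`. Per-component sign is fixed by
#' making the largest-magnitude loading positive, so results do not depend on
#' the eigen-solver's sign convention.
#'
#' @param data Dataset tibble (typically log-transformed and filtered).
#' @param n_components Number of components to keep (default 133).
#' @param standardize Scale genes to unit variance before PCA (default TRUE).
#' @return A list: `scores` (tibble with metadata columns and `PC1..PCk`) and
#'   `model` (a `pca_model` with `rotation`, `center`, `scale`,
#'   `explained_variance` — the leading covariance eigenvalues, descending).
#' @export
pca_reduce <- function(data, n_components = 133, standardize = TRUE) {
  stopifnot(n_components >= 1)
  x <- expr_matrix(data)
  if (nrow(x) < 2L) abort("PCA needs at least 2 samples")
  v <- apply(x, 2, stats::var)
  if (all(v < .Machine$double.eps)) abort("matrix is constant: zero variance")
  if (standardize && any(v < .Machine$double.eps)) {
    abort(sprintf(
      "gene %s has zero variance; filter constant genes before standardized PCA",
      colnames(x)[which(v < .Machine$double.eps)[1]]))
  }
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize, rank. = k)
  rot <- fix_signs(pc$rotation[, seq_len(k), drop = FALSE])
  ctr <- pc$center
  scl <- if (standardize) pc$scale else rep(1, ncol(x))
  scores <- scale(x, center = ctr, scale = scl) %*% rot
  colnames(scores) <- paste0("PC", seq_len(k))
  model <- structure(
    list(rotation = rot, center = ctr, scale = scl,
         explained_variance = pc$sdev[seq_len(k)]^2,
         all_variances = pc$sdev^2, standardize = standardize),
    class = "pca_model")
  out <- bind_cols(data[, meta_cols(data), drop = FALSE],
                   as_tibble(scores, .name_repair = "minimal"))
  list(scores = out, model = model)
}

# Flip each column so its largest-|.| entry is positive (stable tie: first).
fix_signs <- function(rotation) {
  for (j in seq_len(ncol(rotation))) {
    i <- which.max(abs(rotation[, j]))
    if (rotation[i, j] < 0) rotation[, j] <- -rotation[, j]
  }
  rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d genes -> %d components%s\n",
              nrow(x$rotation), ncol(x$rotation),
              if (x$standardize) " (standardized)" else ""))
  pct <- 100 * sum(x$explained_variance) / sum(x$all_variances)
  cat(sprintf("variance explained: %.1f%%\n", pct))
  invisible(x)
}

#' Project new samples with a fitted PCA model
#'
#' @param object A `pca_model` from [pca_reduce()].
#' @param newdata Dataset tibble or numeric matrix with the training genes.
#' @param ... Unused.
#' @return Numeric scores matrix (samples by components).
#' @export
predict.pca_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) expr_matrix(newdata) else as.matrix(newdata)
  if (ncol(x) != nrow(object$rotation)) {
    abort(sprintf("newdata has %d genes, model expects %d",
                  ncol(x), nrow(object$rotation)))
  }
  scale(x, center = object$center, scale = object$scale) %*% object$rotation
}
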