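#' Generate a labelled expression dataset with planted informative genes
#'
#' Emulates a multi-class cancer-subtype count matrix. Every gene's
#' log2-expression is drawn `Normal(baseline_log_mean, dispersion)`; each
#' class owns a disjoint set of `n_informative` genes whose mean is shifted
#' by `+effect_size` (log2 units) in that class's samples. Latent log values
#' are exponentiated to counts (`round(max(2^x - 1, 0))`), so the standard
#' `log2(y + 1)` preprocessing transform approximately inverts the
#' construction. Fully seed-deterministic.
#'
#' @param n_per_class Samples per class (default `c(200, 200)`).
#' @param d Total genes (default 500).
#' @param n_informative Informative genes per class (default 10;
#'   `n_informative * classes <= d`).
#' @param effect_size Log2 mean shift of informative genes (default 2.0).
#' @param baseline_log_mean Baseline log2 mean (default 5.0).
#' @param dispersion Log2-scale standard deviation (default 0.5).
#' @param seed Integer seed.
#' @param class_names Optional class labels (default `class1, class2, ...`).
#' @param keep_latent Also return the latent log2 matrix (for analytic
#'   checks).
#' @return A list: `data` (dataset tibble with `sample_id`, `label`, genes
#'   `g0001...`) and `truth` (ground truth: `informative_mask`, `per_class`
#'   gene-id lists, and `latent` when requested).
#' @export
generate_dataset <- function(n_per_class = c(200, 200), d = 500L,
                             n_informative = 10L, effect_size = 2,
                             baseline_log_mean = 5, dispersion = 0.5,
                             seed = 1L, class_names = NULL,
                             keep_latent = FALSE) {
  n_classes <- length(n_per_class)
  stopifnot(n_classes >= 1, all(n_per_class >= 1), effect_size >= 0,
            dispersion > 0)
  if (n_informative * n_classes > d) {
    abort("n_informative * classes exceeds the number of genes")
  }
  class_names <- class_names %||% paste0("class", seq_len(n_classes))
  m <- sum(n_per_class)
  genes <- sprintf("g%04d", seq_len(d))
  labels <- rep(class_names, times = n_per_class)
  with_seed(seed, {
    inf_idx <- sample.int(d, n_informative * n_classes)
    per_class <- split(inf_idx, rep(seq_len(n_classes), each = n_informative))
    mu <- matrix(baseline_log_mean, m, d)
    for (c_ in seq_len(n_classes)) {
      rows <- which(labels == class_names[c_])
      mu[rows, per_class[[c_]]] <- mu[rows, per_class[[c_]]] + effect_size
    }
    latent <- mu + matrix(rnorm(m * d, sd = dispersion), m, d)
    counts <- round(pmax(2^latent - 1, 0))
    colnames(counts) <- genes
    data <- bind_cols(
      tibble(sample_id = sprintf("s%04d", seq_len(m)), label = labels),
      as_tibble(counts, .name_repair = "minimal"))
    mask <- logical(d)
    mask[inf_idx] <- TRUE
    truth <- list(
      informative_mask = stats::setNames(mask, genes),
      per_class = lapply(per_class, function(i) genes[i]))
    names(truth$per_class) <- class_names
    if (keep_latent) truth$latent <- latent
    list(data = data, truth = truth)
  })
}

#' Fraction of planted genes recovered by a selection
#'
#' @param selection A `feature_selection` (or character vector of selected
#'   gene ids).
#' @param truth Ground truth from [generate_dataset()].
#' @return Fraction of the truth's informative genes present in the
#'   selection, in `[0, 1]`.
#' @export
recovery_score <- function(selection, truth) {
  sel <- if (is.character(selection)) selection else
    selected_genes(selection)
  informative <- names(truth$informative_mask)[truth$informative_mask]
  if (length(informative) == 0L) return(NA_real_)
  mean(informative %in% sel)
}
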