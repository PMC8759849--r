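#' Read a delimited expression table
#'
#' Reads a CSV/TSV expression table into the package's dataset convention
#' (one row per sample, a `sample_id` column, an optional `label` column,
#' gene columns numeric and non-negative). Tables written with genes in rows
#' (the common microarray export) are transposed on the way in.
#'
#' Labels may travel either as a designated column of the table or as a
#' sidecar two-column file (`sample_id`, `label`) passed via `labels_path`.
#'
#' @param path Path to the delimited table. The first column holds
#'   identifiers (sample ids for `samples_in_rows`, gene ids for
#'   `genes_in_rows`).
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @param label_col Name of the label column inside the table, or `NULL` when
#'   labels are absent or sidecar-borne.
#' @param labels_path Optional sidecar label file (two columns:
#'   sample_id, label; same delimiter rules).
#' @param delim Field delimiter; by default inferred from the extension
#'   (`.csv` is comma, anything else tab).
#' @return A dataset tibble passing [validate_dataset()].
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_in_rows",
                                                  "genes_in_rows"),
                                  label_col = "label",
                                  labels_path = NULL,
                                  delim = NULL) {
  orientation <- match.arg(orientation)
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  prob <- readr::problems(raw)
  if (nrow(prob) > 0L) {
    abort(sprintf("malformed table %s: row %d, column %d (%s)",
                  path, prob$row[1], prob$col[1], prob$expected[1]))
  }
  if (orientation == "genes_in_rows") {
    gene_ids <- as.character(raw[[1]])
    vals <- t(as.matrix(raw[, -1, drop = FALSE]))
    out <- tibble(sample_id = colnames(raw)[-1])
    mat <- as_tibble(vals, .name_repair = "minimal")
    names(mat) <- gene_ids
    out <- bind_cols(out, mat)
  } else {
    out <- raw
    names(out)[1] <- "sample_id"
    out$sample_id <- as.character(out$sample_id)
  }
  if (!is.null(label_col) && label_col %in% names(out)) {
    out$label <- as.character(out[[label_col]])
    if (label_col != "label") out[[label_col]] <- NULL
    out <- dplyr::relocate(out, "sample_id", "label")
  }
  if (!is.null(labels_path)) {
    lab <- readr::read_delim(labels_path, delim = guess_delim(labels_path),
                             show_col_types = FALSE, progress = FALSE)
    names(lab)[1:2] <- c("sample_id", "label")
    lab$sample_id <- as.character(lab$sample_id)
    miss <- setdiff(out$sample_id, lab$sample_id)
    if (length(miss) > 0L) {
      abort(sprintf("sidecar label file %s is missing sample %s",
                    labels_path, miss[1]))
    }
    out$label <- as.character(lab$label[match(out$sample_id, lab$sample_id)])
    out <- dplyr::relocate(out, "sample_id", "label")
  }
  validate_dataset(out)
  out
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: writes the dataset as delimited text
#' with floats rendered at 6 significant digits, so read-after-write is the
#' identity at that precision.
#'
#' @inheritParams read_expression_table
#' @param data Dataset tibble.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(data, path,
                                   orientation = c("samples_in_rows",
                                                   "genes_in_rows"),
                                   delim = NULL) {
  orientation <- match.arg(orientation)
  validate_dataset(data)
  delim <- delim %||% guess_delim(path)
  x <- expr_matrix(data)
  fmt <- function(v) formatC(v, digits = 6, format = "g")
  if (orientation == "samples_in_rows") {
    out <- tibble(sample_id = data$sample_id %||% rownames(x))
    if ("label" %in% names(data)) out$label <- as.character(data$label)
    out <- bind_cols(out, as_tibble(apply(x, 2, fmt, simplify = FALSE)))
  } else {
    vals <- t(x)
    out <- tibble(gene_id = colnames(x))
    m <- as_tibble(apply(vals, 2, fmt, simplify = FALSE),
                   .name_repair = "minimal")
    names(m) <- rownames(x)
    out <- bind_cols(out, m)
  }
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

guess_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a dataset manifest
#'
#' A manifest is a YAML list of entries with fields `name` (dataset),
#' `subtype` (class label for every sample in the file) and `path`
#' (expression table, relative paths resolved against the manifest location).
#'
#' @param path Manifest YAML path.
#' @return A tibble with columns `name`, `subtype`, `path`.
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- if (!is.null(y$entries)) y$entries else y
  out <- purrr::map_dfr(entries, function(e) {
    if (is.null(e$name) || is.null(e$subtype) || is.null(e$path))
      abort("manifest entries need fields name, subtype, path")
    tibble(name = e$name, subtype = e$subtype, path = e$path)
  })
  dir <- dirname(path)
  out$path <- ifelse(grepl("^(/|[A-Za-z]:)", out$path), out$path,
                     file.path(dir, out$path))
  out
}

#' Load the datasets named in a manifest
#'
#' Reads every expression table a manifest points at, labels each sample with
#' its entry's `subtype`, and row-binds entries that share a dataset `name`.
#'
#' @param manifest Path to a manifest YAML or the tibble from
#'   [read_manifest()].
#' @param name Optional dataset name to restrict to.
#' @inheritParams read_expression_table
#' @return A single dataset tibble (labels = subtypes).
#' @export
load_manifest <- function(manifest, name = NULL,
                          orientation = "samples_in_rows") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(name)) manifest <- manifest[manifest$name == name, ]
  if (nrow(manifest) == 0L) abort("no manifest entries selected")
  parts <- purrr::pmap(manifest, function(name, subtype, path) {
    ds <- read_expression_table(path, orientation = orientation,
                                label_col = NULL)
    ds$label <- subtype
    dplyr::relocate(ds, "sample_id", "label")
  })
  genes <- gene_names(parts[[1]])
  for (p in parts[-1]) {
    if (!identical(gene_names(p), genes))
      abort("manifest entries disagree on gene columns")
  }
  out <- bind_rows(parts)
  validate_dataset(out, require_label = TRUE)
  out
}

#' Stratified train/validation split
#'
#' Splits a labelled dataset into train and validation parts preserving class
#' proportions. Per-class train counts follow the largest-remainder rule
#' (targets `train_fraction * n_c`, rounded so the overall train size is
#' `round(train_fraction * m)`), then a seeded shuffle decides which samples
#' fill each class quota — so the split is deterministic for a fixed seed and
#' per-class counts are within one sample of the global proportion.
#'
#' @param data Labelled dataset tibble.
#' @param train_fraction Fraction of samples for the training part, in (0,1).
#' @param seed Integer seed controlling the shuffle.
#' @return A list with elements `train` and `validation` (dataset tibbles).
#' @export
stratified_split <- function(data, train_fraction, seed = 1L) {
  validate_dataset(data, require_label = TRUE)
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- dataset_labels(data)
  counts <- table(y)
  if (any(counts < 2L)) {
    abort(sprintf("class '%s' has fewer than 2 samples; cannot split",
                  names(counts)[counts < 2][1]))
  }
  m <- nrow(data)
  total_train <- round(train_fraction * m)
  quota <- largest_remainder(as.numeric(counts) * train_fraction, total_train)
  names(quota) <- names(counts)
  idx_train <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      ids <- which(as.character(y) == cl)
      sample(ids)[seq_len(quota[[cl]])]
    }), use.names = FALSE)
  })
  idx_train <- sort(idx_train)
  list(train = data[idx_train, , drop = FALSE],
       validation = data[-idx_train, , drop = FALSE])
}

# Integer apportionment: round targets so they sum to `total`, adjusting the
# entries with the largest remainders first (ties to lower index).
largest_remainder <- function(targets, total) {
  base <- floor(targets)
  rem <- targets - base
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  } else if (extra < 0) {
    ord <- order(rem, seq_along(rem))
    take <- ord[base[ord] > 0][seq_len(-extra)]
    base[take] <- base[take] - 1
  }
  as.integer(base)
}
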