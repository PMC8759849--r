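#' Default pipeline configuration
#'
#' Builds the fully materialised configuration for [run_pipeline()], with
#' every stage's defaults filled in. Any entry can be overridden by the
#' `config` list / YAML passed to `run_pipeline()`. Every stochastic stage
#' derives its own seed from the single master `seed` by a fixed offset, so
#' one integer reproduces the whole run.
#'
#' @param ... Named overrides (nested lists merged over the defaults).
#' @return The configuration list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    data = list(manifest = NULL, dataset_name = NULL, path = NULL,
                orientation = "samples_in_rows", label_col = "label",
                synthetic = list(n_per_class = c(200, 200), d = 500,
                                 n_informative = 10, effect_size = 2,
                                 baseline_log_mean = 5, dispersion = 0.5)),
    preprocess = list(filter_threshold = 1.19, filter_statistic = "mean",
                      pca_components = 133, standardize = TRUE),
    latent = list(backend = "pca", latent_dim = 8, hidden_dim = 128,
                  epochs = 200, learning_rate = 1e-3),
    selector = list(method = "lfst", p = 20, lambda = 0,
                    mrmr_criterion = "MID", bins = 10,
                    relief_iterations = 50,
                    abc = list(colony_size = 20, limit = 10,
                               max_evaluations = 2000, lambda = 0.01)),
    cnn = list(channels = 32, kernel_size = 5, pool_size = 2, epochs = 60,
               batch_size = 10, learning_rate = 1e-3, weight_decay = 1e-8,
               patience = 10, train_valid_split = 0.5, dropout = FALSE),
    cv = list(k = 2, repeats = 3),
    output_dir = NULL)
  deep_merge(defaults, list(...))
}

deep_merge <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]]))) {
      base[[nm]] <- deep_merge(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full classification pipeline
#'
#' Orchestrates the end-to-end analysis: load (manifest / table / synthetic)
#' -> log2 transform -> low-expression filter -> PCA -> latent embedding ->
#' gene selection (any selector) -> CNN repeated stratified k-fold
#' cross-validation -> classification report. Gene selection operates on
#' the log-scale filtered gene matrix; the latent target kernel comes from
#' the PCA/autoencoder embedding; the CNN consumes the selected genes.
#'
#' @param config A configuration list (see [pipeline_config()]) or the path
#'   to a YAML file of overrides.
#' @param output_dir Optional output directory; when set, writes
#'   `report.json` (config echo, selection, per-fold metrics),
#'   `selection.json` and `selected_genes.txt`. Partial outputs are removed
#'   if a stage fails.
#' @param data Optional pre-loaded dataset tibble (overrides the data
#'   section).
#' @param truth Optional generator ground truth; adds `recovery_score` to
#'   the report.
#' @return The run report (list), invisibly when writing to disk.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL,
                         data = NULL, truth = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- deep_merge(pipeline_config(), config)
  output_dir <- output_dir %||% cfg$output_dir
  seed <- as.integer(cfg$seed)
  log_msg <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  cleanup <- function() {
    if (!is.null(output_dir) && dir.exists(output_dir)) {
      unlink(file.path(output_dir,
                       c("report.json", "selection.json",
                         "selected_genes.txt")))
    }
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      cleanup()
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)))
    })
  }

  ds <- run_stage("load", {
    if (!is.null(data)) data
    else if (!is.null(cfg$data$manifest)) {
      load_manifest(cfg$data$manifest, name = cfg$data$dataset_name,
                    orientation = cfg$data$orientation)
    } else if (!is.null(cfg$data$path)) {
      read_expression_table(cfg$data$path,
                            orientation = cfg$data$orientation,
                            label_col = cfg$data$label_col)
    } else {
      s <- cfg$data$synthetic
      gen <- generate_dataset(n_per_class = unlist(s$n_per_class),
                              d = s$d, n_informative = s$n_informative,
                              effect_size = s$effect_size,
                              baseline_log_mean = s$baseline_log_mean,
                              dispersion = s$dispersion, seed = seed + 11L)
      if (is.null(truth)) truth <- gen$truth
      gen$data
    }
  })
  log_msg("load", "%d samples x %d genes, %d classes", nrow(ds),
          length(gene_names(ds)), nlevels(dataset_labels(ds)))

  logged <- run_stage("log_transform", log_transform(ds))
  filt <- run_stage("filter", filter_genes(
    logged, threshold = cfg$preprocess$filter_threshold,
    statistic = cfg$preprocess$filter_statistic))
  log_msg("filter", "removed %d genes at threshold %g",
          length(filt$removed), cfg$preprocess$filter_threshold)

  pca <- run_stage("pca", pca_reduce(
    filt$data, n_components = cfg$preprocess$pca_components,
    standardize = cfg$preprocess$standardize))
  latent_model <- run_stage("latent", fit_latent(
    pca$scores, backend = cfg$latent$backend,
    latent_dim = min(cfg$latent$latent_dim,
                     ncol(pca$model$rotation)),
    hidden_dim = cfg$latent$hidden_dim, epochs = cfg$latent$epochs,
    learning_rate = cfg$latent$learning_rate, seed = seed + 23L))
  embedding <- encode(latent_model, pca$scores)

  sel_cfg <- cfg$selector
  p <- min(sel_cfg$p, length(gene_names(filt$data)) - 1L)
  selection <- run_stage("select", switch(
    sel_cfg$method,
    lfst = {
      target <- gaussian_kernel(embedding, gamma = "median")
      w <- fit_alignment_weights(filt$data, target,
                                 lambda = sel_cfg$lambda, seed = seed + 37L)
      select_features(w, rule = "top_p", p = p)
    },
    ig = score_to_selection(
      information_gain(filt$data, bins = sel_cfg$bins), p),
    mrmr_mid = mrmr_select(filt$data, k = p, criterion = "MID"),
    mrmr_miq = mrmr_select(filt$data, k = p, criterion = "MIQ"),
    relief_f = score_to_selection(
      relief_weights(filt$data, variant = "relief_f",
                     iterations = sel_cfg$relief_iterations,
                     seed = seed + 41L), p),
    relief_d = score_to_selection(
      relief_weights(filt$data, variant = "relief_d"), p),
    cfs = cfs_select(filt$data),
    abc = abc_select(filt$data, colony_size = sel_cfg$abc$colony_size,
                     limit = sel_cfg$abc$limit,
                     max_evaluations = sel_cfg$abc$max_evaluations,
                     lambda = sel_cfg$abc$lambda, seed = seed + 43L),
    abort(sprintf("unknown selector '%s'", sel_cfg$method))))
  log_msg("select", "%s kept %d genes", sel_cfg$method, attr(selection, "p"))

  sel_data <- filt$data[, c(meta_cols(filt$data), selected_genes(selection)),
                        drop = FALSE]
  cv <- run_stage("cross_validate", cross_validate(
    sel_data, k = cfg$cv$k, repeats = cfg$cv$repeats, seed = seed + 53L,
    channels = cfg$cnn$channels, kernel_size = cfg$cnn$kernel_size,
    pool_size = cfg$cnn$pool_size, epochs = cfg$cnn$epochs,
    batch_size = cfg$cnn$batch_size,
    learning_rate = cfg$cnn$learning_rate,
    weight_decay = cfg$cnn$weight_decay, patience = cfg$cnn$patience,
    train_valid_split = cfg$cnn$train_valid_split,
    dropout = cfg$cnn$dropout))
  log_msg("cross_validate", "mean accuracy %.3f", cv$summary$mean_accuracy)

  report <- list(
    config = cfg,
    n_samples = nrow(ds), n_genes = length(gene_names(ds)),
    n_genes_after_filter = length(gene_names(filt$data)),
    selected_genes = selected_genes(selection),
    selection_weights = stats::setNames(as.list(selection$weight),
                                        selection$gene),
    fold_accuracies = cv$folds$accuracy,
    mean_accuracy = cv$summary$mean_accuracy,
    per_repeat_accuracy = cv$per_repeat$accuracy,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(truth)) {
    report$recovery_score <- recovery_score(selection, truth)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_selection(selection, file.path(output_dir, "selection.json"),
                    file.path(output_dir, "selected_genes.txt"))
    return(invisible(report))
  }
  report
}
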