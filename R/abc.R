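#' Wrapper fitness of a gene subset
#'
#' Scores a candidate mask by mean stratified cross-validated accuracy of a
#' fast reference classifier on the masked genes, minus a size penalty
#' `lambda * (selected / d)` so equally accurate smaller subsets win.
#' Nearest-centroid is the default reference classifier (deterministic,
#' O(nd)); `"knn"` (1-NN) is selectable.
#'
#' @param data Labelled dataset tibble.
#' @param mask Logical vector over genes, at least one TRUE.
#' @param lambda Size penalty coefficient (default 0.01).
#' @param folds Stratified CV folds (default 3; every class needs at least
#'   `folds` samples).
#' @param seed Integer seed for the fold assignment.
#' @param classifier `"centroid"` (default) or `"knn"`.
#' @return The fitness scalar; deterministic for a fixed seed.
#' @export
subset_fitness <- function(data, mask, lambda = 0.01, folds = 3L, seed = 1L,
                           classifier = c("centroid", "knn")) {
  classifier <- match.arg(classifier)
  x <- expr_matrix(data)
  y <- dataset_labels(data)
  mask <- as.logical(mask)
  stopifnot(length(mask) == ncol(x))
  if (!any(mask)) abort("mask selects no genes")
  if (any(table(y) < folds)) abort("each class needs >= folds samples")
  xs <- x[, mask, drop = FALSE]
  fold_id <- stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    pred <- if (classifier == "centroid") {
      nearest_centroid(xs[tr, , drop = FALSE], y[tr], xs[!tr, , drop = FALSE])
    } else {
      one_nn(xs[tr, , drop = FALSE], y[tr], xs[!tr, , drop = FALSE])
    }
    mean(pred == as.character(y[!tr]))
  }, numeric(1))
  mean(acc) - lambda * sum(mask) / ncol(x)
}

# Deterministic stratified fold labels 1..k.
stratified_folds <- function(y, k, seed) {
  n <- length(y)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

nearest_centroid <- function(xtr, ytr, xte) {
  lv <- levels(droplevels(ytr))
  cents <- do.call(rbind, lapply(lv, function(cl)
    colMeans(xtr[ytr == cl, , drop = FALSE])))
  rownames(cents) <- lv
  d2 <- outer(rowSums(xte^2), rowSums(cents^2), `+`) -
    2 * tcrossprod(xte, cents)
  rownames(cents)[max.col(-d2, ties.method = "first")]
}

one_nn <- function(xtr, ytr, xte) {
  d2 <- outer(rowSums(xte^2), rowSums(xtr^2), `+`) - 2 * tcrossprod(xte, xtr)
  as.character(ytr)[max.col(-d2, ties.method = "first")]
}

#' Artificial bee colony feature selection
#'
#' Swarm search over binary gene masks ("food sources"). Each cycle runs the
#' canonical three phases: *employed* bees mutate every source by flipping
#' 1–3 random bits (greedy acceptance; a source's trial counter grows when
#' the mutant is no better); *onlooker* bees re-mutate sources drawn with
#' probability proportional to fitness shifted to be positive; *scout* bees
#' re-randomise any source whose trials exceed `limit`. The best mask ever
#' evaluated is returned. The run is fully determined by `seed` and stops
#' exactly at `max_evaluations` fitness calls.
#'
#' @param data Labelled dataset tibble (ignored when `fitness_fn` is given,
#'   except for the gene names).
#' @param colony_size Number of food sources (default 20).
#' @param limit Trials before a source is abandoned to a scout (default 10).
#' @param max_evaluations Fitness evaluation budget (default 2000; must cover
#'   the initial colony).
#' @param lambda Size penalty passed to [subset_fitness()] (default 0.01).
#' @param p0 Expected genes per initial source (default `max(2, d/10)`).
#' @param seed Integer seed.
#' @param folds,classifier Passed to [subset_fitness()].
#' @param fitness_fn Optional replacement fitness `function(mask) -> real`
#'   (used e.g. with a known-truth oracle); defaults to [subset_fitness()].
#' @return A `feature_selection` with attributes `fitness` (best fitness),
#'   `evaluations`, and `history` (best-ever fitness after each cycle).
#' @export
abc_select <- function(data, colony_size = 20L, limit = 10L,
                       max_evaluations = 2000L, lambda = 0.01, p0 = NULL,
                       seed = 1L, folds = 3L, classifier = "centroid",
                       fitness_fn = NULL) {
  genes <- gene_names(data)
  d <- length(genes)
  if (d < 2L) abort("ABC needs at least 2 genes")
  stopifnot(colony_size >= 2L)
  if (max_evaluations < colony_size) {
    abort("max_evaluations must cover at least the initial colony")
  }
  p0 <- p0 %||% max(2L, round(d / 10))
  fit <- fitness_fn %||% function(mask) {
    subset_fitness(data, mask, lambda = lambda, folds = folds, seed = seed,
                   classifier = classifier)
  }
  evals <- 0L
  budget_fit <- function(mask) {
    evals <<- evals + 1L
    fit(mask)
  }
  with_seed(seed, {
    rand_mask <- function() {
      m <- runif(d) < p0 / d
      if (!any(m)) m[sample.int(d, 1L)] <- TRUE
      m
    }
    mutate <- function(mask) {
      r <- sample.int(3L, 1L)
      flip <- sample.int(d, r)
      mask[flip] <- !mask[flip]
      if (!any(mask)) mask[sample.int(d, 1L)] <- TRUE
      mask
    }
    src <- replicate(colony_size, rand_mask(), simplify = FALSE)
    fitv <- vapply(src, budget_fit, numeric(1))
    trials <- integer(colony_size)
    best_i <- which.max(fitv)
    best_mask <- src[[best_i]]; best_fit <- fitv[best_i]
    history <- best_fit
    try_replace <- function(i) {
      cand <- mutate(src[[i]])
      f <- budget_fit(cand)
      if (f > fitv[i]) {
        src[[i]] <<- cand; fitv[i] <<- f; trials[i] <<- 0L
        if (f > best_fit) { best_fit <<- f; best_mask <<- cand }
      } else {
        trials[i] <<- trials[i] + 1L
      }
    }
    while (evals + colony_size <= max_evaluations) {
      for (i in seq_len(colony_size)) {           # employed phase
        if (evals >= max_evaluations) break
        try_replace(i)
      }
      shifted <- fitv - min(fitv) + 1e-9          # onlooker phase
      probs <- shifted / sum(shifted)
      for (s in seq_len(colony_size)) {
        if (evals >= max_evaluations) break
        try_replace(sample.int(colony_size, 1L, prob = probs))
      }
      for (i in seq_len(colony_size)) {           # scout phase
        if (evals >= max_evaluations) break
        if (trials[i] > limit) {
          src[[i]] <- rand_mask()
          fitv[i] <- budget_fit(src[[i]])
          trials[i] <- 0L
          if (fitv[i] > best_fit) { best_fit <- fitv[i]; best_mask <- src[[i]] }
        }
      }
      history <- c(history, best_fit)
    }
    weights <- as.numeric(best_mask)
    out <- new_feature_selection(genes, weights, best_mask, "abc")
    attr(out, "fitness") <- best_fit
    attr(out, "evaluations") <- evals
    attr(out, "history") <- history
    out
  })
}
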