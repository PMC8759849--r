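#' Information gain per gene
#'
#' Scores each gene by the mutual information (in bits) between the class
#' label and the equal-frequency-binned gene values:
#' `IG(f) = H(Y) - H(Y | bin(f))`. Bin edges are sample quantiles with
#' duplicate edges merged, so heavily tied genes simply use fewer bins.
#'
#' @param data Labelled dataset tibble.
#' @param bins Number of equal-frequency bins (default 10, minimum 2).
#' @return A `feature_score` tibble: `gene`, `score`, `rank` (ties broken by
#'   lower gene index), with `method = "ig"`.
#' @export
information_gain <- function(data, bins = 10L) {
  if (bins < 2L) abort("bins must be >= 2")
  validate_dataset(data, require_label = TRUE, allow_negative = TRUE)
  y <- dataset_labels(data)
  x <- expr_matrix(data)
  hy <- entropy_bits(table(y))
  scores <- apply(x, 2, function(v) {
    b <- equal_freq_bin(v, bins)
    if (nlevels(b) < 2L) return(0)
    tab <- table(b, y)
    pn <- rowSums(tab) / length(y)
    hcond <- sum(pn * apply(tab, 1, entropy_bits))
    max(hy - hcond, 0)
  })
  new_feature_score(colnames(x), scores, "ig")
}

entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

equal_freq_bin <- function(v, bins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2L) return(factor(rep(1L, length(v))))
  cut(v, breaks = br, include.lowest = TRUE)
}

new_feature_score <- function(genes, scores, method) {
  rank <- order(order(-scores, seq_along(scores)))
  out <- tibble(gene = genes, score = unname(scores), rank = rank)
  structure(out, method = method,
            class = c("feature_score", class(out)))
}

#' @export
print.feature_score <- function(x, ...) {
  cat(sprintf("feature scores (%s) over %d genes\n", attr(x, "method"),
              nrow(x)))
  NextMethod()
}

#' @method tidy feature_score
#' @export
tidy.feature_score <- function(x, ...) as_tibble(x)[order(x$rank), ]

#' @method autoplot feature_score
#' @export
autoplot.feature_score <- function(object, top_n = 30, ...) {
  df <- tidy(object)[seq_len(min(top_n, nrow(object))), ]
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$gene)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("%s score", attr(object, "method")), y = NULL)
}

#' Keep the top-k genes of a feature score
#'
#' @param score A `feature_score`.
#' @param k Number of genes to keep.
#' @return A `feature_selection`.
#' @export
score_to_selection <- function(score, k) {
  stopifnot(k >= 1, k < nrow(score))
  mask <- score$rank <= k
  new_feature_selection(score$gene, score$score, mask, attr(score, "method"))
}

#' Minimum-redundancy maximum-relevance selection (MID / MIQ)
#'
#' Greedy forward selection over genes. Relevance is the one-way ANOVA
#' F-statistic of the gene against the class; redundancy is the mean
#' absolute Pearson correlation with already-selected genes. The first pick
#' maximises F alone; thereafter the criterion is `F - mean|rho|` (MID,
#' difference) or `F / mean|rho|` (MIQ, quotient, denominator floored at
#' 1e-12). Zero-variance genes are excluded with a warning.
#'
#' @param data Labelled dataset tibble.
#' @param k Number of genes to select (`1 <= k < d`).
#' @param criterion `"MID"` (default) or `"MIQ"`.
#' @return A `feature_selection`; the greedy order and per-step scores are in
#'   attribute `trajectory`.
#' @export
mrmr_select <- function(data, k, criterion = c("MID", "MIQ")) {
  criterion <- match.arg(criterion)
  validate_dataset(data, require_label = TRUE, allow_negative = TRUE)
  x <- expr_matrix(data)
  y <- dataset_labels(data)
  stopifnot(k >= 1, k < ncol(x))
  v <- apply(x, 2, stats::var)
  usable <- v > .Machine$double.eps
  if (!all(usable)) {
    warn(sprintf("excluding %d zero-variance gene(s) from mRMR",
                 sum(!usable)))
  }
  Fstat <- rep(NA_real_, ncol(x))
  Fstat[usable] <- anova_f(x[, usable, drop = FALSE], y)
  selected <- integer(0)
  traj <- list()
  cand <- which(usable)
  for (step in seq_len(k)) {
    if (step == 1L) {
      scores <- Fstat[cand]
    } else {
      red <- abs(stats::cor(x[, cand, drop = FALSE],
                            x[, selected, drop = FALSE]))
      mean_red <- rowMeans(red)
      scores <- if (criterion == "MID") Fstat[cand] - mean_red else
        Fstat[cand] / pmax(mean_red, 1e-12)
    }
    pick <- cand[order(-scores, cand)[1]]
    traj[[step]] <- tibble(step = step, gene = colnames(x)[pick],
                           score = max(scores))
    selected <- c(selected, pick)
    cand <- setdiff(cand, pick)
  }
  mask <- logical(ncol(x))
  mask[selected] <- TRUE
  weights <- numeric(ncol(x))
  # rank-coded weights: earlier picks weigh more
  weights[selected] <- rev(seq_len(k))
  out <- new_feature_selection(colnames(x), weights, mask,
                               paste0("mrmr_", tolower(criterion)))
  attr(out, "trajectory") <- bind_rows(traj)
  attr(out, "f_statistic") <- Fstat
  out
}

# Vectorised one-way ANOVA F over columns.
anova_f <- function(x, y) {
  n <- nrow(x)
  g <- nlevels(y)
  grand <- colMeans(x)
  ssb <- numeric(ncol(x))
  ssw <- numeric(ncol(x))
  for (cl in levels(y)) {
    xi <- x[y == cl, , drop = FALSE]
    mi <- colMeans(xi)
    ssb <- ssb + nrow(xi) * (mi - grand)^2
    ssw <- ssw + colSums(sweep(xi, 2, mi)^2)
  }
  (ssb / (g - 1)) / pmax(ssw / (n - g), .Machine$double.eps)
}

#' Relief feature weighting (Relief-F / Relief-D)
#'
#' Instance-based weighting: for each reference instance, every feature's
#' weight rises with its separation from the nearest miss(es) (other-class
#' neighbours, weighted by class prior `P(c) / (1 - P(class(x)))`) and falls
#' with its separation from the nearest hit(s) (same-class neighbours).
#' Feature differences are range-normalised (zero-range features contribute
#' 0), and neighbour search uses the range-normalised Manhattan distance.
#'
#' `relief_d` visits every instance deterministically (updates divided by
#' m); `relief_f` samples `iterations` instances with the given seed
#' (updates divided by `iterations`).
#'
#' @param data Labelled dataset tibble.
#' @param variant `"relief_d"` (default) or `"relief_f"`.
#' @param iterations Sampled instances for relief_f (default 50).
#' @param k_neighbors Hits/misses averaged per instance (default 1).
#' @param seed Integer seed (relief_f sampling only).
#' @return A `feature_score` with the final weights.
#' @export
relief_weights <- function(data, variant = c("relief_d", "relief_f"),
                           iterations = 50L, k_neighbors = 1L, seed = 1L) {
  variant <- match.arg(variant)
  validate_dataset(data, require_label = TRUE, allow_negative = TRUE)
  x <- expr_matrix(data)
  y <- dataset_labels(data)
  counts <- table(y)
  if (any(counts < k_neighbors + 1L)) {
    abort(sprintf("class '%s' needs at least k_neighbors + 1 = %d samples",
                  names(counts)[counts < k_neighbors + 1][1],
                  k_neighbors + 1L))
  }
  n <- nrow(x); d <- ncol(x)
  rng <- apply(x, 2, max) - apply(x, 2, min)
  ok <- rng > 0
  xn <- x
  xn[, ok] <- sweep(x[, ok, drop = FALSE], 2, rng[ok], `/`)
  xn[, !ok] <- 0                      # zero-range features: diff defined 0
  dm <- as.matrix(stats::dist(xn, method = "manhattan"))
  diag(dm) <- Inf
  prior <- as.numeric(counts) / n
  names(prior) <- names(counts)
  refs <- if (variant == "relief_d") seq_len(n) else
    with_seed(seed, sample.int(n, iterations, replace = iterations > n))
  w <- numeric(d)
  for (i in refs) {
    own <- as.character(y[i])
    hits <- k_nearest(dm[i, ], which(y == y[i] & seq_len(n) != i),
                      k_neighbors)
    hit_diff <- colMeans(abs(xn[hits, , drop = FALSE] -
                               matrix(xn[i, ], length(hits), d, byrow = TRUE)))
    miss_diff <- numeric(d)
    for (cl in setdiff(levels(y), own)) {
      ms <- k_nearest(dm[i, ], which(y == cl), k_neighbors)
      md <- colMeans(abs(xn[ms, , drop = FALSE] -
                           matrix(xn[i, ], length(ms), d, byrow = TRUE)))
      miss_diff <- miss_diff + prior[[cl]] / (1 - prior[[own]]) * md
    }
    w <- w + (miss_diff - hit_diff)
  }
  w <- w / length(refs)
  new_feature_score(colnames(x), w, variant)
}

k_nearest <- function(dists, candidates, k) {
  candidates[order(dists[candidates], candidates)][seq_len(k)]
}

#' CFS merit of a feature subset
#'
#' `merit(S) = k * rcf / sqrt(k + k (k - 1) * rff)` where `rcf` is the mean
#' absolute feature-class correlation over S (multi-class labels reduce to
#' the mean of one-vs-rest point-biserial magnitudes) and `rff` the mean
#' absolute pairwise Pearson correlation within S.
#'
#' @param data Labelled dataset tibble.
#' @param subset Character vector of gene names or integer indices.
#' @return The merit scalar.
#' @export
cfs_merit <- function(data, subset) {
  x <- expr_matrix(data)
  y <- dataset_labels(data)
  idx <- if (is.character(subset)) match(subset, colnames(x)) else subset
  cfs_merit_idx(x, class_correlations(x, y), idx)
}

class_correlations <- function(x, y) {
  ind <- sapply(levels(y), function(cl) as.numeric(y == cl))
  rowMeans(abs(stats::cor(x, ind)))
}

cfs_merit_idx <- function(x, rcf, idx) {
  k <- length(idx)
  if (k == 0L) return(0)
  rcf_bar <- mean(rcf[idx])
  if (k == 1L) return(rcf_bar)
  cc <- abs(stats::cor(x[, idx, drop = FALSE]))
  rff_bar <- mean(cc[upper.tri(cc)])
  k * rcf_bar / sqrt(k + k * (k - 1) * rff_bar)
}

#' Correlation-based feature selection (CFS)
#'
#' Searches for the subset maximising the CFS merit ([cfs_merit()]).
#' `forward` adds the best-improving gene until no addition improves;
#' `best_first` keeps a frontier of subsets and stops after 5 consecutive
#' expansions without a new best (stale limit).
#'
#' @param data Labelled dataset tibble (at least 2 genes, 2 classes).
#' @param search `"best_first"` (default) or `"forward"`.
#' @param stale_limit Best-first stop criterion (default 5).
#' @return A `feature_selection` with the achieved merit in attribute
#'   `merit`.
#' @export
cfs_select <- function(data, search = c("best_first", "forward"),
                       stale_limit = 5L) {
  search <- match.arg(search)
  validate_dataset(data, require_label = TRUE, allow_negative = TRUE)
  x <- expr_matrix(data)
  y <- dataset_labels(data)
  if (ncol(x) < 2L) abort("CFS needs at least 2 genes")
  rcf <- class_correlations(x, y)
  d <- ncol(x)
  merit <- function(idx) cfs_merit_idx(x, rcf, idx)
  if (search == "forward") {
    cur <- integer(0); cur_m <- -Inf
    repeat {
      cand <- setdiff(seq_len(d), cur)
      ms <- vapply(cand, function(j) merit(c(cur, j)), numeric(1))
      best <- which.max(ms)
      if (ms[best] > cur_m) {
        cur <- c(cur, cand[best]); cur_m <- ms[best]
      } else break
      if (length(cur) == d) break
    }
    best_set <- cur; best_m <- cur_m
  } else {
    # best-first over forward expansions, stale-limited
    frontier <- list(list(set = integer(0), m = 0))
    seen <- new.env(hash = TRUE)
    best_set <- integer(0); best_m <- -Inf; stale <- 0L
    while (length(frontier) > 0L && stale < stale_limit) {
      ms <- vapply(frontier, `[[`, numeric(1), "m")
      i <- which.max(ms)
      node <- frontier[[i]]; frontier[[i]] <- NULL
      improved <- FALSE
      for (j in setdiff(seq_len(d), node$set)) {
        s <- sort(c(node$set, j))
        key <- paste(s, collapse = ",")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        m <- merit(s)
        frontier[[length(frontier) + 1L]] <- list(set = s, m = m)
        if (m > best_m + 1e-12) {
          best_m <- m; best_set <- s; improved <- TRUE
        }
      }
      stale <- if (improved) 0L else stale + 1L
    }
  }
  mask <- logical(d); mask[best_set] <- TRUE
  weights <- numeric(d); weights[best_set] <- rcf[best_set]
  out <- new_feature_selection(colnames(x), weights, mask, "cfs")
  attr(out, "merit") <- best_m
  out
}
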