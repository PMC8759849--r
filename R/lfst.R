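#' Fit non-negative kernel-alignment weights over genes
#'
#' The core of the latent feature selection technique. One Gaussian kernel
#' `K_f` is built per gene (bandwidth from the per-gene median heuristic
#' unless `gamma` is numeric), and a non-negative weight vector `mu` is
#' sought so the combined kernel `K_mu = sum_f mu_f K_f` aligns maximally
#' with the target kernel `K_Z` computed on the latent embedding:
#'
#'   maximise  A(K_mu, K_Z) - lambda * ||mu||_1   subject to  mu >= 0,
#'
#' with `A` the (centered) kernel-target alignment. Because the alignment is
#' scale-invariant in `mu`, the problem is equivalent to a convex program;
#' it is solved by projected-gradient ascent with backtracking, so the
#' objective is non-decreasing across accepted iterations. The returned `mu`
#' is rescaled to unit L1 norm; genes with non-zero weight carry unique
#' information about the latent similarity structure.
#'
#' Centering is linear, so each per-gene kernel is centered once up front.
#' When `d <= gram_cap` the d-by-d Gram matrix of Frobenius products is
#' formed once (fast iterations); above the cap gradient terms are computed
#' by streamed matrix-vector products over the stacked kernels.
#'
#' @param data Dataset tibble (gene columns are the candidate features) or a
#'   numeric samples-by-genes matrix.
#' @param target `kernel_matrix` on the same samples, typically
#'   `gaussian_kernel(encode(latent_model, scores))`.
#' @param gamma Per-gene kernel bandwidth: `"median"` (default) or a
#'   non-negative scalar used for every gene.
#' @param lambda L1 sparsity penalty (default 0).
#' @param centered Use centered alignment (default TRUE).
#' @param max_iter,tol Optimiser budget and relative improvement tolerance.
#' @param seed Integer seed (reserved for stochastic variants; the solver
#'   itself is deterministic).
#' @param gram_cap Largest d for which the d-by-d Gram matrix is formed.
#' @return An `alignment_weights` object: `mu` (named, unit L1), `objective`
#'   (achieved alignment), `converged`, `iterations`, `lambda`.
#' @export
fit_alignment_weights <- function(data, target, gamma = "median",
                                  lambda = 0, centered = TRUE,
                                  max_iter = 500L, tol = 1e-9, seed = 1L,
                                  gram_cap = 2000L) {
  x <- if (is.data.frame(data)) expr_matrix(data) else as.matrix(data)
  d <- ncol(x); n <- nrow(x)
  Kz <- unclass(as.matrix(target))
  if (!all(dim(Kz) == c(n, n))) {
    abort(sprintf("target kernel is %dx%d but data has %d samples",
                  nrow(Kz), ncol(Kz), n))
  }
  if (d < 1L) abort("no candidate features")
  if (centered) Kz <- center_kernel(Kz)
  kz <- as.vector(Kz)
  kz_norm <- sqrt(sum(kz^2))
  if (kz_norm <= 0) abort("target kernel is zero after centering")

  # Stacked per-gene (centered) kernels, one column per gene.
  D <- feature_kernel_stack(x, gamma, centered)
  a <- as.vector(crossprod(D, kz))          # <K_f, K_Z>
  use_gram <- d <= gram_cap
  G <- if (use_gram) crossprod(D) else NULL # <K_f, K_g>
  Gmv <- if (use_gram) function(mu) as.vector(G %*% mu) else
    function(mu) as.vector(crossprod(D, as.vector(D %*% mu)))

  if (d == 1L) {
    mu <- stats::setNames(1, colnames(x))
    obj <- a[1] / (sqrt(Gmv(1)) * kz_norm)
    return(new_alignment_weights(mu, obj, TRUE, 0L, lambda))
  }

  objective <- function(mu, q = NULL) {
    s <- sum(a * mu)
    q <- q %||% sum(mu * Gmv(mu))
    if (q <= 0) return(-Inf)
    s / (sqrt(q) * kz_norm) - lambda * sum(mu)
  }

  # init from per-feature alignment (positive part), fallback uniform
  mu <- pmax(a, 0)
  if (sum(mu) <= 0) mu <- rep(1, d)
  mu <- mu / sum(mu)
  obj <- objective(mu)
  step <- 1 / d
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    gmu <- Gmv(mu)
    q <- sum(mu * gmu)
    s <- sum(a * mu)
    grad <- a / (sqrt(q) * kz_norm) - s * gmu / (q^1.5 * kz_norm) - lambda
    accepted <- FALSE
    for (tries in 1:30) {
      cand <- pmax(mu + step * grad, 0)
      if (sum(cand) <= 0) { step <- step / 2; next }
      cand_obj <- objective(cand)
      if (cand_obj > obj) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    improved <- cand_obj - obj
    mu <- cand; obj <- cand_obj
    step <- step * 2
    if (improved < tol * max(abs(obj), 1)) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("alignment optimiser hit max_iter = %d; returning best iterate",
                 max_iter))
  }
  mu <- mu / sum(mu)
  align <- sum(a * mu) / (sqrt(sum(mu * Gmv(mu))) * kz_norm)
  names(mu) <- colnames(x) %||% paste0("f", seq_len(d))
  new_alignment_weights(mu, align, converged, it, lambda)
}

# n^2-by-d matrix whose f-th column is vec of gene f's (centered) Gaussian
# kernel. Constant genes yield an all-ones kernel (zero after centering).
feature_kernel_stack <- function(x, gamma = "median", centered = TRUE) {
  n <- nrow(x); d <- ncol(x)
  D <- matrix(0, n * n, d)
  ones <- rep(1, n)
  for (f in seq_len(d)) {
    v <- x[, f]
    d2 <- outer(v, v, `-`)^2
    if (identical(gamma, "median")) {
      med <- stats::median(abs(outer(v, v, `-`))[upper.tri(d2)])
      g <- if (med > 0) 1 / (2 * med^2) else 0
    } else {
      g <- gamma
    }
    K <- if (g > 0) exp(-g * d2) else matrix(1, n, n)
    if (centered) K <- center_kernel(K)
    D[, f] <- as.vector(K)
  }
  colnames(D) <- colnames(x)
  D
}

new_alignment_weights <- function(mu, objective, converged, iterations,
                                  lambda) {
  structure(list(mu = mu, objective = objective, converged = converged,
                 iterations = iterations, lambda = lambda),
            class = "alignment_weights")
}

#' @export
print.alignment_weights <- function(x, ...) {
  cat(sprintf("alignment weights over %d genes: %d non-zero, alignment %.4f%s\n",
              length(x$mu), sum(x$mu > 1e-12), x$objective,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @method tidy alignment_weights
#' @export
tidy.alignment_weights <- function(x, ...) {
  tibble(gene = names(x$mu), weight = unname(x$mu)) |>
    arrange(dplyr::desc(.data$weight))
}

#' @method glance alignment_weights
#' @export
glance.alignment_weights <- function(x, ...) {
  tibble(alignment = x$objective, n_nonzero = sum(x$mu > 1e-12),
         iterations = x$iterations, converged = x$converged,
         lambda = x$lambda)
}

#' Turn alignment weights (or any per-gene scores) into a selection
#'
#' @param weights An `alignment_weights` object, or a named numeric vector of
#'   non-negative per-gene scores.
#' @param rule `"top_p"` keeps the `p` largest weights (ties broken by lower
#'   gene index); `"nonzero"` keeps weights above `epsilon`.
#' @param p Number of genes for `rule = "top_p"` (`1 <= p < d`).
#' @param epsilon Threshold for `rule = "nonzero"` (default 1e-6).
#' @return A `feature_selection`: a tibble with columns `gene`, `weight`,
#'   `selected`, carrying the selection size `p` and method as attributes.
#' @export
select_features <- function(weights, rule = c("top_p", "nonzero"), p = NULL,
                            epsilon = 1e-6) {
  rule <- match.arg(rule)
  method <- "scores"
  if (inherits(weights, "alignment_weights")) {
    method <- "lfst"
    weights <- weights$mu
  }
  stopifnot(is.numeric(weights))
  d <- length(weights)
  genes <- names(weights) %||% paste0("f", seq_len(d))
  if (rule == "top_p") {
    stopifnot(!is.null(p), p >= 1, p < d)
    ord <- order(-weights, seq_len(d))
    mask <- logical(d)
    mask[ord[seq_len(p)]] <- TRUE
  } else {
    stopifnot(epsilon >= 0)
    mask <- unname(weights > epsilon)
    if (!any(mask) || all(mask)) {
      abort(sprintf(
        "nonzero rule selected %d of %d genes; use rule = 'top_p'",
        sum(mask), d))
    }
  }
  new_feature_selection(genes, unname(weights), mask, method)
}

new_feature_selection <- function(genes, weights, mask, method) {
  out <- tibble(gene = genes, weight = weights, selected = mask)
  structure(out, p = sum(mask), method = method,
            class = c("feature_selection", class(out)))
}

#' Genes retained by a selection
#'
#' @param selection A `feature_selection`.
#' @return Character vector of selected gene ids (selection order preserved).
#' @export
selected_genes <- function(selection) {
  selection$gene[selection$selected]
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("feature selection (%s): %d of %d genes\n",
              attr(x, "method"), attr(x, "p"), nrow(x)))
  NextMethod()
}

#' @method tidy feature_selection
#' @export
tidy.feature_selection <- function(x, ...) {
  as_tibble(x)[order(-x$weight, seq_len(nrow(x))), ]
}

#' @method glance feature_selection
#' @export
glance.feature_selection <- function(x, ...) {
  tibble(method = attr(x, "method"), p = attr(x, "p"), d = nrow(x))
}

#' @method autoplot feature_selection
#' @export
autoplot.feature_selection <- function(object, top_n = 30, ...) {
  df <- tidy(object)[seq_len(min(top_n, nrow(object))), ]
  df$gene <- factor(df$gene, levels = rev(df$gene))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, y = .data$gene,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "weight", y = NULL,
                  title = sprintf("%s selection (top %d genes)",
                                  attr(object, "method"), nrow(df)))
}

#' Serialize a selection as JSON weights plus a plain gene list
#'
#' @param selection A `feature_selection`.
#' @param json_path Path for the `{gene: weight}` JSON.
#' @param list_path Optional path for a newline-separated selected-gene list.
#' @return `json_path`, invisibly.
#' @export
write_selection <- function(selection, json_path, list_path = NULL) {
  w <- stats::setNames(as.list(selection$weight), selection$gene)
  jsonlite::write_json(w, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(list_path)) {
    writeLines(selected_genes(selection), list_path)
  }
  invisible(json_path)
}
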