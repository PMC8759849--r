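#' Gaussian (RBF) kernel matrix
#'
#' Builds `K[i,j] = exp(-gamma * ||x_i - x_j||^2)` over the rows of `points`.
#' `gamma = "median"` resolves the bandwidth by the median heuristic,
#' `gamma = 1 / (2 * median(pairwise distance)^2)`, a standard scale-free
#' default.
#'
#' @param points Numeric matrix (n samples by q coordinates) or a vector
#'   (treated as a single coordinate).
#' @param gamma Non-negative scalar, or `"median"`.
#' @return An n-by-n `kernel_matrix` (symmetric, unit diagonal, PSD) with the
#'   resolved `gamma` attached as an attribute.
#' @examples
#' K <- gaussian_kernel(matrix(rnorm(20), 10, 2), gamma = "median")
#' all(diag(K) == 1)
#' @export
gaussian_kernel <- function(points, gamma = "median") {
  x <- if (is.null(dim(points))) matrix(points, ncol = 1) else
    as.matrix(points)
  if (nrow(x) < 2L) abort("need at least 2 points")
  if (any(!is.finite(x))) abort("points must be finite")
  d2 <- sq_dists(x)
  if (identical(gamma, "median")) {
    med <- stats::median(sqrt(d2[upper.tri(d2)]))
    if (med <= 0) {
      abort("all points identical: median pairwise distance is zero")
    }
    gamma <- 1 / (2 * med^2)
  }
  stopifnot(is.numeric(gamma), gamma >= 0)
  K <- exp(-gamma * d2)
  diag(K) <- 1
  structure(K, gamma = gamma, class = c("kernel_matrix", "matrix", "array"))
}

# Squared Euclidean distance matrix, symmetric with exact zero diagonal.
sq_dists <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, `+`) - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  (d2 + t(d2)) / 2
}

#' Double-center a kernel matrix
#'
#' Computes `HKH` with `H = I - 11'/n`, removing row/column means; the
#' centered Frobenius geometry makes alignment insensitive to the kernel
#' mean.
#'
#' @param K Square numeric matrix.
#' @return The centered matrix.
#' @export
center_kernel <- function(K) {
  K <- unclass(as.matrix(K))
  rm <- rowMeans(K)
  K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), colMeans(K)) +
    mean(K)
}

#' Kernel-target alignment
#'
#' The normalized Frobenius inner product
#' `A(K1, K2) = <K1, K2>_F / sqrt(<K1, K1>_F <K2, K2>_F)`, a cosine between
#' similarity structures, in `[-1, 1]` (non-negative for PSD kernels when
#' uncentered). With `centered = TRUE` (recommended) both kernels are doubly
#' centered first.
#'
#' @param K1,K2 Square numeric matrices of matching size.
#' @param centered Center both kernels before comparing (default TRUE).
#' @return The alignment scalar.
#' @examples
#' K <- gaussian_kernel(matrix(rnorm(12), 6, 2))
#' kernel_alignment(K, K)  # 1
#' @export
kernel_alignment <- function(K1, K2, centered = TRUE) {
  K1 <- unclass(as.matrix(K1)); K2 <- unclass(as.matrix(K2))
  if (!all(dim(K1) == dim(K2))) abort("kernel sizes differ")
  if (centered) {
    K1 <- center_kernel(K1)
    K2 <- center_kernel(K2)
  }
  n1 <- sum(K1 * K1); n2 <- sum(K2 * K2)
  if (n1 <= 0 || n2 <= 0) abort("zero kernel: alignment undefined")
  sum(K1 * K2) / sqrt(n1 * n2)
}
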