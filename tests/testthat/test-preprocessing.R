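test_that("log transform matches its closed form and preserves zeros", {
  ds <- tibble::tibble(sample_id = "s1", g1 = 0, g2 = 1, g3 = 3, g4 = 7)
  out <- log_transform(ds)
  expect_equal(as.vector(expr_matrix(out)), c(0, 1, 2, 3))
  # monotone on random data
  gen <- small_planted(seed = 2, n = 5, d = 10)$data
  lx <- expr_matrix(log_transform(gen))
  rx <- expr_matrix(gen)
  expect_true(all((order(rx[1, ]) == order(lx[1, ]))[rank(rx[1, ]) > 0]))
})

test_that("gene filter keeps exactly the genes a per-gene recount keeps", {
  gen <- generate_dataset(n_per_class = c(15, 15), d = 200,
                          n_informative = 5, baseline_log_mean = 1.2,
                          dispersion = 1, seed = 9)
  lg <- log_transform(gen$data)
  for (stat in c("mean", "max")) {
    res <- filter_genes(lg, threshold = 1.19, statistic = stat)
    x <- expr_matrix(lg)
    f <- if (stat == "mean") colMeans(x) else apply(x, 2, max)
    expect_setequal(gene_names(res$data), colnames(x)[f > 1.19])
    expect_setequal(res$removed, colnames(x)[f <= 1.19])
    # order preserved among survivors
    expect_identical(gene_names(res$data),
                     intersect(colnames(x), gene_names(res$data)))
  }
  # a gene constant at 0.5 is removed at the default threshold
  lg$g_low <- 0.5
  expect_true("g_low" %in% filter_genes(lg)$removed)
  # threshold 0 with positive values is the identity
  pos <- lg
  pos[gene_names(pos)] <- lapply(pos[gene_names(pos)], function(v) v + 1)
  expect_length(filter_genes(pos, threshold = 0)$removed, 0)
  expect_error(filter_genes(lg, threshold = 1e6), "lower the threshold")
})

test_that("filter commutes with column subsetting", {
  gen <- small_planted(seed = 4, n = 10, d = 30)$data
  lg <- log_transform(gen)
  keep <- c("sample_id", "label", gene_names(lg)[1:15])
  a <- filter_genes(lg[, keep], threshold = 4)$data
  b <- filter_genes(lg, threshold = 4)$data
  common <- intersect(gene_names(a), gene_names(lg)[1:15])
  expect_identical(gene_names(a), intersect(gene_names(b), keep))
  expect_equal(expr_matrix(a), expr_matrix(b[, c("sample_id", "label",
                                                 gene_names(a))]))
})

test_that("PCA reduction matches the eigendecomposition oracle", {
  withr::with_seed(42, {
    x <- matrix(rnorm(50 * 20), 50, 20)
  })
  colnames(x) <- sprintf("g%02d", 1:20)
  ds <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%02d", 1:50)),
                         tibble::as_tibble(as.data.frame(x + 10)))
  res <- pca_reduce(ds, n_components = 5, standardize = FALSE)
  # oracle: full eigendecomposition of the covariance matrix
  xc <- scale(expr_matrix(ds), scale = FALSE)
  ev <- eigen(crossprod(xc) / (nrow(xc) - 1), symmetric = TRUE)
  expect_equal(res$model$explained_variance, ev$values[1:5],
               tolerance = 1e-8)
  # reconstruction residual equals the discarded eigenvalue mass
  scores <- as.matrix(res$scores[, paste0("PC", 1:5)])
  recon <- scores %*% t(res$model$rotation)
  resid <- sum((xc - recon)^2)
  expect_equal(resid, sum(ev$values[6:20]) * (nrow(xc) - 1),
               tolerance = 1e-6)
})

test_that("rank-1 data put all variance on the first component", {
  withr::with_seed(1, {
    u <- rnorm(12); v <- abs(rnorm(6)) + 1
  })
  x <- 5 + outer(u, v)
  colnames(x) <- sprintf("g%d", 1:6)
  ds <- dplyr::bind_cols(tibble::tibble(sample_id = sprintf("s%02d", 1:12)),
                         tibble::as_tibble(as.data.frame(x - min(x))))
  res <- pca_reduce(ds, n_components = 3, standardize = FALSE)
  expect_equal(res$model$explained_variance[1] /
                 sum(res$model$all_variances), 1, tolerance = 1e-10)
})

test_that("PCA is invariant to sample order and keeps sample ids", {
  ds <- small_planted(seed = 8, n = 12, d = 25)$data
  lg <- log_transform(ds)
  perm <- withr::with_seed(3, sample(nrow(lg)))
  a <- pca_reduce(lg, n_components = 4)
  b <- pca_reduce(lg[perm, ], n_components = 4)
  expect_equal(a$scores$sample_id, ds$sample_id)
  bm <- as.matrix(b$scores[match(a$scores$sample_id, b$scores$sample_id),
                           paste0("PC", 1:4)])
  expect_equal(as.matrix(a$scores[, paste0("PC", 1:4)]), bm,
               tolerance = 1e-8)
})

test_that("degenerate PCA inputs are rejected", {
  ds <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       g1 = c(2, 2, 2), g2 = c(1, 1, 1))
  expect_error(pca_reduce(ds), "constant|zero variance")
})
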