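test_that("gaussian kernel closed forms hold", {
  withr::with_seed(1, x <- matrix(rnorm(12), 6, 2))
  K <- gaussian_kernel(x, gamma = 0.7)
  expect_equal(diag(K), rep(1, 6))
  expect_equal(unclass(K), t(unclass(K)))
  expect_true(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
              >= -1e-8)
  # gamma = 0 gives the all-ones kernel
  expect_true(all(unclass(gaussian_kernel(x, gamma = 0)) == 1))
  # two points at distance 1 with gamma = ln 2 -> off-diagonal 0.5
  K2 <- gaussian_kernel(matrix(c(0, 1), 2, 1), gamma = log(2))
  expect_equal(K2[1, 2], 0.5)
  expect_error(gaussian_kernel(matrix(1, 3, 2), gamma = "median"),
               "identical")
})

test_that("median-heuristic kernels are PSD with unit diagonal", {
  for (s in 1:5) {
    withr::with_seed(s, x <- matrix(rnorm(15 * 3), 15, 3))
    K <- gaussian_kernel(x)
    expect_equal(diag(K), rep(1, 15))
    expect_lt(max(abs(unclass(K) - t(unclass(K)))), 1e-10)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("alignment matches Frobenius arithmetic and its invariances", {
  K1 <- diag(2)
  K2 <- matrix(1, 2, 2)
  expect_equal(kernel_alignment(K1, K2, centered = FALSE),
               2 / sqrt(2 * 4))
  withr::with_seed(2, z <- matrix(rnorm(16), 8, 2))
  K <- gaussian_kernel(z)
  expect_equal(kernel_alignment(K, K), 1)
  expect_equal(kernel_alignment(3.7 * unclass(K), K),
               kernel_alignment(K, K))
  expect_error(kernel_alignment(matrix(0, 3, 3), diag(3)), "zero kernel")
})

test_that("single-feature weights reduce to the trivial solution", {
  withr::with_seed(3, {
    v <- matrix(rnorm(15), 15, 1)
    z <- matrix(rnorm(30), 15, 2)
  })
  colnames(v) <- "gene1"
  K <- gaussian_kernel(z)
  w <- fit_alignment_weights(v, K)
  expect_equal(unname(w$mu), 1)
  expect_equal(w$objective,
               kernel_alignment(gaussian_kernel(v[, 1]), K, centered = TRUE))
})

test_that("a feature whose kernel equals the target dominates the weights", {
  withr::with_seed(10, {
    v1 <- rnorm(20)
    noise <- matrix(rnorm(20 * 4), 20, 4)
  })
  x <- cbind(v1, noise)
  colnames(x) <- paste0("f", 1:5)
  target <- gaussian_kernel(matrix(v1, 20, 1))
  w <- fit_alignment_weights(x, target)
  expect_gte(w$mu[["f1"]], 0.9)
  # exhaustive uniform-weight subsets confirm {f1} is the best subset
  Kz <- target
  best <- -Inf; best_set <- NULL
  for (m in 1:31) {
    subset <- which(as.logical(intToBits(m)[1:5]))
    al <- subset_alignment(x, subset, Kz)
    if (al > best) { best <- al; best_set <- subset }
  }
  expect_equal(best_set, 1L)
  expect_gte(w$objective, best - 1e-6)
})

test_that("identical features receive uniform weights", {
  withr::with_seed(11, v <- rnorm(12))
  x <- cbind(v, v, v)
  colnames(x) <- paste0("f", 1:3)
  withr::with_seed(12, z <- matrix(rnorm(24), 12, 2))
  K <- gaussian_kernel(z)
  w <- fit_alignment_weights(x, K)
  expect_equal(unname(w$mu), rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(w$objective,
               kernel_alignment(gaussian_kernel(v), K, centered = TRUE),
               tolerance = 1e-10)
})

test_that("optimiser is not beaten by any uniform-weight subset (small instances)", {
  for (s in 0:9) {
    withr::with_seed(s, {
      n <- sample(8:15, 1)
      d <- sample(2:5, 1)
      x <- matrix(rnorm(n * d), n, d)
      z <- matrix(rnorm(n * 2), n, 2)
    })
    colnames(x) <- paste0("f", seq_len(d))
    Kz <- gaussian_kernel(z)
    w <- fit_alignment_weights(x, Kz)
    expect_gte(w$objective, best_subset_alignment(x, Kz) - 1e-6)
  }
})

test_that("selection rules and their edge cases behave as specified", {
  mu <- c(a = 0.5, b = 0, c = 0.2)
  sel <- select_features(mu, rule = "nonzero", epsilon = 1e-6)
  expect_equal(sel$selected, c(TRUE, FALSE, TRUE))
  expect_equal(attr(sel, "p"), 2L)
  sel2 <- select_features(c(a = 0.1, b = 0.7, c = 0.2), rule = "top_p",
                          p = 1)
  expect_equal(selected_genes(sel2), "b")
  # ties break to the lower index
  sel3 <- select_features(c(a = 0.4, b = 0.4, c = 0.2), rule = "top_p",
                          p = 1)
  expect_equal(selected_genes(sel3), "a")
  expect_error(select_features(c(a = 1, b = 1), rule = "nonzero"),
               "top_p")
})

test_that("selected subsets align better than random subsets of equal size", {
  wins <- 0L
  for (s in 1:10) {
    gen <- small_planted(seed = s, n = 15, d = 40, n_inf = 4)
    lg <- log_transform(gen$data)
    x <- expr_matrix(lg)
    pc <- pca_reduce(lg, n_components = 10)
    emb <- encode(fit_latent(pc$scores, "pca", latent_dim = 4), pc$scores)
    Kz <- gaussian_kernel(emb)
    w <- fit_alignment_weights(x, Kz)
    sel <- select_features(w, "top_p", p = 8)
    a_sel <- subset_alignment(x, which(sel$selected), Kz)
    rand <- withr::with_seed(100 + s, sample(ncol(x), 8))
    a_rand <- subset_alignment(x, rand, Kz)
    wins <- wins + (a_sel >= a_rand)
  }
  expect_gte(wins, 9L)
})

test_that("selection JSON round-trips weights by gene", {
  sel <- select_features(c(g1 = 0.6, g2 = 0.3, g3 = 0.1), "top_p", p = 2)
  path <- withr::local_tempfile(fileext = ".json")
  lst <- withr::local_tempfile(fileext = ".txt")
  write_selection(sel, path, lst)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back), c(g1 = 0.6, g2 = 0.3, g3 = 0.1))
  expect_equal(readLines(lst), c("g1", "g2"))
})
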