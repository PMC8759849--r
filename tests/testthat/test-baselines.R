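make_ds <- function(x, y) {
  colnames(x) <- colnames(x) %||% sprintf("g%02d", seq_len(ncol(x)))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("s%03d", seq_len(nrow(x))),
                   label = as.character(y)),
    tibble::as_tibble(as.data.frame(x)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("information gain closed forms and independence behaviour", {
  withr::with_seed(1, {
    y <- rep(c("a", "b"), each = 50)
    ind <- as.numeric(y == "a")
    noise <- runif(100)
  })
  ds <- make_ds(cbind(const = 1, indicator = ind, noise = noise), y)
  ig <- information_gain(ds, bins = 10)
  s <- setNames(ig$score, ig$gene)
  expect_equal(s[["const"]], 0)
  expect_equal(s[["indicator"]], 1.0, tolerance = 1e-12)
  expect_true(all(ig$score >= 0))
  # a feature independent of labels at n = 1000 carries < 0.05 bits
  withr::with_seed(2, {
    y2 <- rep(c("a", "b"), each = 500)
    f <- rnorm(1000)
  })
  ig2 <- information_gain(make_ds(cbind(f = f), y2))
  expect_lt(ig2$score[1], 0.05)
  expect_error(information_gain(ds, bins = 1), "bins")
})

test_that("mRMR formula arithmetic and greedy trajectory match brute force", {
  # formula spot check: F = 9, mean|rho| = 0.9
  expect_equal(9 - 0.9, 8.1)
  expect_equal(9 / 0.9, 10, tolerance = 1e-12)
  withr::with_seed(3, {
    y <- rep(c("a", "b"), each = 20)
    sig <- as.numeric(y == "a") * 2 + rnorm(40, sd = 0.5)
    x <- cbind(sig, sig + rnorm(40, sd = 0.1),
               matrix(rnorm(40 * 6), 40, 6))
  })
  ds <- make_ds(x, y)
  # k = 1 is the max-F feature
  f <- ktafs:::anova_f(expr_matrix(ds), factor(y))
  sel1 <- mrmr_select(ds, k = 1)
  expect_equal(selected_genes(sel1), gene_names(ds)[which.max(f)])
  # greedy MID trajectory equals step-by-step brute-force recomputation
  sel <- mrmr_select(ds, k = 3, criterion = "MID")
  traj <- attr(sel, "trajectory")
  xm <- expr_matrix(ds)
  chosen <- integer(0)
  for (step in 1:3) {
    cand <- setdiff(seq_len(ncol(xm)), chosen)
    sc <- sapply(cand, function(j) {
      if (length(chosen) == 0) f[j] else
        f[j] - mean(abs(cor(xm[, j], xm[, chosen, drop = FALSE])))
    })
    pick <- cand[which.max(sc)]
    expect_equal(traj$gene[step], colnames(xm)[pick])
    expect_equal(traj$score[step], max(sc), tolerance = 1e-10)
    chosen <- c(chosen, pick)
  }
})

test_that("duplicating a selected feature cannot raise its MID score", {
  withr::with_seed(4, {
    y <- rep(c("a", "b"), each = 15)
    x <- matrix(rnorm(30 * 4), 30, 4)
  })
  ds <- make_ds(x, y)
  f <- ktafs:::anova_f(expr_matrix(ds), factor(y))
  xm <- expr_matrix(ds)
  sel <- c(1L)
  mid <- function(j, S) f[j] - mean(abs(cor(xm[, j], xm[, S, drop = FALSE])))
  # adding an exact duplicate of the selected feature to S can only
  # increase mean redundancy of every remaining candidate
  for (j in 2:4) {
    expect_lte(mid(j, c(1L, 1L)), mid(j, 1L) + 1e-12)
  }
})

test_that("relief weights match hand enumeration and the neighbour oracle", {
  # 1-D: values [0,0,1,1], labels [0,0,1,1] -> weight exactly 1
  ds <- make_ds(matrix(c(0, 0, 1, 1), 4, 1), c("a", "a", "b", "b"))
  w <- relief_weights(ds, variant = "relief_d")
  expect_equal(w$score[1], 1.0)
  # constant feature gets zero weight
  ds2 <- make_ds(cbind(c(0, 0, 1, 1), 5), c("a", "a", "b", "b"))
  w2 <- relief_weights(ds2, variant = "relief_d")
  expect_equal(setNames(w2$score, w2$gene)[["g02"]], 0)

  # indicator vs noise on n = 40, checked against an independent
  # all-instances enumeration of nearest hits and misses
  withr::with_seed(5, {
    y <- rep(c("a", "b"), each = 20)
    ind <- as.numeric(y == "a")
    noise <- runif(40)
  })
  x <- cbind(ind = ind, noise = noise)
  ds3 <- make_ds(x, y)
  got <- relief_weights(ds3, variant = "relief_d")
  # oracle: range-normalise, enumerate every instance
  xn <- apply(x, 2, function(v) v / (max(v) - min(v)))
  n <- nrow(xn)
  wo <- c(0, 0)
  for (i in seq_len(n)) {
    dists <- rowSums(abs(sweep(xn, 2, xn[i, ])))
    dists[i] <- Inf
    hit <- which(y == y[i] & seq_len(n) != i)
    hit <- hit[which.min(dists[hit])]
    miss <- which(y != y[i])
    miss <- miss[which.min(dists[miss])]
    # two balanced classes: prior weight P(miss)/(1-P(own)) = 1
    wo <- wo + (abs(xn[miss, ] - xn[i, ]) - abs(xn[hit, ] - xn[i, ]))
  }
  wo <- wo / n
  expect_equal(setNames(got$score, got$gene),
               setNames(wo, c("ind", "noise")), tolerance = 1e-12)
  expect_gt(setNames(got$score, got$gene)[["ind"]],
            setNames(got$score, got$gene)[["noise"]])
})

test_that("relief_f is seed-deterministic and sample-order stable", {
  gen <- small_planted(seed = 6, n = 12, d = 15)
  lg <- log_transform(gen$data)
  a <- relief_weights(lg, "relief_f", iterations = 30, seed = 3)
  b <- relief_weights(lg, "relief_f", iterations = 30, seed = 3)
  expect_equal(a$score, b$score)
  # relief_d invariant to sample order
  perm <- withr::with_seed(9, sample(nrow(lg)))
  d1 <- relief_weights(lg, "relief_d")
  d2 <- relief_weights(lg[perm, ], "relief_d")
  expect_equal(setNames(d1$score, d1$gene), setNames(d2$score, d2$gene),
               tolerance = 1e-12)
})

test_that("CFS merit formula and exhaustive best-first optimality", {
  # |S| = 1 reduces to the feature-class correlation
  withr::with_seed(7, {
    y <- rep(c("a", "b"), each = 12)
    f1 <- as.numeric(y == "a") + rnorm(24, sd = 0.4)
  })
  ds1 <- make_ds(cbind(f1 = f1, f2 = rnorm(24)), y)
  r <- abs(cor(f1, as.numeric(y == "a")))
  expect_equal(cfs_merit(ds1, "f1"), r, tolerance = 1e-12)
  # k = 2, rcf = 0.5, rff = 1 -> merit 0.5 (direct arithmetic)
  expect_equal(2 * 0.5 / sqrt(2 + 2 * 1 * 1), 0.5)

  # best-first ties the exhaustive optimum over all 63 subsets (d = 6)
  withr::with_seed(8, {
    y2 <- rep(c("a", "b"), each = 15)
    base <- as.numeric(y2 == "a")
    x <- cbind(base + rnorm(30, sd = 0.5), base + rnorm(30, sd = 0.7),
               matrix(rnorm(30 * 4), 30, 4))
  })
  ds <- make_ds(x, y2)
  sel <- cfs_select(ds, search = "best_first")
  best <- -Inf
  for (m in 1:63) {
    subset <- gene_names(ds)[as.logical(intToBits(m)[1:6])]
    best <- max(best, cfs_merit(ds, subset))
  }
  expect_equal(attr(sel, "merit"), best, tolerance = 1e-10)
  # merit magnitude bound
  rcf <- ktafs:::class_correlations(expr_matrix(ds), factor(y2))
  k <- attr(sel, "p")
  expect_lte(abs(attr(sel, "merit")), max(rcf) * sqrt(k) + 1e-12)
})
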