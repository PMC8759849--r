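# Shared fixtures built in code.

# Small labelled dataset with planted informative genes.
small_planted <- function(seed = 1, n = 30, d = 60, n_inf = 5) {
  generate_dataset(n_per_class = c(n, n), d = d, n_informative = n_inf,
                   seed = seed)
}

# Linearly separable two-class matrix fixture for the classifier.
separable_fixture <- function(seed = 0, n_per_class = 30, d = 20,
                              shift = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d, 0), n_per_class, d),
               matrix(rnorm(n_per_class * d, shift), n_per_class, d))
    colnames(x) <- sprintf("g%03d", seq_len(d))
    list(x = x, y = rep(c("a", "b"), each = n_per_class))
  })
}

# The published two-class evaluation blocks: confusion proportions over 33
# validation samples plus the printed 2-decimal report cells
# (rows: class0 P/R/F1, class1 P/R/F1, accuracy, macro P/R/F1,
#  weighted P/R/F1).
published_blocks <- function() {
  blk <- function(P, vals) list(P = P, printed = vals)
  list(
    decision_tree = blk(
      rbind(c(0.09, 0.09), c(0.15, 0.67)),
      list(class = rbind(c(0.38, 0.50, 0.43), c(0.88, 0.81, 0.85)),
           accuracy = 0.76, macro = c(0.63, 0.66, 0.64),
           weighted = c(0.79, 0.76, 0.77))),
    random_forest = blk(
      rbind(c(0.00, 0.18), c(0.00, 0.82)),
      list(class = rbind(c(0.00, 0.00, 0.00), c(0.82, 1.00, 0.90)),
           accuracy = 0.82, macro = c(0.41, 0.50, 0.45),
           weighted = c(0.67, 0.82, 0.74))),
    gaussian_nb = blk(
      rbind(c(0.03, 0.15), c(0.00, 0.82)),
      list(class = rbind(c(1.00, 0.17, 0.29), c(0.84, 1.00, 0.92)),
           accuracy = 0.85, macro = c(0.92, 0.58, 0.60),
           weighted = c(0.87, 0.85, 0.80))),
    gradient_logistic = blk(
      rbind(c(0.15, 0.03), c(0.09, 0.73)),
      list(class = rbind(c(0.62, 0.83, 0.71), c(0.96, 0.89, 0.92)),
           accuracy = 0.88, macro = c(0.79, 0.86, 0.82),
           weighted = c(0.90, 0.88, 0.89))),
    gradient_hinge = blk(
      rbind(c(0.00, 0.18), c(0.00, 0.82)),
      list(class = rbind(c(0.00, 0.00, 0.00), c(0.82, 1.00, 0.90)),
           accuracy = 0.82, macro = c(0.41, 0.50, 0.45),
           weighted = c(0.67, 0.82, 0.74))),
    svm = blk(
      rbind(c(0.12, 0.06), c(0.03, 0.79)),
      list(class = rbind(c(0.80, 0.67, 0.73), c(0.93, 0.96, 0.95)),
           accuracy = 0.91, macro = c(0.86, 0.81, 0.84),
           weighted = c(0.91, 0.91, 0.91))),
    mlp_adam = blk(
      rbind(c(0.18, 0.00), c(0.82, 0.00)),
      list(class = rbind(c(0.18, 1.00, 0.31), c(0.00, 0.00, 0.00)),
           accuracy = 0.18, macro = c(0.09, 0.50, 0.15),
           weighted = c(0.03, 0.18, 0.06))),
    mlp_lbfgs = blk(
      rbind(c(0.00, 0.18), c(0.00, 0.82)),
      list(class = rbind(c(0.00, 0.00, 0.00), c(0.82, 1.00, 0.90)),
           accuracy = 0.82, macro = c(0.41, 0.50, 0.45),
           weighted = c(0.67, 0.82, 0.74))))
}

# Round a report to 2 decimals in the same shape as `printed` above.
rounded_report <- function(rep) {
  b <- rep$by_class
  list(class = cbind(round(b$precision, 2), round(b$recall, 2),
                     round(b$f1, 2)),
       accuracy = round(rep$accuracy, 2),
       macro = round(unname(rep$macro_avg), 2),
       weighted = round(unname(rep$weighted_avg), 2))
}

# Independent centered-alignment of a uniform-weight feature subset,
# computed from scratch (no optimiser code shared).
subset_alignment <- function(x, subset, Kz) {
  n <- nrow(x)
  Ksum <- matrix(0, n, n)
  for (f in subset) {
    v <- x[, f]
    dd <- abs(outer(v, v, `-`))
    med <- stats::median(dd[upper.tri(dd)])
    g <- if (med > 0) 1 / (2 * med^2) else 0
    Ksum <- Ksum + if (g > 0) exp(-g * dd^2) else matrix(1, n, n)
  }
  kernel_alignment(Ksum, Kz, centered = TRUE)
}

# Best uniform-weight subset alignment by exhaustive enumeration.
best_subset_alignment <- function(x, Kz) {
  d <- ncol(x)
  best <- -Inf
  for (m in seq_len(2^d - 1)) {
    subset <- which(as.logical(intToBits(m)[seq_len(d)]))
    best <- max(best, subset_alignment(x, subset, Kz))
  }
  best
}
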