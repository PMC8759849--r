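#' Train a 1-D convolutional softmax classifier
#'
#' Each sample's gene vector is treated as a length-d single-channel 1-D
#' signal. The architecture is a single convolution (`channels` filters of
#' width `kernel_size`) -> ReLU -> max pooling (`pool_size`) -> flatten ->
#' fully-connected softmax over the classes. Training is mini-batch
#' cross-entropy minimisation with Adam and decoupled weight decay; an
#' internal stratified train/validation split (`train_valid_split`) drives
#' early stopping: after `patience` epochs without a validation-loss
#' improvement, training stops and the best-epoch weights are restored.
#'
#' Default hyperparameters: 32 channels, kernel width 5, pool 2, 60 epochs,
#' batch 10, weight decay 1e-8, patience 10, no dropout.
#'
#' @param data Labelled dataset tibble (or numeric matrix with `labels`).
#' @param labels Class labels when `data` is a matrix.
#' @param channels,kernel_size,pool_size Convolution/pooling geometry.
#' @param epochs,batch_size,learning_rate,weight_decay Optimisation controls.
#' @param patience Early-stopping patience in epochs (capped at `epochs`).
#' @param train_valid_split Fraction of the data kept for fitting; the rest
#'   is the internal validation set (default 0.5). Set to 1 to disable early
#'   stopping.
#' @param dropout Apply dropout (p = 0.5) to the flattened layer (default
#'   FALSE).
#' @param standardize Standardise features with training statistics (default
#'   TRUE).
#' @param seed Integer seed (initialisation, batching, split).
#' @return A `cnn_model` with weights, `class_names`, a per-epoch
#'   `loss_trace` (train and validation loss), and the config echo.
#' @export
train_cnn <- function(data, labels = NULL, channels = 32L, kernel_size = 5L,
                      pool_size = 2L, epochs = 60L, batch_size = 10L,
                      learning_rate = 1e-3, weight_decay = 1e-8,
                      patience = 10L, train_valid_split = 0.5,
                      dropout = FALSE, standardize = TRUE, seed = 1L) {
  if (is.data.frame(data)) {
    x <- expr_matrix(data)
    y <- dataset_labels(data)
  } else {
    x <- as.matrix(data)
    if (is.null(labels)) abort("labels required for matrix input")
    y <- if (is.factor(labels)) factor(labels) else
      factor(labels, levels = unique(labels))
  }
  if (nlevels(y) < 2L) abort("training needs at least 2 classes")
  if (ncol(x) < kernel_size) {
    abort(sprintf("feature count %d is smaller than kernel_size %d",
                  ncol(x), kernel_size))
  }
  stopifnot(train_valid_split > 0, train_valid_split <= 1)
  cfg <- list(channels = channels, kernel_size = kernel_size,
              pool_size = pool_size, epochs = epochs,
              batch_size = batch_size, learning_rate = learning_rate,
              weight_decay = weight_decay, patience = patience,
              train_valid_split = train_valid_split, dropout = dropout,
              standardize = standardize, seed = seed)
  patience <- min(patience, epochs)
  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) pmax(apply(x, 2, stats::sd), 1e-8) else
    rep(1, ncol(x))
  xs <- scale(x, center = ctr, scale = scl)
  C <- nlevels(y)
  d <- ncol(x)
  Tc <- d - kernel_size + 1L                # conv output length
  Tp <- Tc %/% pool_size                    # pooled length
  if (Tp < 1L) abort("pool_size too large for this feature count")
  yi <- as.integer(y)

  with_seed(seed, {
    # internal stratified split (largest-remainder quotas, seeded shuffle)
    use_valid <- train_valid_split < 1 && all(table(y) >= 2)
    if (use_valid) {
      counts <- table(y)
      quota <- largest_remainder(as.numeric(counts) * train_valid_split,
                                 round(train_valid_split * nrow(xs)))
      names(quota) <- names(counts)
      idx_tr <- sort(unlist(lapply(names(counts), function(cl) {
        ids <- which(as.character(y) == cl)
        sample(ids)[seq_len(quota[[cl]])]
      }), use.names = FALSE))
      idx_va <- setdiff(seq_len(nrow(xs)), idx_tr)
      if (length(idx_va) == 0L || nlevels(droplevels(y[idx_tr])) < C) {
        use_valid <- FALSE
      }
    }
    if (!use_valid) {
      idx_tr <- seq_len(nrow(xs)); idx_va <- integer(0)
    }
    W1 <- matrix(rnorm(kernel_size * channels,
                       sd = sqrt(2 / kernel_size)), kernel_size, channels)
    b1 <- numeric(channels)
    W2 <- matrix(rnorm(Tp * channels * C, sd = sqrt(2 / (Tp * channels))),
                 Tp * channels, C)
    b2 <- numeric(C)
    adam <- adam_state(list(W1, b1, W2, b2))
    best <- list(loss = Inf, W1 = W1, b1 = b1, W2 = W2, b2 = b2, epoch = 0L)
    wait <- 0L
    trace <- list()
    xtr <- xs[idx_tr, , drop = FALSE]; ytr <- yi[idx_tr]
    for (ep in seq_len(epochs)) {
      ord <- sample(length(ytr))
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (bi in batches) {
        fw <- cnn_forward(xtr[bi, , drop = FALSE], W1, b1, W2, b2,
                          kernel_size, pool_size,
                          dropout_p = if (dropout) 0.5 else 0)
        ep_loss <- ep_loss + fw$ce_loss(ytr[bi]) * length(bi)
        gr <- cnn_backward(fw, ytr[bi], W1, W2, kernel_size, pool_size)
        upd <- adam_step(adam, gr, learning_rate,
                         weight_decay = weight_decay,
                         params = list(W1, b1 * 0, W2, b2 * 0))
        adam <- upd$state
        W1 <- W1 - upd$delta[[1]]; b1 <- b1 - upd$delta[[2]]
        W2 <- W2 - upd$delta[[3]]; b2 <- b2 - upd$delta[[4]]
      }
      train_loss <- ep_loss / length(ytr)
      valid_loss <- NA_real_
      if (use_valid) {
        fv <- cnn_forward(xs[idx_va, , drop = FALSE], W1, b1, W2, b2,
                          kernel_size, pool_size, dropout_p = 0)
        valid_loss <- fv$ce_loss(yi[idx_va])
      }
      trace[[ep]] <- tibble(epoch = ep, train_loss = train_loss,
                            valid_loss = valid_loss)
      monitor <- if (use_valid) valid_loss else train_loss
      if (monitor < best$loss - 1e-12) {
        best <- list(loss = monitor, W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                     epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (use_valid && wait >= patience) break
      }
    }
    structure(
      list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
           center = ctr, scale = scl, class_names = levels(y),
           kernel_size = kernel_size, pool_size = pool_size,
           input_dim = d, best_epoch = best$epoch,
           best_valid_loss = if (use_valid) best$loss else NA_real_,
           loss_trace = bind_rows(trace), config = cfg),
      class = "cnn_model")
  })
}

# Forward pass. Conv as im2col matrix product; returns cached activations
# and a closure computing mean cross-entropy for integer labels.
cnn_forward <- function(x, W1, b1, W2, b2, ks, ps, dropout_p = 0) {
  B <- nrow(x); d <- ncol(x)
  Tc <- d - ks + 1L; Tp <- Tc %/% ps; Ch <- ncol(W1)
  cols <- im2col(x, ks)                       # (B*Tc) x ks
  z1 <- sweep(cols %*% W1, 2, b1, `+`)        # (B*Tc) x Ch
  a1 <- pmax(z1, 0)
  # pool over windows of ps along the Tc axis, per sample and channel
  a1a <- array(a1, dim = c(Tc, B, Ch))        # im2col emits position-major
  keep <- seq_len(Tp * ps)
  wins <- matrix(array(a1a[keep, , , drop = FALSE],
                       dim = c(ps, Tp, B, Ch)), nrow = ps)
  pooledv <- do.call(pmax, lapply(seq_len(ps), function(i) wins[i, ]))
  argmx <- max.col(t(wins), ties.method = "first")     # window-local argmax
  pooled <- array(pooledv, dim = c(Tp, B, Ch))
  flat <- matrix(aperm(pooled, c(2, 1, 3)), nrow = B)  # B x (Tp*Ch)
  dmask <- NULL
  if (dropout_p > 0) {
    dmask <- matrix(runif(length(flat)) >= dropout_p, nrow(flat), ncol(flat))
    flat <- flat * dmask / (1 - dropout_p)
  }
  logits <- sweep(flat %*% W2, 2, b2, `+`)
  logits <- logits - apply(logits, 1, max)
  expl <- exp(logits)
  probs <- expl / rowSums(expl)
  list(x = x, cols = cols, z1 = z1, argmx = argmx, flat = flat,
       dmask = dmask, dropout_p = dropout_p, probs = probs,
       B = B, Tc = Tc, Tp = Tp, Ch = Ch,
       ce_loss = function(yidx) {
         -mean(log(pmax(probs[cbind(seq_len(B), yidx)], 1e-12)))
       })
}

im2col <- function(x, ks) {
  B <- nrow(x); d <- ncol(x); Tc <- d - ks + 1L
  out <- matrix(0, B * Tc, ks)
  for (j in seq_len(ks)) {
    # row-block layout: position-major within sample handled via t()
    out[, j] <- as.vector(t(x[, j:(j + Tc - 1L), drop = FALSE]))
  }
  out
}

cnn_backward <- function(fw, yidx, W1, W2, ks, ps) {
  B <- fw$B; Tc <- fw$Tc; Tp <- fw$Tp; Ch <- fw$Ch
  dlogits <- fw$probs
  dlogits[cbind(seq_len(B), yidx)] <- dlogits[cbind(seq_len(B), yidx)] - 1
  dlogits <- dlogits / B
  gW2 <- crossprod(fw$flat, dlogits)
  gb2 <- colSums(dlogits)
  dflat <- dlogits %*% t(W2)
  if (!is.null(fw$dmask)) dflat <- dflat * fw$dmask / (1 - fw$dropout_p)
  dpool <- aperm(array(dflat, dim = c(B, Tp, Ch)), c(2, 1, 3)) # Tp x B x Ch
  # route gradient to the argmax position inside each pooling window
  da1 <- array(0, dim = c(Tc, B, Ch))
  off <- (seq_len(Tp) - 1L) * ps
  idx <- as.vector(outer(off, as.vector(outer((seq_len(B) - 1L) * Tc,
         (seq_len(Ch) - 1L) * Tc * B, `+`)), `+`)) + as.vector(fw$argmx)
  da1[idx] <- as.vector(dpool)
  da1 <- matrix(da1, B * Tc, Ch) * (fw$z1 > 0)
  gW1 <- crossprod(fw$cols, da1)
  gb1 <- colSums(da1)
  list(gW1, gb1, gW2, gb2)
}

#' Class probabilities from a trained CNN
#'
#' @param model A `cnn_model`.
#' @param data Dataset tibble or numeric matrix with the training genes.
#' @return Samples-by-classes matrix of softmax probabilities (rows sum
#'   to 1).
#' @export
predict_proba <- function(model, data) {
  x <- if (is.data.frame(data)) expr_matrix(data) else as.matrix(data)
  if (ncol(x) != model$input_dim) {
    abort(sprintf("input has %d features, model expects %d",
                  ncol(x), model$input_dim))
  }
  xs <- scale(x, center = model$center, scale = model$scale)
  fw <- cnn_forward(xs, model$W1, model$b1, model$W2, model$b2,
                    model$kernel_size, model$pool_size, dropout_p = 0)
  p <- fw$probs
  colnames(p) <- model$class_names
  p
}

#' @export
predict.cnn_model <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  factor(object$class_names[max.col(p, ties.method = "first")],
         levels = object$class_names)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "1-D CNN: %d features -> conv(%d x %d) -> relu -> pool(%d) -> softmax(%d)\n",
    x$input_dim, x$config$channels, x$kernel_size, x$pool_size,
    length(x$class_names)))
  cat(sprintf("trained %d epochs (best epoch %d)\n",
              nrow(x$loss_trace), x$best_epoch))
  invisible(x)
}

#' @method glance cnn_model
#' @export
glance.cnn_model <- function(x, ...) {
  tibble(epochs_run = nrow(x$loss_trace), best_epoch = x$best_epoch,
         best_valid_loss = x$best_valid_loss,
         final_train_loss = x$loss_trace$train_loss[nrow(x$loss_trace)])
}

#' @method autoplot cnn_model
#' @export
autoplot.cnn_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$loss_trace, -"epoch",
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df[!is.na(df$loss), ],
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "CNN training trace")
}

#' Repeated stratified k-fold cross-validation of the CNN
#'
#' Splits the samples into `k` stratified folds, trains on k-1 and evaluates
#' on the held-out fold, and repeats the whole procedure `repeats` times
#' with reshuffled folds — `k * repeats` fold results in total (the default
#' 2 x 3 mirrors twofold cross-validation performed three times).
#'
#' @param data Labelled dataset tibble.
#' @param k Folds (default 2; no class may be smaller than `k`).
#' @param repeats Whole-procedure repetitions (default 3).
#' @param seed Integer seed; each repeat derives its own fold shuffle and
#'   training seed.
#' @param ... Passed to [train_cnn()].
#' @return A `cv_result`: `folds` (tibble with repeat, fold, accuracy and a
#'   list-column of `classification_report`s) and `summary` (mean/sd and
#'   per-repeat means).
#' @export
cross_validate <- function(data, k = 2L, repeats = 3L, seed = 1L, ...) {
  validate_dataset(data, require_label = TRUE, allow_negative = TRUE)
  y <- dataset_labels(data)
  if (k > min(table(y))) {
    abort(sprintf("k = %d exceeds the smallest class size %d", k,
                  min(table(y))))
  }
  rows <- list()
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(y, k, seed = seed + 1000L * r)
    for (f in seq_len(k)) {
      tr <- fold_id != f
      model <- train_cnn(data[tr, , drop = FALSE],
                         seed = seed + 1000L * r + f, ...)
      pred <- predict(model, data[!tr, , drop = FALSE])
      truth <- factor(as.character(y[!tr]), levels = levels(y))
      cm <- confusion_matrix(truth, factor(pred, levels = levels(y)))
      rows[[length(rows) + 1L]] <- tibble(
        repeat_id = r, fold = f,
        accuracy = sum(diag(cm$counts)) / sum(cm$counts),
        report = list(classification_report(cm)))
    }
  }
  folds <- bind_rows(rows)
  per_repeat <- folds |> group_by(.data$repeat_id) |>
    summarise(accuracy = mean(.data$accuracy), .groups = "drop")
  structure(list(
    folds = folds,
    summary = tibble(mean_accuracy = mean(folds$accuracy),
                     sd_accuracy = stats::sd(folds$accuracy),
                     k = k, repeats = repeats),
    per_repeat = per_repeat), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repeats: mean accuracy %.3f (sd %.3f)\n",
              x$summary$k, x$summary$repeats, x$summary$mean_accuracy,
              x$summary$sd_accuracy))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::select(x$folds, "repeat_id", "fold", "accuracy")
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  bind_cols(x$summary,
            tidyr::pivot_wider(x$per_repeat, names_from = "repeat_id",
                               values_from = "accuracy",
                               names_prefix = "repeat_"))
}

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$repeat_id),
                                   y = .data$accuracy)) +
    ggplot2::geom_point(ggplot2::aes(shape = factor(.data$fold)), size = 3) +
    ggplot2::geom_hline(yintercept = object$summary$mean_accuracy,
                        linetype = 2) +
    ggplot2::labs(x = "repeat", shape = "fold",
                  title = "cross-validated accuracy per fold")
}
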