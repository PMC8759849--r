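#' Fit a latent representation
#'
#' Learns a low-dimensional embedding of samples that later serves as the
#' target similarity structure for alignment-based gene selection. Two
#' backends are provided:
#'
#' * `"pca"` — linear projection onto the leading principal components
#'   (sign-fixed, fully deterministic); the default, and the backend used in
#'   all deterministic end-to-end checks.
#' * `"autoencoder"` — a symmetric multilayer perceptron
#'   `d -> hidden -> l -> hidden -> d` with tanh hidden activations and
#'   linear bottleneck/output, trained full-batch to minimise mean squared
#'   reconstruction error with Adam. Seed-deterministic.
#'
#' @param data Numeric samples-by-features matrix, or a tibble of scores
#'   (e.g. the `scores` from [pca_reduce()]); metadata columns are dropped.
#' @param backend `"pca"` or `"autoencoder"`.
#' @param latent_dim Latent dimension `l` (default 64, capped at the input
#'   dimension for pca; must satisfy `l <= d`).
#' @param hidden_dim Autoencoder hidden width (default 128).
#' @param epochs Autoencoder training epochs (default 200).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed (weight initialisation).
#' @return A `latent_model` exposing [encode()]; autoencoder models carry a
#'   per-epoch `loss_trace`.
#' @export
fit_latent <- function(data, backend = c("pca", "autoencoder"),
                       latent_dim = 64, hidden_dim = 128, epochs = 200,
                       learning_rate = 1e-3, seed = 1L) {
  backend <- match.arg(backend)
  x <- latent_input(data)
  stopifnot(latent_dim >= 1, epochs >= 1)
  if (latent_dim > ncol(x)) {
    abort(sprintf("latent_dim %d exceeds input dimension %d",
                  latent_dim, ncol(x)))
  }
  if (any(!is.finite(x))) abort("latent input must be finite")
  model <- switch(backend,
    pca = fit_latent_pca(x, latent_dim),
    autoencoder = fit_latent_ae(x, latent_dim, hidden_dim, epochs,
                                learning_rate, seed))
  model$backend <- backend
  model$latent_dim <- latent_dim
  model$input_dim <- ncol(x)
  class(model) <- "latent_model"
  model
}

latent_input <- function(data) {
  if (is.data.frame(data)) {
    keep <- setdiff(names(data), c("sample_id", "label"))
    as.matrix(as.data.frame(data)[, keep, drop = FALSE])
  } else {
    as.matrix(data)
  }
}

fit_latent_pca <- function(x, l) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc, nu = 0, nv = min(l, ncol(x)))
  rot <- fix_signs(sv$v[, seq_len(l), drop = FALSE])
  list(kind = "pca", rotation = rot, center = ctr)
}

fit_latent_ae <- function(x, l, hidden, epochs, lr, seed) {
  d <- ncol(x); n <- nrow(x)
  # center/scale inputs so MSE is comparable across features
  ctr <- colMeans(x)
  scl <- pmax(apply(x, 2, stats::sd), 1e-8)
  xs <- scale(x, center = ctr, scale = scl)
  init <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(1 / nin)),
                                     nin, nout)
  with_seed(seed, {
    W <- list(init(d, hidden), init(hidden, l), init(l, hidden),
              init(hidden, d))
    b <- list(numeric(hidden), numeric(l), numeric(hidden), numeric(d))
    adam <- adam_state(c(W, b))
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      h1 <- tanh(sweep(xs %*% W[[1]], 2, b[[1]], `+`))
      z  <- sweep(h1 %*% W[[2]], 2, b[[2]], `+`)
      h2 <- tanh(sweep(z %*% W[[3]], 2, b[[3]], `+`))
      xhat <- sweep(h2 %*% W[[4]], 2, b[[4]], `+`)
      err <- xhat - xs
      trace[ep] <- mean(err^2)
      g <- 2 * err / (n * d)
      gW4 <- crossprod(h2, g);           gb4 <- colSums(g)
      dh2 <- (g %*% t(W[[4]])) * (1 - h2^2)
      gW3 <- crossprod(z, dh2);          gb3 <- colSums(dh2)
      dz <- dh2 %*% t(W[[3]])
      gW2 <- crossprod(h1, dz);          gb2 <- colSums(dz)
      dh1 <- (dz %*% t(W[[2]])) * (1 - h1^2)
      gW1 <- crossprod(xs, dh1);         gb1 <- colSums(dh1)
      upd <- adam_step(adam, list(gW1, gW2, gW3, gW4, gb1, gb2, gb3, gb4), lr)
      adam <- upd$state
      W <- list(W[[1]] - upd$delta[[1]], W[[2]] - upd$delta[[2]],
                W[[3]] - upd$delta[[3]], W[[4]] - upd$delta[[4]])
      b <- list(b[[1]] - upd$delta[[5]], b[[2]] - upd$delta[[6]],
                b[[3]] - upd$delta[[7]], b[[4]] - upd$delta[[8]])
    }
    list(kind = "autoencoder", W = W, b = b, center = ctr, scale = scl,
         loss_trace = tibble(epoch = seq_len(epochs), mse = trace))
  })
}

# Minimal Adam optimiser over a list of parameter arrays.
adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0, params = NULL) {
  state$t <- state$t + 1L
  delta <- vector("list", length(grads))
  for (i in seq_along(grads)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    delta[[i]] <- lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && !is.null(params)) {
      delta[[i]] <- delta[[i]] + lr * weight_decay * params[[i]]
    }
  }
  list(state = state, delta = delta)
}

#' Encode samples into the latent space
#'
#' @param model A `latent_model` from [fit_latent()].
#' @param data Matrix or tibble with the training feature columns.
#' @return Samples-by-`latent_dim` numeric matrix; bit-for-bit repeatable for
#'   the same model and input.
#' @export
encode <- function(model, data) UseMethod("encode")

#' @export
encode.latent_model <- function(model, data) {
  x <- latent_input(data)
  if (ncol(x) != model$input_dim) {
    abort(sprintf("input has %d features, model expects %d",
                  ncol(x), model$input_dim))
  }
  if (model$kind == "pca") {
    z <- sweep(x, 2, model$center) %*% model$rotation
  } else {
    xs <- scale(x, center = model$center, scale = model$scale)
    h1 <- tanh(sweep(xs %*% model$W[[1]], 2, model$b[[1]], `+`))
    z <- sweep(h1 %*% model$W[[2]], 2, model$b[[2]], `+`)
  }
  colnames(z) <- paste0("L", seq_len(ncol(z)))
  z
}

#' Decode latent coordinates back to the input space
#'
#' For the pca backend this is the transpose projection; for the autoencoder
#' the decoder half of the network (returned on the original input scale).
#'
#' @inheritParams encode
#' @param z Samples-by-`latent_dim` matrix.
#' @return Reconstruction matrix, samples by input features.
#' @export
decode <- function(model, z) {
  z <- as.matrix(z)
  if (model$kind == "pca") {
    sweep(z %*% t(model$rotation), 2, model$center, `+`)
  } else {
    h2 <- tanh(sweep(z %*% model$W[[3]], 2, model$b[[3]], `+`))
    xs <- sweep(h2 %*% model$W[[4]], 2, model$b[[4]], `+`)
    sweep(sweep(xs, 2, model$scale, `*`), 2, model$center, `+`)
  }
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("latent model (%s): %d -> %d\n", x$backend, x$input_dim,
              x$latent_dim))
  if (!is.null(x$loss_trace)) {
    cat(sprintf("final reconstruction MSE: %.4g (epoch 1: %.4g)\n",
                x$loss_trace$mse[nrow(x$loss_trace)], x$loss_trace$mse[1]))
  }
  invisible(x)
}
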