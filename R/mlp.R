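# Dense softmax network used for every branch classifier: fully connected
# layers with batch normalization, ReLU and dropout on the hidden layers,
# softmax output, multi-class cross-entropy loss, Adam updates. Written
# against base R matrices (BLAS does the work); all randomness flows from
# the config seed so training is bit-reproducible.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

mlp_init <- function(d_in, d_out, cfg) {
  widths <- c(d_in, rep(cfg$hidden_dim, cfg$n_layers - 1L), d_out)
  layers <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    fan_in <- widths[l]
    W <- matrix(stats::rnorm(fan_in * widths[l + 1L], sd = sqrt(2 / fan_in)),
                fan_in, widths[l + 1L])
    layer <- list(W = W, b = numeric(widths[l + 1L]))
    if (l < cfg$n_layers) {
      layer$gamma <- rep(1, widths[l + 1L])
      layer$beta <- numeric(widths[l + 1L])
      layer$run_mean <- numeric(widths[l + 1L])
      layer$run_var <- rep(1, widths[l + 1L])
    }
    layers[[l]] <- layer
  }
  layers
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# training-mode forward pass; caches everything the backward pass needs and
# updates running batch-norm statistics in place (returned)
mlp_forward_train <- function(layers, x, dropout_rate) {
  n_layers <- length(layers)
  cache <- vector("list", n_layers)
  a <- x
  for (l in seq_len(n_layers - 1L)) {
    ly <- layers[[l]]
    z <- a %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    mu <- colMeans(z)
    va <- colMeans(sweep(z, 2, mu)^2)
    inv_sd <- 1 / sqrt(va + BN_EPS)
    zhat <- sweep(sweep(z, 2, mu), 2, inv_sd, "*")
    y <- sweep(sweep(zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    relu_mask <- y > 0
    a_out <- y * relu_mask
    if (dropout_rate > 0) {
      keep <- matrix(stats::runif(length(a_out)) >= dropout_rate,
                     nrow(a_out), ncol(a_out))
      a_out <- a_out * keep / (1 - dropout_rate)
    } else {
      keep <- NULL
    }
    layers[[l]]$run_mean <- BN_MOMENTUM * ly$run_mean + (1 - BN_MOMENTUM) * mu
    layers[[l]]$run_var <- BN_MOMENTUM * ly$run_var + (1 - BN_MOMENTUM) * va
    cache[[l]] <- list(a_in = a, z = z, mu = mu, inv_sd = inv_sd, zhat = zhat,
                       relu_mask = relu_mask, keep = keep)
    a <- a_out
  }
  lyo <- layers[[n_layers]]
  logits <- sweep(a %*% lyo$W, 2, lyo$b, "+")
  cache[[n_layers]] <- list(a_in = a)
  list(layers = layers, probs = softmax_rows(logits), cache = cache)
}

# backward pass for softmax cross-entropy; returns per-layer gradients
mlp_backward <- function(layers, cache, probs, y_onehot, w, dropout_rate) {
  n_layers <- length(layers)
  grads <- vector("list", n_layers)
  # delta = gradient w.r.t. the current layer's pre-activation (weighted mean)
  delta <- (probs - y_onehot) * (w / sum(w))
  for (l in rev(seq_len(n_layers))) {
    ca <- cache[[l]]
    grads[[l]]$W <- crossprod(ca$a_in, delta)
    grads[[l]]$b <- colSums(delta)
    if (l == 1L) break
    da <- tcrossprod(delta, layers[[l]]$W)  # gradient w.r.t. layer l-1 output
    cp <- cache[[l - 1L]]
    if (!is.null(cp$keep)) da <- da * cp$keep / (1 - dropout_rate)
    dy <- da * cp$relu_mask
    grads[[l - 1L]] <- list(gamma = colSums(dy * cp$zhat), beta = colSums(dy))
    dzhat <- sweep(dy, 2, layers[[l - 1L]]$gamma, "*")
    m <- nrow(dzhat)
    zc <- sweep(cp$z, 2, cp$mu)
    dvar <- colSums(dzhat * zc) * (-0.5) * cp$inv_sd^3
    dmu <- colSums(dzhat) * (-cp$inv_sd) + dvar * colMeans(-2 * zc)
    delta <- sweep(dzhat, 2, cp$inv_sd, "*") +
      sweep(zc, 2, 2 * dvar / m, "*") +
      matrix(dmu / m, m, length(dmu), byrow = TRUE)
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    lapply(ly[intersect(names(ly), c("W", "b", "gamma", "beta"))],
           function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    for (p in names(state[[l]])) {
      g <- grads[[l]][[p]]
      st <- state[[l]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

# inference-mode forward pass: dropout off, running BN statistics
mlp_predict_probs <- function(layers, x) {
  n_layers <- length(layers)
  a <- x
  for (l in seq_len(n_layers - 1L)) {
    ly <- layers[[l]]
    z <- sweep(a %*% ly$W, 2, ly$b, "+")
    zhat <- sweep(sweep(z, 2, ly$run_mean), 2,
                  1 / sqrt(ly$run_var + BN_EPS), "*")
    y <- sweep(sweep(zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
    a <- y * (y > 0)
  }
  lyo <- layers[[n_layers]]
  softmax_rows(sweep(a %*% lyo$W, 2, lyo$b, "+"))
}

ce_loss <- function(probs, y, w) {
  p <- pmax(probs[cbind(seq_len(nrow(probs)), y)], 1e-12)
  sum(w * -log(p)) / sum(w)
}

# core training loop: minibatch Adam with early stopping on a held-out
# validation split; returns the parameters from the best validation epoch
mlp_fit <- function(x, y, d_out, cfg, class_weights = NULL) {
  set.seed(cfg$seed)
  n <- nrow(x)
  w_class <- class_weights %||% rep(1, d_out)
  w <- w_class[y]

  n_val <- if (n >= 20) max(2L, floor(cfg$val_fraction * n)) else 0L
  perm <- sample.int(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)

  layers <- mlp_init(ncol(x), d_out, cfg)
  state <- adam_init(layers)
  best <- list(loss = Inf, layers = layers)
  patience_left <- cfg$early_stop_patience
  t <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (b in batches) {
      xb <- x[b, , drop = FALSE]
      yb <- y[b]
      fw <- mlp_forward_train(layers, xb, cfg$dropout_rate)
      layers <- fw$layers
      onehot <- matrix(0, length(yb), d_out)
      onehot[cbind(seq_along(yb), yb)] <- 1
      grads <- mlp_backward(layers, fw$cache, fw$probs, onehot, w[b],
                            cfg$dropout_rate)
      t <- t + 1L
      upd <- adam_step(layers, grads, state, cfg$learning_rate, t)
      layers <- upd$layers
      state <- upd$state
    }
    monitor_idx <- if (n_val > 0) val_idx else tr_idx
    loss <- ce_loss(mlp_predict_probs(layers, x[monitor_idx, , drop = FALSE]),
                    y[monitor_idx], w[monitor_idx])
    if (loss < best$loss - 1e-6) {
      best <- list(loss = loss, layers = layers)
      patience_left <- cfg$early_stop_patience
    } else {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }
  list(layers = best$layers, val_loss = best$loss, epochs_run = epoch)
}
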