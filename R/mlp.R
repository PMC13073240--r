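# Gated-attention MLP engine. Pure-R minibatch training with an Adam-style
# optimizer; all stochastic steps (init, shuffling, dropout, validation
# split) draw from the single R RNG stream seeded by the caller, so training
# is deterministic given (data, config, seed).

sigmoid_ <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(n_in, hidden_sizes, n_out, attention) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nrow = nin, ncol = nout)
  w <- list()
  if (attention) {
    # learned input gate: g = sigmoid(x Wg + bg), gated input x * g
    w$Wg <- matrix(stats::rnorm(n_in * n_in, sd = sqrt(1 / n_in)), n_in, n_in)
    w$bg <- numeric(n_in)
  }
  dims <- c(n_in, hidden_sizes, n_out)
  for (l in seq_len(length(dims) - 1)) {
    w[[paste0("W", l)]] <- he(dims[l], dims[l + 1])
    w[[paste0("b", l)]] <- numeric(dims[l + 1])
  }
  w
}

# forward pass; when `dropout_masks` is NULL inference mode is used
mlp_forward <- function(w, X, hidden_sizes, attention, dropout = 0,
                        dropout_masks = NULL) {
  cache <- list()
  if (attention) {
    a <- sweep(X %*% w$Wg, 2, w$bg, "+")
    g <- sigmoid_(a)
    H <- X * g
    cache$gate <- g
  } else H <- X
  cache$H0 <- H
  n_hidden <- length(hidden_sizes)
  for (l in seq_len(n_hidden)) {
    pre <- sweep(H %*% w[[paste0("W", l)]], 2, w[[paste0("b", l)]], "+")
    act <- pmax(pre, 0)
    if (!is.null(dropout_masks) && dropout > 0) {
      act <- act * dropout_masks[[l]] / (1 - dropout)
    }
    cache[[paste0("pre", l)]] <- pre
    cache[[paste0("act", l)]] <- act
    H <- act
  }
  L <- length(hidden_sizes) + 1L
  logits <- sweep(H %*% w[[paste0("W", L)]], 2, w[[paste0("b", L)]], "+")
  cache$probs <- softmax_rows(logits)
  cache
}

mlp_backward <- function(w, X, Y, cache, hidden_sizes, attention, dropout,
                         dropout_masks, sample_w) {
  n <- nrow(X)
  grads <- list()
  L <- length(hidden_sizes) + 1L
  dlogits <- (cache$probs - Y) * sample_w / sum(sample_w)
  Hprev <- if (L > 1) cache[[paste0("act", L - 1)]] else cache$H0
  grads[[paste0("W", L)]] <- crossprod(Hprev, dlogits)
  grads[[paste0("b", L)]] <- colSums(dlogits)
  dH <- dlogits %*% t(w[[paste0("W", L)]])
  for (l in rev(seq_len(length(hidden_sizes)))) {
    if (!is.null(dropout_masks) && dropout > 0)
      dH <- dH * dropout_masks[[l]] / (1 - dropout)
    dpre <- dH * (cache[[paste0("pre", l)]] > 0)
    Hin <- if (l > 1) cache[[paste0("act", l - 1)]] else cache$H0
    grads[[paste0("W", l)]] <- crossprod(Hin, dpre)
    grads[[paste0("b", l)]] <- colSums(dpre)
    dH <- dpre %*% t(w[[paste0("W", l)]])
  }
  if (attention) {
    dgate <- dH * X
    da <- dgate * cache$gate * (1 - cache$gate)
    grads$Wg <- crossprod(X, da)
    grads$bg <- colSums(da)
  }
  grads
}

mlp_train <- function(X, y_idx, n_classes, cfg, class_weights = NULL) {
  n <- nrow(X)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y_idx)] <- 1
  sample_w <- if (is.null(class_weights)) rep(1, n) else class_weights[y_idx]

  # stratified validation split for early stopping
  val_idx <- integer(0)
  if (cfg$val_frac > 0 && n >= 20) {
    for (k in seq_len(n_classes)) {
      idx_k <- which(y_idx == k)
      n_val <- max(1L, floor(length(idx_k) * cfg$val_frac))
      val_idx <- c(val_idx, sample(idx_k, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  w <- mlp_init(ncol(X), cfg$hidden_sizes, n_classes, cfg$attention)
  mstate <- lapply(w, function(p) p * 0)
  vstate <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0

  xent <- function(P, Yt, sw) -sum(sw * log(pmax(rowSums(P * Yt), 1e-12))) / sum(sw)
  best_val <- Inf; best_w <- w; patience_left <- cfg$early_stop_patience

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(tr_idx)
    starts <- seq(1, length(perm), by = cfg$batch_size)
    for (s in starts) {
      batch <- perm[s:min(s + cfg$batch_size - 1, length(perm))]
      Xb <- X[batch, , drop = FALSE]; Yb <- Y[batch, , drop = FALSE]
      masks <- NULL
      if (cfg$dropout > 0) {
        masks <- lapply(cfg$hidden_sizes, function(h)
          matrix(stats::runif(length(batch) * h) >= cfg$dropout, length(batch), h))
      }
      cache <- mlp_forward(w, Xb, cfg$hidden_sizes, cfg$attention,
                           cfg$dropout, masks)
      grads <- mlp_backward(w, Xb, Yb, cache, cfg$hidden_sizes, cfg$attention,
                            cfg$dropout, masks, sample_w[batch])
      t_step <- t_step + 1
      for (nm in names(w)) {
        gmat <- grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gmat
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gmat^2
        mhat <- mstate[[nm]] / (1 - b1^t_step)
        vhat <- vstate[[nm]] / (1 - b2^t_step)
        w[[nm]] <- w[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    if (length(val_idx)) {
      Pv <- mlp_forward(w, X[val_idx, , drop = FALSE], cfg$hidden_sizes,
                        cfg$attention)$probs
      vloss <- xent(Pv, Y[val_idx, , drop = FALSE], sample_w[val_idx])
      if (vloss < best_val - 1e-6) {
        best_val <- vloss; best_w <- w; patience_left <- cfg$early_stop_patience
      } else {
        patience_left <- patience_left - 1
        if (patience_left <= 0) break
      }
    } else best_w <- w
  }
  best_w
}
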