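# Batched forward/backward passes for the GRU stack. Sequences in a batch
# share the same length T (guaranteed by fixed-length preprocessing), so a
# batch is a list over time of B x width matrices and every step is one BLAS
# call. Gradients are derived by backpropagation through time and verified
# against finite differences in the test suite.

.add_bias <- function(M, b) M + rep(b, each = nrow(M))

# One direction of one layer. X_list: list over t of B x in matrices.
# reverse = TRUE runs the recursion from t = T down to 1; outputs/caches are
# stored at their true time index either way.
.gru_dir_forward <- function(X_list, p, reverse = FALSE) {
  T_len <- length(X_list)
  B <- nrow(X_list[[1]])
  H <- length(p$b_z)
  order_t <- if (reverse) rev(seq_len(T_len)) else seq_len(T_len)
  tWz <- t(p$W_z); tUz <- t(p$U_z)
  tWr <- t(p$W_r); tUr <- t(p$U_r)
  tWh <- t(p$W_h); tUh <- t(p$U_h)
  Hout <- vector("list", T_len)
  cache <- vector("list", T_len)
  h <- matrix(0, B, H)
  for (t in order_t) {
    Xt <- X_list[[t]]
    Z <- .sigmoid(.add_bias(Xt %*% tWz + h %*% tUz, p$b_z))
    R <- .sigmoid(.add_bias(Xt %*% tWr + h %*% tUr, p$b_r))
    C <- tanh(.add_bias(Xt %*% tWh + (R * h) %*% tUh, p$b_h))
    h_new <- (1 - Z) * h + Z * C
    cache[[t]] <- list(Z = Z, R = R, C = C, Hprev = h)
    h <- h_new
    Hout[[t]] <- h
  }
  list(H = Hout, cache = cache, order = order_t)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward through one direction. dH_list holds the gradient flowing into the
# direction's output at each true time index. Returns dX per time step and
# the parameter gradients.
.gru_dir_backward <- function(X_list, p, fwd_res, dH_list) {
  T_len <- length(X_list)
  B <- nrow(X_list[[1]])
  H <- length(p$b_z)
  g <- list(W_z = 0 * p$W_z, U_z = 0 * p$U_z, b_z = 0 * p$b_z,
            W_r = 0 * p$W_r, U_r = 0 * p$U_r, b_r = 0 * p$b_r,
            W_h = 0 * p$W_h, U_h = 0 * p$U_h, b_h = 0 * p$b_h)
  dX <- vector("list", T_len)
  dcarry <- matrix(0, B, H)
  for (t in rev(fwd_res$order)) {
    cc <- fwd_res$cache[[t]]
    dh <- dH_list[[t]] + dcarry
    dz <- dh * (cc$C - cc$Hprev)
    dc <- dh * cc$Z
    dhprev <- dh * (1 - cc$Z)
    dAc <- dc * (1 - cc$C^2)
    dRH <- dAc %*% p$U_h
    dr <- dRH * cc$Hprev
    dhprev <- dhprev + dRH * cc$R
    dAz <- dz * cc$Z * (1 - cc$Z)
    dAr <- dr * cc$R * (1 - cc$R)
    dhprev <- dhprev + dAz %*% p$U_z + dAr %*% p$U_r
    Xt <- X_list[[t]]
    dX[[t]] <- dAz %*% p$W_z + dAr %*% p$W_r + dAc %*% p$W_h
    g$W_z <- g$W_z + crossprod(dAz, Xt)
    g$U_z <- g$U_z + crossprod(dAz, cc$Hprev)
    g$b_z <- g$b_z + colSums(dAz)
    g$W_r <- g$W_r + crossprod(dAr, Xt)
    g$U_r <- g$U_r + crossprod(dAr, cc$Hprev)
    g$b_r <- g$b_r + colSums(dAr)
    g$W_h <- g$W_h + crossprod(dAc, Xt)
    g$U_h <- g$U_h + crossprod(dAc, cc$R * cc$Hprev)
    g$b_h <- g$b_h + colSums(dAc)
    dcarry <- dhprev
  }
  list(dX = dX, grads = g)
}

# Full batched forward with caches. feats: list of T x F matrices (one per
# clip). training = TRUE draws inverted-dropout masks from the current RNG
# stream; evaluation is deterministic.
.model_forward_batch <- function(feats, params, training = FALSE,
                                 keep_cache = FALSE) {
  cfg <- params$config
  T_len <- nrow(feats[[1]])
  B <- length(feats)
  # time-major slices: X_list[[t]] is B x F
  arr <- array(unlist(feats, use.names = FALSE),
               dim = c(T_len, cfg$input_size, B))
  X_list <- lapply(seq_len(T_len), function(t) {
    t(matrix(arr[t, , ], nrow = cfg$input_size, ncol = B))
  })
  L <- length(params$layers)
  layer_caches <- vector("list", L)
  cur <- X_list
  for (l in seq_len(L)) {
    layer <- params$layers[[l]]
    f_res <- .gru_dir_forward(cur, layer$fwd, reverse = FALSE)
    b_res <- .gru_dir_forward(cur, layer$bwd, reverse = TRUE)
    out <- lapply(seq_len(T_len), function(t) cbind(f_res$H[[t]], b_res$H[[t]]))
    mask <- NULL
    if (training && cfg$dropout_p > 0 && l < L) {
      keep <- 1 - cfg$dropout_p
      mask <- lapply(seq_len(T_len), function(t) {
        matrix(stats::rbinom(B * 2 * cfg$hidden_size, 1, keep),
               B) / keep
      })
      out <- lapply(seq_len(T_len), function(t) out[[t]] * mask[[t]])
    }
    layer_caches[[l]] <- list(input = cur, fwd = f_res, bwd = b_res,
                              mask = mask)
    cur <- out
  }
  h_bar <- Reduce(`+`, cur) / T_len                      # B x 2H pooled
  head_mask <- NULL
  h_drop <- h_bar
  if (training && cfg$dropout_p > 0) {
    keep <- 1 - cfg$dropout_p
    head_mask <- matrix(stats::rbinom(length(h_bar), 1, keep),
                        nrow(h_bar)) / keep
    h_drop <- h_bar * head_mask
  }
  logits <- .add_bias(h_drop %*% t(params$head$W), params$head$b)
  res <- list(logits = logits)
  if (keep_cache) {
    res$cache <- list(layers = layer_caches, h_drop = h_drop,
                      head_mask = head_mask, T_len = T_len, B = B)
  }
  res
}

# Backward from dlogits (B x K) to gradients for every parameter.
.model_backward_batch <- function(params, cache, dlogits) {
  cfg <- params$config
  T_len <- cache$T_len
  g_head <- list(W = crossprod(dlogits, cache$h_drop),
                 b = colSums(dlogits))
  dh_bar <- dlogits %*% params$head$W
  if (!is.null(cache$head_mask)) dh_bar <- dh_bar * cache$head_mask
  dOut <- lapply(seq_len(T_len), function(t) dh_bar / T_len)
  L <- length(params$layers)
  g_layers <- vector("list", L)
  H <- cfg$hidden_size
  for (l in rev(seq_len(L))) {
    lc <- cache$layers[[l]]
    if (!is.null(lc$mask)) {
      dOut <- lapply(seq_len(T_len), function(t) dOut[[t]] * lc$mask[[t]])
    }
    dF <- lapply(dOut, function(m) m[, seq_len(H), drop = FALSE])
    dB <- lapply(dOut, function(m) m[, H + seq_len(H), drop = FALSE])
    layer <- params$layers[[l]]
    back_f <- .gru_dir_backward(lc$input, layer$fwd, lc$fwd, dF)
    back_b <- .gru_dir_backward(lc$input, layer$bwd, lc$bwd, dB)
    g_layers[[l]] <- list(fwd = back_f$grads, bwd = back_b$grads)
    dOut <- lapply(seq_len(T_len), function(t) back_f$dX[[t]] + back_b$dX[[t]])
  }
  list(layers = g_layers, head = g_head)
}

# Class-weighted softmax cross-entropy from logits (numerically stable),
# returning the batch-mean loss and its gradient w.r.t. the logits.
.loss_and_dlogits <- function(logits, y, weights) {
  B <- nrow(logits)
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  logp <- logits - lse
  wy <- weights[y]
  loss <- mean(-wy * logp[cbind(seq_len(B), y)])
  P <- exp(logp)
  Y <- matrix(0, B, ncol(logits))
  Y[cbind(seq_len(B), y)] <- 1
  dlogits <- (wy / B) * (P - Y)
  list(loss = loss, dlogits = dlogits)
}

# ---- Adam with coupled L2 weight decay over the parameter tree -------------

.tree_map <- function(f, ...) {
  trees <- list(...)
  t1 <- trees[[1]]
  if (is.list(t1)) {
    out <- lapply(seq_along(t1), function(i) {
      do.call(.tree_map, c(list(f), lapply(trees, `[[`, i)))
    })
    names(out) <- names(t1)
    out
  } else {
    do.call(f, trees)
  }
}

.trainable <- function(params) list(layers = params$layers, head = params$head)

.set_trainable <- function(params, tree) {
  params$layers <- tree$layers
  params$head <- tree$head
  params
}

.adam_init <- function(theta) {
  list(m = .tree_map(function(x) 0 * x, theta),
       v = .tree_map(function(x) 0 * x, theta),
       t = 0L)
}

.adam_step <- function(theta, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (weight_decay > 0) {
    grads <- .tree_map(function(g, th) g + weight_decay * th, grads, theta)
  }
  state$t <- state$t + 1L
  state$m <- .tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- .tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  theta <- .tree_map(function(th, m, v) {
    th - lr * (m / c1) / (sqrt(v / c2) + eps)
  }, theta, state$m, state$v)
  list(theta = theta, state = state)
}
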