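## Minimal MLP machinery for converter models.
##
## A converter network is a flat list of ops (affine, instance norm, ReLU,
## residual block). Forward passes are vectorized over a batch of row
## vectors; backward passes return both the input gradient and per-parameter
## gradients for the Adam updates. Instance normalization standardizes each
## sample across its hidden units using that sample's own statistics (its
## defining behavior), so single-sample and batched conversion are identical
## by construction.

IN_EPS <- 1e-5

op_affine <- function(n_in, n_out, scale = NULL) {
  sd <- scale %||% sqrt(2 / n_in)
  list(type = "affine",
       params = list(W = matrix(stats::rnorm(n_in * n_out, sd = sd), n_in, n_out),
                     b = rep(0, n_out)))
}

op_inorm <- function(n) {
  list(type = "inorm", params = list(gamma = rep(1, n), beta = rep(0, n)))
}

op_relu <- function() list(type = "relu", params = list())

op_resblock <- function(n) {
  list(type = "resblock",
       inner = list(op_affine(n, n), op_inorm(n), op_relu(),
                    op_affine(n, n), op_inorm(n)))
}

ops_forward <- function(ops, X, cache = FALSE) {
  caches <- vector("list", length(ops))
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    if (op$type == "affine") {
      if (cache) caches[[k]] <- list(X = X)
      X <- X %*% op$params$W + rep(op$params$b, each = nrow(X))
    } else if (op$type == "inorm") {
      mu <- rowMeans(X)
      Xc <- X - mu
      sd <- sqrt(rowMeans(Xc^2) + IN_EPS)
      Xh <- Xc / sd
      if (cache) caches[[k]] <- list(Xh = Xh, sd = sd)
      X <- Xh * rep(op$params$gamma, each = nrow(X)) +
        rep(op$params$beta, each = nrow(X))
    } else if (op$type == "relu") {
      if (cache) caches[[k]] <- list(mask = X > 0)
      X[X < 0] <- 0
    } else if (op$type == "resblock") {
      inner <- ops_forward(op$inner, X, cache = cache)
      if (cache) caches[[k]] <- list(X = X, inner = inner$caches)
      X <- X + inner$out
    }
  }
  list(out = X, caches = if (cache) caches)
}

ops_backward <- function(ops, caches, G) {
  grads <- vector("list", length(ops))
  for (k in rev(seq_along(ops))) {
    op <- ops[[k]]
    cc <- caches[[k]]
    if (op$type == "affine") {
      grads[[k]] <- list(W = crossprod(cc$X, G), b = colSums(G))
      G <- G %*% t(op$params$W)
    } else if (op$type == "inorm") {
      n <- ncol(cc$Xh)
      grads[[k]] <- list(gamma = colSums(G * cc$Xh), beta = colSums(G))
      dXh <- G * rep(op$params$gamma, each = nrow(G))
      ## layer-norm backward, per row
      m1 <- rowMeans(dXh)
      m2 <- rowMeans(dXh * cc$Xh)
      G <- (dXh - m1 - cc$Xh * m2) / cc$sd
    } else if (op$type == "relu") {
      grads[[k]] <- list()
      G <- G * cc$mask
    } else if (op$type == "resblock") {
      bw <- ops_backward(op$inner, cc$inner, G)
      grads[[k]] <- list(inner = bw$grads)
      G <- G + bw$G
    }
  }
  list(G = G, grads = grads)
}

## Adam over the nested op/param structure.
adam_init <- function(ops) {
  lapply(ops, function(op) {
    if (op$type == "resblock") {
      list(inner = adam_init(op$inner))
    } else {
      lapply(op$params, function(p) list(m = p * 0, v = p * 0))
    }
  })
}

adam_step <- function(ops, grads, state, lr, beta1, beta2, eps, t) {
  for (k in seq_along(ops)) {
    if (ops[[k]]$type == "resblock") {
      upd <- adam_step(ops[[k]]$inner, grads[[k]]$inner, state[[k]]$inner,
                       lr, beta1, beta2, eps, t)
      ops[[k]]$inner <- upd$ops
      state[[k]]$inner <- upd$state
    } else if (length(ops[[k]]$params)) {
      for (pn in names(ops[[k]]$params)) {
        g <- grads[[k]][[pn]]
        st <- state[[k]][[pn]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g^2
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        ops[[k]]$params[[pn]] <- ops[[k]]$params[[pn]] -
          lr * mhat / (sqrt(vhat) + eps)
        state[[k]][[pn]] <- st
      }
    }
  }
  list(ops = ops, state = state)
}

## Architecture builders. Hidden width is ceiling(m / 2) of the input layer.
build_converter_ops <- function(kind, m, n) {
  h <- max(1L, ceiling(m / 2))
  switch(kind,
    content_mlp_nonlinear = list(
      op_affine(m, h), op_inorm(h), op_relu(),
      op_affine(h, h), op_inorm(h), op_relu(),
      op_affine(h, n)),
    content_mlp_linear = list(
      op_affine(m, h), op_affine(h, h), op_affine(h, n)),
    content_mlp_residual = list(
      op_affine(m, h), op_inorm(h), op_relu(),
      op_affine(h, h), op_inorm(h), op_relu(),
      op_resblock(h), op_resblock(h), op_resblock(h),
      op_affine(h, n)),
    stop("unknown MLP converter kind '", kind, "'"))
}
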