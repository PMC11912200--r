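# Plain multilayer-perceptron conditioner (tanh hidden layers) with manual
# forward/backward passes, plus an Adam optimiser over nested parameter
# lists. The final linear layer is zero-initialised so every coupling layer
# starts as the identity map.

mlp_init <- function(d_in, d_hidden, d_out, n_hidden = 2L) {
  dims <- c(d_in, rep(d_hidden, n_hidden), d_out)
  n_lay <- length(dims) - 1L
  W <- vector("list", n_lay)
  b <- vector("list", n_lay)
  for (l in seq_len(n_lay)) {
    if (l == n_lay) {
      W[[l]] <- matrix(0, dims[l], dims[l + 1])  # identity init
    } else {
      sdv <- sqrt(1 / dims[l])
      W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], sd = sdv), dims[l], dims[l + 1])
    }
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b, n_lay = n_lay)
}

mlp_forward <- function(mlp, X) {
  n_lay <- mlp$n_lay
  acts <- vector("list", n_lay + 1L)
  acts[[1]] <- X
  for (l in seq_len(n_lay)) {
    Z <- sweep(acts[[l]] %*% mlp$W[[l]], 2, mlp$b[[l]], "+")
    acts[[l + 1]] <- if (l < n_lay) tanh(Z) else Z
  }
  list(out = acts[[n_lay + 1L]], acts = acts)
}

mlp_backward <- function(mlp, cache, g_out) {
  n_lay <- mlp$n_lay
  gW <- vector("list", n_lay)
  gb <- vector("list", n_lay)
  g <- g_out
  for (l in rev(seq_len(n_lay))) {
    a_in <- cache$acts[[l]]
    gW[[l]] <- crossprod(a_in, g)
    gb[[l]] <- colSums(g)
    g <- g %*% t(mlp$W[[l]])
    if (l > 1L) {
      g <- g * (1 - cache$acts[[l]]^2)  # tanh'
    }
  }
  list(gW = gW, gb = gb, g_in = g)
}

# ---- Adam over nested numeric lists -----------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
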