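# Spline coupling layers: one subset of the marginal variables is
# transformed elementwise by rational-quadratic splines whose knots are
# predicted by an MLP conditioner reading the complementary subset. The
# partition masks follow a deterministic, non-random protocol (see
# build_coupling_masks): complementary masks that split every molecule's
# degrees of freedom across the two blocks and alternate which semantic
# groups condition which, maximising cross-conditioning between positional
# and rotational variables.

make_coupling_layer <- function(D, mask, periodic, K = 4L, hidden = 128L,
                                n_hidden = 2L) {
  t_idx <- which(mask)
  if (length(t_idx) == 0L || length(t_idx) == D) {
    abort("coupling mask must split dimensions into two non-empty blocks")
  }
  groups <- list()
  offset <- 0L
  for (per in c(FALSE, TRUE)) {
    dims <- t_idx[periodic[t_idx] == per]
    if (!length(dims)) next
    n_par <- if (per) 3L * K else 3L * K - 1L
    ng <- length(dims)
    groups[[length(groups) + 1L]] <- list(
      periodic = per, dims = dims, offset = offset, ng = ng, n_par = n_par
    )
    offset <- offset + ng * n_par
  }
  list(mask = mask, t_idx = t_idx, c_idx = which(!mask), groups = groups,
       K = K, out_dim = offset,
       mlp = mlp_init(D - length(t_idx), hidden, offset, n_hidden))
}

# Conditioner output columns are laid out per transformed dimension as
# [w_1..w_K, h_1..h_K, d_...]; each group occupies one contiguous column
# range, so gathering/scattering the per-element K-column raw matrices is a
# single reshape.
.gather_group <- function(out, g, K) {
  B <- nrow(out)
  block <- out[, g$offset + seq_len(g$ng * g$n_par), drop = FALSE]
  arr <- array(block, c(B, g$n_par, g$ng))
  to_mat <- function(cols) {
    matrix(aperm(arr[, cols, , drop = FALSE], c(1, 3, 2)), B * g$ng,
           length(cols))
  }
  list(w = to_mat(seq_len(K)), h = to_mat(K + seq_len(K)),
       d = to_mat((2L * K + 1L):g$n_par))
}

.scatter_group <- function(g_w, g_h, g_d, g, B, K) {
  big <- array(0, c(B, g$n_par, g$ng))
  put <- function(cols, m) {
    aperm(array(m, c(B, g$ng, length(cols))), c(1, 3, 2))
  }
  big[, seq_len(K), ] <- put(seq_len(K), g_w)
  big[, K + seq_len(K), ] <- put(K + seq_len(K), g_h)
  big[, (2L * K + 1L):g$n_par, ] <- put((2L * K + 1L):g$n_par, g_d)
  matrix(big, B, g$n_par * g$ng)
}

coupling_forward <- function(layer, x, keep_cache = FALSE) {
  B <- nrow(x)
  xa <- x[, layer$c_idx, drop = FALSE]
  mf <- mlp_forward(layer$mlp, xa)
  y <- x
  logdet <- numeric(B)
  n_outside <- 0L
  gcaches <- vector("list", length(layer$groups))
  for (gi in seq_along(layer$groups)) {
    g <- layer$groups[[gi]]
    xt <- as.vector(x[, g$dims, drop = FALSE])
    raw <- .gather_group(mf$out, g, layer$K)
    fw <- rqs_forward(xt, raw$w, raw$h, raw$d, periodic = g$periodic)
    y[, g$dims] <- matrix(fw$y, B)
    logdet <- logdet + rowSums(matrix(fw$logdet, B))
    n_outside <- n_outside + fw$n_outside
    if (keep_cache) gcaches[[gi]] <- fw
  }
  cache <- if (keep_cache) list(mlp = mf, groups = gcaches, B = B) else NULL
  list(y = y, logdet = logdet, n_outside = n_outside, cache = cache)
}

# g_y: B x D gradient w.r.t. the layer output; g_ld: length-B gradient
# w.r.t. the layer's logdet. Returns gradient w.r.t. the input and the MLP
# parameter gradients.
coupling_backward <- function(layer, cache, g_y, g_ld) {
  B <- cache$B
  g_x <- g_y
  g_out <- matrix(0, B, layer$out_dim)
  for (gi in seq_along(layer$groups)) {
    g <- layer$groups[[gi]]
    fw <- cache$groups[[gi]]
    ng <- length(g$dims)
    bk <- rqs_backward(fw,
                       as.vector(g_y[, g$dims, drop = FALSE]),
                       rep(g_ld, ng))
    g_x[, g$dims] <- matrix(bk$g_x, B)
    if (!is.null(bk$g_raw_w)) {
      g_out[, g$offset + seq_len(g$ng * g$n_par)] <-
        .scatter_group(bk$g_raw_w, bk$g_raw_h, bk$g_raw_d, g, B, layer$K)
    }
  }
  mb <- mlp_backward(layer$mlp, cache$mlp, g_out)
  g_x[, layer$c_idx] <- g_x[, layer$c_idx, drop = FALSE] + mb$g_in
  list(g_x = g_x, gW = mb$gW, gb = mb$gb)
}

coupling_inverse <- function(layer, y) {
  B <- nrow(y)
  ya <- y[, layer$c_idx, drop = FALSE]
  mf <- mlp_forward(layer$mlp, ya)
  x <- y
  logdet <- numeric(B)
  for (g in layer$groups) {
    yt <- as.vector(y[, g$dims, drop = FALSE])
    raw <- .gather_group(mf$out, g, layer$K)
    iv <- rqs_inverse(yt, raw$w, raw$h, raw$d, periodic = g$periodic)
    x[, g$dims] <- matrix(iv$x, B)
    logdet <- logdet + rowSums(matrix(iv$logdet, B))
  }
  list(x = x, logdet = logdet)
}

# Deterministic partition masks. Within every semantic group the dimensions
# alternate between the two blocks; layer pairs (1,2) use position parity,
# pairs (3,4) use pair-of-positions parity, and even layers are the
# complement of the preceding odd layer. This always splits each molecule's
# DOFs across both blocks and alternates whitened-oxygen vs internal/angle
# conditioning from layer to layer.
build_coupling_masks <- function(tags, n_layers) {
  D <- length(tags)
  grp <- match(tags, unique(tags))
  pos <- integer(D)
  for (g in unique(grp)) pos[grp == g] <- seq_len(sum(grp == g))
  masks <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    variant <- ((l - 1L) %/% 2L) %% 2L
    base <- if (variant == 0L) pos %% 2L == 1L else (pos %/% 2L) %% 2L == 0L
    m <- if (l %% 2L == 1L) base else !base
    if (!any(m) || all(m)) m <- seq_len(D) %% 2L == 1L  # degenerate fallback
    masks[[l]] <- m
  }
  masks
}
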