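# Monotone rational-quadratic splines (elementwise, 5 knots / 4 bins by
# default) with exact log-volume, exact inverse, and an analytic backward
# pass for maximum-likelihood training. Raw (unconstrained) parameters per
# element: K bin widths and K bin heights (softmax with a small minimum bin
# fraction), and interior knot derivatives through a shifted softplus so that
# zero raw parameters give the identity map. Non-periodic splines act on
# [-1, 1] with fixed boundary derivatives of 1 and identity linear tails
# outside the interval (keeping the map bijective on the whole line);
# periodic (circular) splines act on [-1, 1) with a shared trainable
# boundary derivative.

SOFTPLUS_SHIFT <- log(exp(1) - 1)  # softplus(0 + shift) == 1
MIN_BIN_FRAC <- 1e-3

softplus <- function(x) {
  # stable: log1p(exp(-|x|)) + max(x, 0)
  log1p(exp(-abs(x))) + pmax(x, 0)
}

row_softmax <- function(m) {
  mx <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, j])
  e <- exp(m - mx)
  e / rowSums(e)
}

# widths/heights from raw parameters: total length 2, minimum bin MIN_BIN_FRAC
.rqs_bins <- function(raw) {
  sig <- row_softmax(raw)
  K <- ncol(raw)
  list(sig = sig, w = 2 * (MIN_BIN_FRAC + (1 - K * MIN_BIN_FRAC) * sig))
}

.rqs_knots <- function(w) {
  K <- ncol(w)
  kx <- matrix(-1, nrow(w), K + 1)
  for (j in seq_len(K)) kx[, j + 1] <- kx[, j] + w[, j]
  kx[, K + 1] <- 1
  kx
}

.rqs_derivs <- function(raw_d, K, periodic) {
  dint <- softplus(raw_d + SOFTPLUS_SHIFT)
  if (periodic) {
    cbind(dint[, K, drop = FALSE], dint[, seq_len(K - 1), drop = FALSE],
          dint[, K, drop = FALSE])
  } else {
    cbind(1, dint, 1)
  }
}

# Forward pass on a vector of elements. raw_w, raw_h: m x K; raw_d:
# m x (K - 1) (non-periodic) or m x K (periodic). Returns y, logdet and a
# cache for the backward pass.
rqs_forward <- function(x, raw_w, raw_h, raw_d, periodic = FALSE) {
  m <- length(x)
  K <- ncol(raw_w)
  y <- x
  logdet <- numeric(m)
  if (periodic) {
    xs_all <- ((x + 1) %% 2) - 1
    inside <- rep(TRUE, m)
  } else {
    inside <- x >= -1 & x <= 1
    xs_all <- x
  }
  n_outside <- sum(!inside)
  if (!any(inside)) {
    return(list(y = y, logdet = logdet, n_outside = n_outside, cache = NULL))
  }
  xs <- xs_all[inside]
  bw <- .rqs_bins(raw_w[inside, , drop = FALSE])
  bh <- .rqs_bins(raw_h[inside, , drop = FALSE])
  w <- bw$w; h <- bh$w
  kx <- .rqs_knots(w); ky <- .rqs_knots(h)
  dmat <- .rqs_derivs(raw_d[inside, , drop = FALSE], K, periodic)
  k <- rowSums(xs > kx[, 2:K, drop = FALSE]) + 1L
  ii <- seq_along(xs)
  idx <- cbind(ii, k)
  wk <- w[idx]; hk <- h[idx]
  xk <- kx[idx]; yk <- ky[idx]
  dk <- dmat[idx]; dk1 <- dmat[cbind(ii, k + 1L)]
  xi <- pmin(pmax((xs - xk) / wk, 0), 1)
  s <- hk / wk
  u <- xi * (1 - xi)
  KK <- dk1 + dk - 2 * s
  N <- s * xi^2 + dk * u
  D <- s + KK * u
  num <- dk1 * xi^2 + 2 * s * u + dk * (1 - xi)^2
  ys <- yk + hk * N / D
  ld <- 2 * log(s) + log(num) - 2 * log(D)
  y[inside] <- ys
  logdet[inside] <- ld
  cache <- list(
    inside = inside, K = K, periodic = periodic, k = k,
    sig_w = bw$sig, sig_h = bh$sig, w = w, h = h,
    raw_d = raw_d[inside, , drop = FALSE],
    wk = wk, hk = hk, dk = dk, dk1 = dk1, xi = xi, s = s, u = u,
    KK = KK, N = N, D = D, num = num
  )
  list(y = y, logdet = logdet, n_outside = n_outside, cache = cache)
}

# Backward pass: given gradients w.r.t. y and w.r.t. logdet (per element),
# return gradients w.r.t. x and the raw parameters.
rqs_backward <- function(fw, g_y, g_ld) {
  m <- length(g_y)
  c <- fw$cache
  g_x <- g_y  # identity tails / default
  K <- if (is.null(c)) NULL else c$K
  if (is.null(c)) {
    return(list(g_x = g_x, g_raw_w = NULL, g_raw_h = NULL, g_raw_d = NULL))
  }
  inside <- c$inside
  gy <- g_y[inside]; gl <- g_ld[inside]
  xi <- c$xi; u <- c$u; s <- c$s
  wk <- c$wk; hk <- c$hk; dk <- c$dk; dk1 <- c$dk1
  N <- c$N; D <- c$D; num <- c$num; KK <- c$KK
  one_m2u <- 1 - 2 * u
  # partials of y
  T_s <- (xi^2 * D - N * one_m2u) / D^2
  dy_dxi <- hk * ((2 * s * xi + dk * (1 - 2 * xi)) * D - N * KK * (1 - 2 * xi)) / D^2
  dy_dh <- N / D + s * T_s
  dy_dw <- -s^2 * T_s
  dy_ddk <- hk * u * (D - N) / D^2
  dy_ddk1 <- -hk * N * u / D^2
  # partials of logdet
  dld_ds <- 2 / s + 2 * u / num - 2 * one_m2u / D
  dld_dxi <- (2 * dk1 * xi + 2 * s * (1 - 2 * xi) - 2 * dk * (1 - xi)) / num -
    2 * KK * (1 - 2 * xi) / D
  dld_ddk <- (1 - xi)^2 / num - 2 * u / D
  dld_ddk1 <- xi^2 / num - 2 * u / D
  # combine
  g_xi <- gy * dy_dxi + gl * dld_dxi
  g_wk <- gy * dy_dw + gl * dld_ds * (-s / wk) + g_xi * (-xi / wk)
  g_hk <- gy * dy_dh + gl * dld_ds / wk
  g_yk <- gy
  g_xk <- -g_xi / wk
  g_dk <- gy * dy_ddk + gl * dld_ddk
  g_dk1 <- gy * dy_ddk1 + gl * dld_ddk1
  g_x_in <- g_xi / wk
  g_x[inside] <- g_x_in

  mi <- length(xi)
  ii <- seq_len(mi)
  k <- c$k
  idx <- cbind(ii, k)
  # width gradients: direct + prefix contribution through the left knot
  gW <- matrix(0, mi, K)
  gW[idx] <- g_wk
  before <- outer(k, seq_len(K), ">")
  gW <- gW + before * g_xk
  gH <- matrix(0, mi, K)
  gH[idx] <- g_hk
  gH <- gH + before * g_yk
  # chain through softmax-with-minimum-bin
  chain_bins <- function(g, sig) {
    rs <- rowSums(g * sig)
    2 * (1 - K * MIN_BIN_FRAC) * sig * (g - rs)
  }
  g_raw_w_in <- chain_bins(gW, c$sig_w)
  g_raw_h_in <- chain_bins(gH, c$sig_h)
  # derivative gradients
  gD <- matrix(0, mi, K + 1)
  gD[idx] <- g_dk
  gD[cbind(ii, k + 1L)] <- gD[cbind(ii, k + 1L)] + g_dk1
  sig_d <- 1 / (1 + exp(-(c$raw_d + SOFTPLUS_SHIFT)))
  if (c$periodic) {
    g_raw_d_in <- matrix(0, mi, K)
    if (K > 1) g_raw_d_in[, seq_len(K - 1)] <- gD[, 2:K, drop = FALSE]
    g_raw_d_in[, K] <- gD[, 1] + gD[, K + 1]
    g_raw_d_in <- g_raw_d_in * sig_d
  } else {
    g_raw_d_in <- gD[, 2:K, drop = FALSE] * sig_d
  }
  # expand to full element set (zeros outside the domain)
  expand <- function(g_in, cols) {
    g <- matrix(0, m, cols)
    g[inside, ] <- g_in
    g
  }
  list(
    g_x = g_x,
    g_raw_w = expand(g_raw_w_in, K),
    g_raw_h = expand(g_raw_h_in, K),
    g_raw_d = expand(g_raw_d_in, ncol(c$raw_d))
  )
}

# Exact inverse: same parameters, solves the per-bin quadratic with the
# numerically stable root. logdet returned is that of the inverse direction.
rqs_inverse <- function(y, raw_w, raw_h, raw_d, periodic = FALSE) {
  m <- length(y)
  K <- ncol(raw_w)
  x <- y
  logdet <- numeric(m)
  if (periodic) {
    ys_all <- ((y + 1) %% 2) - 1
    inside <- rep(TRUE, m)
  } else {
    inside <- y >= -1 & y <= 1
    ys_all <- y
  }
  if (!any(inside)) return(list(x = x, logdet = logdet))
  ys <- ys_all[inside]
  w <- .rqs_bins(raw_w[inside, , drop = FALSE])$w
  h <- .rqs_bins(raw_h[inside, , drop = FALSE])$w
  kx <- .rqs_knots(w); ky <- .rqs_knots(h)
  dmat <- .rqs_derivs(raw_d[inside, , drop = FALSE], K, periodic)
  k <- rowSums(ys > ky[, 2:K, drop = FALSE]) + 1L
  ii <- seq_along(ys)
  idx <- cbind(ii, k)
  wk <- w[idx]; hk <- h[idx]
  xk <- kx[idx]; yk <- ky[idx]
  dk <- dmat[idx]; dk1 <- dmat[cbind(ii, k + 1L)]
  s <- hk / wk
  r <- ys - yk
  KK <- dk1 + dk - 2 * s
  a <- r * KK + hk * (s - dk)
  b <- hk * dk - r * KK
  cc <- -r * s
  disc <- pmax(b^2 - 4 * a * cc, 0)
  xi <- 2 * cc / (-b - sqrt(disc))
  xi <- pmin(pmax(xi, 0), 1)
  u <- xi * (1 - xi)
  D <- s + KK * u
  num <- dk1 * xi^2 + 2 * s * u + dk * (1 - xi)^2
  x[inside] <- xk + xi * wk
  logdet[inside] <- -(2 * log(s) + log(num) - 2 * log(D))
  list(x = x, logdet = logdet)
}
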