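# PCA whitening of the centred oxygen coordinates. After per-frame removal
# of the oxygen COM the data live on a 3(n_mol - 1)-dimensional hyperplane;
# the covariance therefore has exactly 3 null directions, which the layer
# drops, giving the flow its 3(N - 1)-dimensional marginal space.

#' Fit the PCA whitening transform on centred oxygen coordinates
#'
#' Eigendecomposition of the covariance of the flattened oxygen coordinates
#' over the *entire* data set (training plus validation). Exactly three
#' eigenvalues must fall below `null_tol` times the largest (the removed
#' centre-of-mass directions); anything else means the input was not
#' COM-centred and is a hard error, as is a single-molecule input, which
#' would retain no dimensions.
#'
#' @param o_coords matrix n_frames x (3 n_mol) of centred oxygen coordinates
#'   (nm), or a [supercell_frames()] ensemble.
#' @param null_tol relative null-space threshold.
#' @return object of class `whitening_transform` with the mean, the retained
#'   orthonormal basis, eigenvalues (nm^2, descending) and the whitening
#'   log-volume `-(1/2) sum(log lambda)`.
#' @export
fit_whitening <- function(o_coords, null_tol = 1e-10) {
  if (inherits(o_coords, "supercell_frames")) {
    o_coords <- flatten_coords(
      o_coords$coords[, atom_indices(o_coords, "O"), , drop = FALSE]
    )
  }
  n_dim <- ncol(o_coords)
  if (n_dim <= 3) abort("whitening needs at least 2 molecules (retained dims > 0)")
  mu <- colMeans(o_coords)
  X <- sweep(o_coords, 2, mu)
  C <- crossprod(X) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  vals <- eg$values
  n_null <- sum(vals < null_tol * vals[1])
  if (n_null != 3) {
    abort(sprintf(
      "expected exactly 3 null directions (COM), found %d; was the oxygen COM removed?",
      n_null
    ))
  }
  keep <- seq_len(n_dim - 3L)
  structure(
    list(mean = mu, basis = eg$vectors[, keep, drop = FALSE],
         values = vals[keep],
         log_volume = -0.5 * sum(log(vals[keep]))),
    class = "whitening_transform"
  )
}

#' Whiten / unwhiten oxygen coordinates
#'
#' `whiten()` projects onto the retained eigenbasis and scales each direction
#' by \eqn{\lambda_j^{-1/2}}; its log-volume is \eqn{-\frac12\sum_j \ln\lambda_j}.
#' `unwhiten()` is the exact inverse with log-volume \eqn{+\frac12\sum_j \ln\lambda_j},
#' so the pair sums to zero.
#'
#' @param wt a fitted `whitening_transform`.
#' @param x matrix n x (3 n_mol) of centred oxygen coordinates.
#' @return list with `y` (n x 3(n_mol - 1) whitened coordinates) and
#'   `log_volume` (scalar, per frame).
#' @export
whiten <- function(wt, x) {
  if (ncol(x) != length(wt$mean)) abort("whitening dimension mismatch")
  y <- sweep(x, 2, wt$mean) %*% wt$basis
  y <- sweep(y, 2, sqrt(wt$values), "/")
  list(y = y, log_volume = wt$log_volume)
}

#' @rdname whiten
#' @param y whitened matrix n x 3(n_mol - 1).
#' @export
unwhiten <- function(wt, y) {
  if (ncol(y) != ncol(wt$basis)) abort("whitening dimension mismatch")
  x <- sweep(y, 2, sqrt(wt$values), "*") %*% t(wt$basis)
  x <- sweep(x, 2, wt$mean, "+")
  list(x = x, log_volume = -wt$log_volume)
}
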