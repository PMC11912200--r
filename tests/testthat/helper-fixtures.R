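# Shared fixtures and independent oracles, all generated in code.

# small harmonic crystal reused across tests (built once per test run)
tiny_fixture <- local({
  cache <- NULL
  function(n_frames = 2000L) {
    if (is.null(cache) || length(cache$beta_u) < n_frames) {
      spec <- harmonic_crystal_spec(n_mol = 4L, seed = 3L)
      cache <<- sample_fixture(spec, n_frames = n_frames, seed = 11L)
    }
    if (length(cache$beta_u) == n_frames) return(cache)
    out <- cache
    out$frames$coords <- out$frames$coords[seq_len(n_frames), , , drop = FALSE]
    out$beta_u <- out$beta_u[seq_len(n_frames)]
    out
  }
})

# random geometrically valid water molecules (vectors of length n)
random_molecules <- function(n) {
  list(
    d1 = runif(n, 0.08, 0.12),
    d2 = runif(n, 0.08, 0.12),
    theta = runif(n, 0.5, 2.5),
    quat = runif_hemisphere_quat_oracle(n)
  )
}

# independent uniform hemisphere sampler (kept separate from the package's)
runif_hemisphere_quat_oracle <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  q * ifelse(q[, 1] < 0, -1, 1)
}

# Brute-force internal-coordinate log-volume: (1/2) log det(J^T J) of the
# numerical Jacobian of the molecule reconstruction, with the quaternion
# varied along an orthonormal tangent basis of S^3. Vectorised over
# molecules; this is the independent oracle for the closed form.
numeric_internal_logvol <- function(d1, d2, theta, quat, h = 1e-6) {
  n <- length(d1)
  tb <- array(0, c(n, 4, 3))
  for (i in seq_len(n)) {
    P <- diag(4) - tcrossprod(quat[i, ])
    tb[i, , ] <- svd(P)$u[, 1:3]
  }
  rebuild <- function(d1p, d2p, thp, qp) {
    qp <- qp / sqrt(rowSums(qp^2))
    internal <- list(
      d1 = matrix(d1p, ncol = 1), d2 = matrix(d2p, ncol = 1),
      theta = matrix(thp, ncol = 1),
      quat = array(qp, c(n, 1, 4)), r_O = array(0, c(n, 1, 3))
    )
    rec <- internal_to_molecules(internal, water_topology(1))
    cbind(
      rec$frames$coords[, 2, 1], rec$frames$coords[, 2, 2], rec$frames$coords[, 2, 3],
      rec$frames$coords[, 3, 1], rec$frames$coords[, 3, 2], rec$frames$coords[, 3, 3]
    )
  }
  J <- array(0, c(n, 6, 6))
  for (j in 1:6) {
    dd1p <- d1; dd1m <- d1; dd2p <- d2; dd2m <- d2; thp <- theta; thm <- theta
    qp <- quat; qm <- quat
    if (j == 1) { dd1p <- d1 + h; dd1m <- d1 - h }
    if (j == 2) { dd2p <- d2 + h; dd2m <- d2 - h }
    if (j == 3) { thp <- theta + h; thm <- theta - h }
    if (j >= 4) {
      qp <- quat + h * tb[, , j - 3]
      qm <- quat - h * tb[, , j - 3]
    }
    J[, , j] <- (rebuild(dd1p, dd2p, thp, qp) - rebuild(dd1m, dd2m, thm, qm)) / (2 * h)
  }
  vapply(seq_len(n), function(i) {
    0.5 * determinant(crossprod(J[i, , ]))$modulus[1]
  }, numeric(1))
}
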