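test_that("oxygen COM removal centres every frame and shifts all atoms rigidly", {
  top <- water_topology(2)
  coords <- array(0, c(1, 6, 3))
  coords[1, 1, ] <- c(1, 1, 1)   # O of molecule 1
  coords[1, 4, ] <- c(3, 3, 3)   # O of molecule 2
  coords[1, 2, ] <- c(1.1, 1, 1); coords[1, 3, ] <- c(1, 1.1, 1)
  coords[1, 5, ] <- c(3.1, 3, 3); coords[1, 6, ] <- c(3, 3.1, 3)
  fr <- supercell_frames(coords, top)
  out <- remove_oxygen_com(fr)
  expect_equal(out$coords[1, 1, ], c(-1, -1, -1))
  expect_equal(out$coords[1, 4, ], c(1, 1, 1))
  # the same shift applied to every atom
  expect_equal(out$coords[1, 2, ] - out$coords[1, 1, ], c(0.1, 0, 0))
  # already-centred frames are unchanged
  again <- remove_oxygen_com(out)
  expect_equal(again$coords, out$coords)
})

test_that("COM removal leaves exactly 3 null directions in the oxygen covariance", {
  set.seed(1)
  spec <- harmonic_crystal_spec(n_mol = 8, seed = 5)
  fx <- sample_fixture(spec, n_frames = 500, seed = 2)
  fr <- remove_oxygen_com(fx$frames)
  o_idx <- which(fr$roles == "O")
  O <- vapply(1:3, function(d) fr$coords[, o_idx, d], fr$coords[, o_idx, 1])
  Om <- matrix(O, nrow = 500)
  cm <- vapply(1:3, function(d) rowMeans(fr$coords[, o_idx, d]), numeric(500))
  expect_lt(max(abs(cm)), 1e-12)
  ev <- eigen(cov(Om), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-10 * ev[1]), 3)
})

test_that("virtual-site reconstruction is exact, invertible and validated", {
  fx <- tiny_fixture(50)
  fr <- fx$frames
  # degenerate weights (1, 0, 0): M coincides with O
  w_deg <- reconstruct_virtual_site(fr, c(1, 0, 0))
  m_idx <- which(w_deg$roles == "M")
  o_idx <- which(w_deg$roles == "O")
  expect_equal(w_deg$coords[, m_idx, ], w_deg$coords[, o_idx, ])
  # TIP4P-style weights on an idealized (equal-bond) molecule: M sits on the
  # H-O-H bisector at the distance implied by the weights
  w_h <- 0.13194
  d <- 0.09572; th <- 104.52 * pi / 180
  ideal <- internal_to_molecules(list(
    d1 = matrix(d), d2 = matrix(d), theta = matrix(th),
    quat = array(c(1, 0, 0, 0), c(1, 1, 4)), r_O = array(1, c(1, 1, 3))
  ), water_topology(1))$frames
  fr2 <- reconstruct_virtual_site(ideal, c(1 - 2 * w_h, w_h, w_h))
  f1 <- fr2$coords[1, , ]
  o <- f1[1, ]; h1 <- f1[2, ]; h2 <- f1[3, ]; m <- f1[4, ]
  bis <- (h1 - o) / sqrt(sum((h1 - o)^2)) + (h2 - o) / sqrt(sum((h2 - o)^2))
  bis <- bis / sqrt(sum(bis^2))
  mo <- m - o
  expect_equal(mo / sqrt(sum(mo^2)), bis, tolerance = 1e-10)
  # O-M distance is the weighted projection of the bonds onto the bisector
  expect_equal(sqrt(sum(mo^2)), 2 * w_h * d * cos(th / 2), tolerance = 1e-12)
  # round trip add-then-drop is bit-identical
  fr3 <- reconstruct_virtual_site(fr, c(1 - 2 * w_h, w_h, w_h))
  back <- drop_virtual_site(fr3)
  expect_identical(back$coords, fr$coords)
  expect_error(reconstruct_virtual_site(fr, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("internal-coordinate map round-trips and its log-volumes cancel", {
  fx <- tiny_fixture(500)
  fr <- remove_oxygen_com(fx$frames)
  int <- molecules_to_internal(fr)
  rec <- internal_to_molecules(int, fr$topology)
  expect_lt(max(abs(rec$frames$coords - fr$coords)), 1e-10)
  expect_lt(max(abs(int$log_volume + rec$log_volume)), 1e-8)
  # canonical molecule: identity quaternion reproduces the canonical frame
  internal <- list(
    d1 = matrix(0.1), d2 = matrix(0.1), theta = matrix(pi / 2),
    quat = array(c(1, 0, 0, 0), c(1, 1, 4)), r_O = array(0, c(1, 1, 3))
  )
  out <- internal_to_molecules(internal, water_topology(1))
  expect_equal(out$frames$coords[1, 2, ], c(0.1, 0, 0))
  expect_equal(out$frames$coords[1, 3, ], c(0, 0.1, 0))
  expect_error(
    internal_to_molecules(list(
      d1 = matrix(0.1), d2 = matrix(0.1), theta = matrix(0),
      quat = array(c(1, 0, 0, 0), c(1, 1, 4)), r_O = array(0, c(1, 1, 3))
    ), water_topology(1)),
    "invalid internal"
  )
})

test_that("closed-form internal log-volume matches the numerical Jacobian spectrum", {
  set.seed(42)
  mols <- random_molecules(60)
  num <- numeric_internal_logvol(mols$d1, mols$d2, mols$theta, mols$quat)
  closed <- log(8) + 2 * log(mols$d1) + 2 * log(mols$d2) + log(sin(mols$theta))
  expect_lt(max(abs(num - closed)), 1e-6)
})

test_that("hemisphere fixing preserves the rotation and fixes the sign", {
  expect_equal(fix_hemisphere(matrix(c(-1, 0, 0, 0), 1)),
               matrix(c(1, 0, 0, 0), 1))
  q_pos <- matrix(c(0.9, 0.1, 0.3, -0.2), 1)
  q_pos <- q_pos / sqrt(sum(q_pos^2))
  expect_equal(fix_hemisphere(q_pos), q_pos)
  # boundary convention sign(0) = +1
  q0 <- matrix(c(0, 1, 0, 0), 1)
  expect_equal(fix_hemisphere(q0), q0)
  set.seed(8)
  q <- matrix(rnorm(400), 100, 4)
  q <- q / sqrt(rowSums(q^2))
  qf <- fix_hemisphere(q)
  expect_true(all(qf[, 1] >= 0))
  expect_lt(max(abs(latticeflow:::quat_to_rotmat(q) -
                      latticeflow:::quat_to_rotmat(qf))), 1e-12)
})

test_that("hyperspherical map matches hand values and round-trips", {
  # pole convention
  r <- quat_to_hyperspherical(matrix(c(1, 0, 0, 0), 1))
  expect_equal(as.vector(r$angles), c(0, 0, 0))
  # closed-form angles of (1/2, 1/2, 1/2, 1/2)
  r <- quat_to_hyperspherical(matrix(rep(0.5, 4), 1))
  expect_equal(as.vector(r$angles), c(pi / 3, acos(1 / sqrt(3)), pi / 4),
               tolerance = 1e-12)
  bk <- hyperspherical_to_quat(r$angles)
  expect_equal(as.vector(bk$q), rep(0.5, 4), tolerance = 1e-12)
  # log-volume at theta0 = theta1 = pi/2 is ln(1) = 0
  lv <- hyperspherical_to_quat(matrix(c(pi / 2, pi / 2, 1), 1))$log_volume
  expect_equal(lv, 0)
  # round trip on random quaternions; log-volumes cancel
  set.seed(3)
  q <- runif_hemisphere_quat_oracle(2000)
  hs <- quat_to_hyperspherical(q)
  bk <- hyperspherical_to_quat(hs$angles)
  expect_lt(max(abs(bk$q - q)), 1e-10)
  expect_lt(max(abs(hs$log_volume + bk$log_volume)), 1e-8)
})

test_that("weighted hyperspherical samples reproduce uniform-rotation statistics", {
  set.seed(7)
  n <- 1e5
  s <- cbind(runif(n, 0, pi / 2), runif(n, 0, pi), runif(n, 0, 2 * pi))
  w <- sin(s[, 1])^2 * sin(s[, 2])  # exp(log-volume), bounded by 1
  n_eff <- sum(w)^2 / sum(w^2)
  bins <- 20
  chisq_p <- function(x, lim, cdf) {
    br <- seq(lim[1], lim[2], length.out = bins + 1)
    o <- vapply(seq_len(bins), function(b)
      sum(w[x >= br[b] & x < br[b + 1]]), numeric(1)) / sum(w) * n_eff
    e <- diff(cdf(br)) * n_eff
    stat <- sum((o - e)^2 / e)
    pchisq(stat, df = bins - 1, lower.tail = FALSE)
  }
  # uniform-rotation marginals: theta0 ~ sin^2, theta1 ~ sin/2, theta2 uniform
  p0 <- chisq_p(s[, 1], c(0, pi / 2), function(t) (t - sin(t) * cos(t)) * 2 / pi)
  p1 <- chisq_p(s[, 2], c(0, pi), function(t) (1 - cos(t)) / 2)
  p2 <- chisq_p(s[, 3], c(0, 2 * pi), function(t) t / (2 * pi))
  expect_gt(min(p0, p1, p2), 1e-4)
})

test_that("reference-rotation offsets centre theta0 and invert exactly", {
  set.seed(5)
  n <- 400; n_mol <- 3
  quat <- array(0, c(n, n_mol, 4))
  for (m in seq_len(n_mol)) {
    base <- runif_hemisphere_quat_oracle(1)
    noise <- matrix(rnorm(4 * n, sd = 0.05), n, 4)
    q <- matrix(base[rep(1, n), ], n, 4) + noise
    quat[, m, ] <- fix_hemisphere(q / sqrt(rowSums(q^2)))
  }
  off <- align_reference_rotations(quat)
  shifted <- apply_rotation_offsets(quat, off)
  for (m in seq_len(n_mol)) {
    t0 <- quat_to_hyperspherical(matrix(shifted[, m, ], ncol = 4))$angles[, 1]
    expect_gt(mean(t0), pi / 8)
    expect_lt(mean(t0), 3 * pi / 8)
  }
  # offsets then conjugates restore the quaternions (no hemisphere refix)
  noref <- apply_rotation_offsets(quat, off, refix = FALSE)
  back <- apply_rotation_offsets(noref, off, inverse = TRUE, refix = FALSE)
  expect_lt(max(abs(back - quat)), 1e-12)
  # idempotence: re-aligning already-centred data keeps theta0 centred
  off2 <- align_reference_rotations(shifted)
  shifted2 <- apply_rotation_offsets(shifted, off2)
  t0 <- quat_to_hyperspherical(matrix(shifted2[, 1, ], ncol = 4))$angles[, 1]
  expect_gt(mean(t0), pi / 8)
  expect_lt(mean(t0), 3 * pi / 8)
  # a rotationally diffuse site warns but offsets are still produced
  diffuse <- array(runif_hemisphere_quat_oracle(n), c(n, 1, 4))
  expect_warning(off_d <- align_reference_rotations(diffuse), "diffuse")
  expect_equal(dim(off_d), c(1, 4))
})
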