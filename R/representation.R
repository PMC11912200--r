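# Transformations between raw supercell Cartesian coordinates and the flow's
# marginal variables: centre-of-mass removal, virtual-site handling, water
# internal coordinates with their exact log-volume, and the per-molecule
# reference-rotation alignment used to keep hyperspherical angles away from
# coordinate singularities.

#' Remove the oxygen centre of mass from every frame
#'
#' Subtracts the (mass-weighted) centroid of the oxygen atoms from every atom
#' of each frame, so the oxygen coordinates of the output lie on the
#' 3(n_mol - 1)-dimensional hyperplane with zero centroid. Periodic images
#' are assumed already unwrapped; no wrapping is performed.
#'
#' @param frames a [supercell_frames()] ensemble.
#' @return the shifted ensemble (same class).
#' @export
remove_oxygen_com <- function(frames) {
  if (!all(is.finite(frames$coords))) abort("non-finite coordinates")
  o_idx <- atom_indices(frames, "O")
  # oxygen masses are all equal, so the mass-weighted COM is the centroid;
  # keep the mass weighting for generality
  w <- rep(frames$topology$masses["O"], length(o_idx))
  w <- w / sum(w)
  coords <- frames$coords
  for (d in 1:3) {
    cm <- as.vector(coords[, o_idx, d, drop = FALSE][, , 1] %*% w)
    coords[, , d] <- coords[, , d] - cm
  }
  frames$coords <- coords
  frames
}

#' Reconstruct (or drop) the virtual interaction site
#'
#' Adds the virtual site M of each molecule as the fixed linear combination
#' `w_O * r_O + w_H * r_H1 + w_H * r_H2`. The virtual site carries no degrees
#' of freedom, so dropping it loses no information.
#'
#' @param frames ensemble without (with, for the inverse) M sites.
#' @param weights length-3 weights `(w_O, w_H, w_H)` summing to 1 within
#'   1e-10; defaults to the topology's `vsite_weights`.
#' @return ensemble with a trailing M atom per molecule.
#' @export
reconstruct_virtual_site <- function(frames, weights = NULL) {
  weights <- weights %||% frames$topology$vsite_weights
  if (is.null(weights)) abort("no virtual-site weights supplied")
  if (abs(sum(weights) - 1) > 1e-10) abort("virtual-site weights must sum to 1")
  if (any(frames$roles == "M")) abort("frames already carry virtual sites")
  n_mol <- frames$topology$n_mol
  nf <- n_frames(frames)
  old <- frames$coords
  n_atoms_new <- n_mol * 4L
  coords <- array(0, c(nf, n_atoms_new, 3))
  roles <- character(n_atoms_new)
  mol_index <- integer(n_atoms_new)
  for (m in seq_len(n_mol)) {
    src <- which(frames$mol_index == m)
    o <- src[frames$roles[src] == "O"]
    h1 <- src[frames$roles[src] == "H1"]
    h2 <- src[frames$roles[src] == "H2"]
    dst <- (m - 1L) * 4L + 1:4
    for (d in 1:3) {
      coords[, dst[1], d] <- old[, o, d]
      coords[, dst[2], d] <- old[, h1, d]
      coords[, dst[3], d] <- old[, h2, d]
      coords[, dst[4], d] <- weights[1] * old[, o, d] +
        weights[2] * old[, h1, d] + weights[3] * old[, h2, d]
    }
    roles[dst] <- c("O", "H1", "H2", "M")
    mol_index[dst] <- m
  }
  frames$coords <- coords
  frames$roles <- roles
  frames$mol_index <- mol_index
  frames
}

#' @rdname reconstruct_virtual_site
#' @export
drop_virtual_site <- function(frames) {
  keep <- frames$roles != "M"
  frames$coords <- frames$coords[, keep, , drop = FALSE]
  frames$mol_index <- frames$mol_index[keep]
  frames$roles <- frames$roles[keep]
  frames
}

# Log-volume of the internal-to-Cartesian reconstruction of one water
# molecule, with the quaternion measured on the surface of S^3:
#   ln|J| = ln 8 + 2 ln d1 + 2 ln d2 + ln sin(theta).
# The ln 8 term converts between the S^3 surface measure and the rotation-
# vector measure (|domega| = 2 |dq| per tangent dimension).
internal_log_volume <- function(d1, d2, theta) {
  log(8) + 2 * log(d1) + 2 * log(d2) + log(sin(theta))
}

#' Water Cartesian coordinates to internal coordinates (whole ensemble)
#'
#' Decomposes every molecule of every frame into bond lengths `d1`, `d2`,
#' bond angle `theta`, the oxygen position, and a unit quaternion `q`
#' describing the rotation from the canonical molecule frame (H1 along +x at
#' distance d1, H2 in the xy-plane at angle theta, O at the origin) to the
#' observed geometry. The returned log-volume is the exact Jacobian
#' contribution of the Cartesian-to-internal direction, summed per frame;
#' its closed form equals `-(ln 8 + 2 ln d1 + 2 ln d2 + ln sin theta)` per
#' molecule and matches `(1/2) sum(log eig(J^T J))` of the numerical
#' reconstruction Jacobian.
#'
#' @param frames a [supercell_frames()] ensemble (no virtual sites).
#' @return list with matrices `d1`, `d2`, `theta` (n_frames x n_mol), array
#'   `quat` (n_frames x n_mol x 4, not hemisphere-fixed), array `r_O`
#'   (n_frames x n_mol x 3) and vector `log_volume` (per frame, direction
#'   Cartesian -> internal).
#' @export
molecules_to_internal <- function(frames) {
  n_mol <- frames$topology$n_mol
  nf <- n_frames(frames)
  d1 <- d2 <- theta <- matrix(0, nf, n_mol)
  quat <- array(0, c(nf, n_mol, 4))
  r_O <- array(0, c(nf, n_mol, 3))
  lv <- numeric(nf)
  for (m in seq_len(n_mol)) {
    idx <- which(frames$mol_index == m & frames$roles != "M")
    o <- idx[frames$roles[idx] == "O"]
    h1 <- idx[frames$roles[idx] == "H1"]
    h2 <- idx[frames$roles[idx] == "H2"]
    ro <- cbind(frames$coords[, o, 1], frames$coords[, o, 2], frames$coords[, o, 3])
    v1 <- cbind(frames$coords[, h1, 1], frames$coords[, h1, 2], frames$coords[, h1, 3]) - ro
    v2 <- cbind(frames$coords[, h2, 1], frames$coords[, h2, 2], frames$coords[, h2, 3]) - ro
    b1 <- sqrt(rowSums(v1^2))
    b2 <- sqrt(rowSums(v2^2))
    if (any(b1 < 1e-12) || any(b2 < 1e-12)) {
      abort("degenerate molecule geometry: zero-length bond")
    }
    e1 <- v1 / b1
    proj <- rowSums(v2 * e1)
    ct <- pmin(pmax(proj / b2, -1), 1)
    th <- acos(ct)
    perp <- v2 - proj * e1
    pn <- sqrt(rowSums(perp^2))
    if (any(pn < 1e-12)) abort("degenerate molecule geometry: collinear atoms")
    e2 <- perp / pn
    e3 <- cbind(
      e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
      e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
      e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    )
    q <- rotmat_to_quat(cbind(e1, e2, e3))
    d1[, m] <- b1; d2[, m] <- b2; theta[, m] <- th
    quat[, m, ] <- q
    r_O[, m, ] <- ro
    lv <- lv - internal_log_volume(b1, b2, th)
  }
  list(d1 = d1, d2 = d2, theta = theta, quat = quat, r_O = r_O,
       log_volume = lv)
}

#' Reconstruct water Cartesian coordinates from internal coordinates
#'
#' Inverse of [molecules_to_internal()]: places the canonical molecule,
#' rotates it by `R(q)` and translates by `r_O`. The returned log-volume is
#' the internal-to-Cartesian direction (exact negative of the forward one).
#'
#' @param internal list as returned by [molecules_to_internal()].
#' @param topology a [water_topology()].
#' @param temperature optional temperature tag for the rebuilt ensemble.
#' @return list with `frames` (a [supercell_frames()]) and `log_volume`.
#' @export
internal_to_molecules <- function(internal, topology, temperature = NULL) {
  n_mol <- topology$n_mol
  nf <- nrow(internal$d1)
  coords <- array(0, c(nf, 3L * n_mol, 3))
  lv <- numeric(nf)
  for (m in seq_len(n_mol)) {
    d1 <- internal$d1[, m]; d2 <- internal$d2[, m]; th <- internal$theta[, m]
    if (any(d1 <= 0) || any(d2 <= 0) || any(th <= 0) || any(th >= pi)) {
      abort("invalid internal coordinates (need d1, d2 > 0 and 0 < theta < pi)")
    }
    q <- matrix(internal$quat[, m, ], nf, 4)
    R <- quat_to_rotmat(q)
    ro <- matrix(internal$r_O[, m, ], nf, 3)
    # columns of R are the images of the canonical axes
    e1 <- R[, 1:3]; e2 <- R[, 4:6]
    h1 <- ro + d1 * e1
    h2 <- ro + (d2 * cos(th)) * e1 + (d2 * sin(th)) * e2
    at <- (m - 1L) * 3L
    for (d in 1:3) {
      coords[, at + 1L, d] <- ro[, d]
      coords[, at + 2L, d] <- h1[, d]
      coords[, at + 3L, d] <- h2[, d]
    }
    lv <- lv + internal_log_volume(d1, d2, th)
  }
  frames <- supercell_frames(coords, topology, temperature = temperature)
  list(frames = frames, log_volume = lv)
}

#' Per-molecule reference-rotation alignment
#'
#' The hyperspherical parametrisation is singular at `theta0 = 0` and loses
#' flip symmetry at the hemisphere edge `theta0 = pi/2`. For a locally
#' ergodic crystal each molecule's quaternions are narrowly concentrated, so
#' one fixed offset rotation per molecule suffices to move its `theta0`
#' marginal to the well-behaved middle of the range. The offset is the
#' chordal-mean quaternion (principal eigenvector of the averaged outer
#' product) conjugated to the identity and composed with a fixed rotation
#' placing the mean at `theta0 = pi/4`. Offsets must be fitted once and
#' applied identically to training, validation and generated data.
#'
#' @param quat array n_frames x n_mol x 4 of hemisphere-fixed quaternions.
#' @param dispersion_warn warn when the principal eigenvalue of the mean
#'   outer product falls below this (rotationally diffuse site).
#' @return matrix n_mol x 4 of offset quaternions (applied by left
#'   multiplication).
#' @export
align_reference_rotations <- function(quat, dispersion_warn = 0.8) {
  n_mol <- dim(quat)[2]
  target <- c(cos(pi / 4), sin(pi / 4), 0, 0)
  offsets <- matrix(0, n_mol, 4)
  for (m in seq_len(n_mol)) {
    q <- matrix(quat[, m, ], ncol = 4)
    A <- crossprod(q) / nrow(q)
    eg <- eigen(A, symmetric = TRUE)
    if (eg$values[1] < dispersion_warn) {
      warn(sprintf(
        "molecule %d is rotationally diffuse (mean-quaternion concentration %.3f)",
        m, eg$values[1]
      ))
    }
    mean_q <- eg$vectors[, 1]
    if (mean_q[1] < 0) mean_q <- -mean_q
    offsets[m, ] <- quat_multiply(matrix(target, 1),
                                  quat_conjugate(matrix(mean_q, 1)))
  }
  offsets
}

#' Apply (or undo) per-molecule rotation offsets
#'
#' Left-composes each molecule's quaternions with its stored offset (the
#' global-reference-frame rotation of that lattice site); `inverse = TRUE`
#' composes with the conjugate instead. The result is hemisphere-fixed.
#'
#' @param quat array n_frames x n_mol x 4.
#' @param offsets matrix n_mol x 4 from [align_reference_rotations()].
#' @param inverse undo rather than apply.
#' @param refix re-fix the hemisphere after composition (set to `FALSE` for
#'   exact group-inverse round trips).
#' @return array of the same shape.
#' @export
apply_rotation_offsets <- function(quat, offsets, inverse = FALSE, refix = TRUE) {
  n_mol <- dim(quat)[2]
  out <- quat
  for (m in seq_len(n_mol)) {
    o <- matrix(offsets[m, ], 1)
    if (inverse) o <- quat_conjugate(o)
    q <- quat_multiply(o[rep(1, dim(quat)[1]), , drop = FALSE],
                       matrix(quat[, m, ], ncol = 4))
    if (refix) q <- fix_hemisphere(q)
    out[, m, ] <- q
  }
  out
}
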