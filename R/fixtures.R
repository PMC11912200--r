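# Harmonic-crystal synthetic ensembles with exactly known configurational
# free energies. The potential is a quadratic form in Cartesian atom
# displacements, assembled per molecule from physically meaningful
# stiffnesses (oxygen positional spring, bond and angle stiffness,
# rotational/librational concentration) through the internal-coordinate
# Jacobian at the reference geometry, and restricted to the oxygen-centroid
# hyperplane. Everything downstream — the exact reduced potential of any
# frame, the closed-form free energy, direct Gaussian sampling, and exact
# sampling of every Einstein-crystal lambda window — follows from one
# eigendecomposition of the reduced precision matrix.
#
# Measure convention (used package-wide): f = -ln Z with Z the integral of
# exp(-beta U) over the oxygen-centroid-zero hyperplane equipped with the
# orthonormal (surface-Lebesgue) measure, hydrogens unconstrained. This is
# exactly the measure the flow models define through whitening, so fixture,
# flow and Einstein-crystal estimates are directly comparable.

#' Specification of a harmonic molecular crystal
#'
#' @param n_mol number of molecules (default 16).
#' @param lattice integer vector of grid repeats whose product is `n_mol`.
#' @param spacing lattice spacing (nm).
#' @param d1,d2 reference bond lengths (nm).
#' @param theta reference bond angle (rad).
#' @param k_pos oxygen positional spring constant (kJ mol^-1 nm^-2).
#' @param k_bond bond-stretch stiffness (kJ mol^-1 nm^-2).
#' @param k_angle angle-bend stiffness (kJ mol^-1 rad^-2).
#' @param k_rot rotational (librational) stiffness (kJ mol^-1 rad^-2); sets
#'   the per-site rotational concentration.
#' @param temperature temperature in kelvin (default 123.15 K, i.e. -150 C).
#' @param seed seed for the deterministic per-site reference orientations.
#' @return object of class `harmonic_crystal_spec`.
#' @export
harmonic_crystal_spec <- function(n_mol = 16L,
                                  lattice = NULL,
                                  spacing = 0.45,
                                  d1 = 0.09572, d2 = 0.09572,
                                  theta = 104.52 * pi / 180,
                                  k_pos = 6e3,
                                  k_bond = 5e5,
                                  k_angle = 400,
                                  k_rot = 75,
                                  temperature = 123.15,
                                  seed = 42L) {
  stopifnot(n_mol >= 2, k_pos > 0, k_bond > 0, k_angle > 0, k_rot > 0,
            d1 > 0, d2 > 0, theta > 0, theta < pi, temperature > 0)
  if (is.null(lattice)) {
    lattice <- c(1L, 1L, n_mol)
    for (a in floor(n_mol^(1 / 3)):1) {
      if (n_mol %% a == 0) {
        rem <- n_mol %/% a
        b <- floor(sqrt(rem))
        while (rem %% b != 0) b <- b - 1
        lattice <- c(a, b, rem %/% b)
        break
      }
    }
  }
  if (prod(lattice) != n_mol) abort("prod(lattice) must equal n_mol")
  # deterministic lattice sites and per-site reference orientations
  sites <- as.matrix(expand.grid(
    x = seq_len(lattice[1]), y = seq_len(lattice[2]), z = seq_len(lattice[3])
  )) * spacing
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  ref_quat <- runif_hemisphere_quat(n_mol)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  structure(
    list(n_mol = as.integer(n_mol), lattice = lattice, spacing = spacing,
         sites = sites, ref_quat = ref_quat,
         d1 = d1, d2 = d2, theta = theta,
         k_pos = k_pos, k_bond = k_bond, k_angle = k_angle, k_rot = k_rot,
         temperature = temperature, seed = as.integer(seed)),
    class = "harmonic_crystal_spec"
  )
}

# 9x9 Jacobian of one molecule's Cartesian displacements w.r.t.
# (delta r_O, delta omega, delta d1, delta d2, delta theta) at the reference
# geometry, in the space frame (site rotation R).
.mol_jacobian <- function(spec, R) {
  u1 <- c(spec$d1, 0, 0)
  u2 <- spec$d2 * c(cos(spec$theta), sin(spec$theta), 0)
  a1 <- as.vector(R %*% u1)
  a2 <- as.vector(R %*% u2)
  e1 <- a1 / spec$d1
  e2hat <- as.vector(R %*% c(cos(spec$theta), sin(spec$theta), 0))
  wvec <- as.vector(R %*% (spec$d2 * c(-sin(spec$theta), cos(spec$theta), 0)))
  skew <- function(v) matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  M <- matrix(0, 9, 9)
  I3 <- diag(3)
  M[1:3, 1:3] <- I3
  M[4:6, 1:3] <- I3
  M[7:9, 1:3] <- I3
  M[4:6, 4:6] <- -skew(a1)
  M[7:9, 4:6] <- -skew(a2)
  M[4:6, 7] <- e1
  M[7:9, 8] <- e2hat
  M[7:9, 9] <- wvec
  M
}

#' Build the harmonic crystal (precision matrix, plane basis, exact f)
#'
#' Assembles the reduced (beta-scaled) Cartesian precision matrix from the
#' spec's stiffnesses, restricts it to the oxygen-centroid hyperplane and
#' eigendecomposes it, giving the closed-form reduced free energy
#' \eqn{f = \frac12\sum_i \ln(\lambda_i / 2\pi)}.
#'
#' @param spec a [harmonic_crystal_spec()].
#' @return object of class `harmonic_crystal` with elements `spec`, `r0`
#'   (reference flat coordinates, oxygen-centred), `plane` (orthonormal
#'   basis of the constrained subspace), `evals`/`evecs` of the reduced
#'   precision on that subspace, `f_analytic`, `n_dim` and `topology`.
#' @export
build_harmonic_crystal <- function(spec) {
  n <- spec$n_mol
  kT <- kT_kJ_per_mol(spec$temperature)
  topology <- water_topology(n)
  # reference configuration
  coords0 <- matrix(0, 3L * n, 3)
  B <- matrix(0, 9L * n, 9L * n)
  Dloc <- diag(c(rep(spec$k_pos, 3), rep(spec$k_rot, 3),
                 spec$k_bond, spec$k_bond, spec$k_angle) / kT)
  for (m in seq_len(n)) {
    R <- matrix(quat_to_rotmat(spec$ref_quat[m, , drop = FALSE]), 3, 3)
    o <- spec$sites[m, ]
    h1 <- o + as.vector(R %*% c(spec$d1, 0, 0))
    h2 <- o + as.vector(R %*% (spec$d2 * c(cos(spec$theta), sin(spec$theta), 0)))
    at <- (m - 1L) * 3L
    coords0[at + 1L, ] <- o
    coords0[at + 2L, ] <- h1
    coords0[at + 3L, ] <- h2
    M <- .mol_jacobian(spec, R)
    Minv <- solve(M)
    G <- t(Minv) %*% Dloc %*% Minv
    idx <- (m - 1L) * 9L + 1:9
    B[idx, idx] <- (G + t(G)) / 2
  }
  # centre the reference on the oxygen centroid
  o_rows <- rep(seq(1, 3L * n, by = 3L))
  cm <- colMeans(coords0[o_rows, , drop = FALSE])
  coords0 <- sweep(coords0, 2, cm)
  r0 <- as.vector(t(coords0))  # atom-major x,y,z flattening
  # orthonormal basis of the oxygen-centroid-zero hyperplane
  n_dof <- 9L * n
  C <- matrix(0, n_dof, 3)
  for (d in 1:3) {
    C[(o_rows - 1L) * 3L + d, d] <- 1 / sqrt(n)
  }
  Q <- qr.Q(qr(cbind(C, diag(n_dof))))
  plane <- Q[, 4:n_dof, drop = FALSE]
  A <- t(plane) %*% B %*% plane
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (any(eg$values <= 0)) abort("harmonic crystal precision is not positive definite")
  structure(
    list(spec = spec, topology = topology, r0 = r0, plane = plane,
         evals = eg$values, evecs = eg$vectors,
         n_dim = n_dof - 3L,
         f_analytic = 0.5 * sum(log(eg$values / (2 * pi)))),
    class = "harmonic_crystal"
  )
}

#' Sample frames from a harmonic crystal fixture
#'
#' Draws independent configurations from the exact Gaussian ensemble on the
#' constrained subspace and returns them together with the exact reduced
#' potential of every frame and the closed-form free energy.
#'
#' @param spec a [harmonic_crystal_spec()] or a prebuilt
#'   [build_harmonic_crystal()] object.
#' @param n_frames number of frames (default 20000, the desk-scale study
#'   size).
#' @param seed RNG seed.
#' @return list with `frames` (a [supercell_frames()]), `beta_u` (exact
#'   reduced potentials), `f_analytic`, and the `crystal` object.
#' @export
sample_fixture <- function(spec, n_frames = 20000L, seed = 1L) {
  crystal <- if (inherits(spec, "harmonic_crystal")) spec else
    build_harmonic_crystal(spec)
  set.seed(seed)
  d <- crystal$n_dim
  eps <- matrix(rnorm(n_frames * d), n_frames, d)
  # c = V Lambda^{-1/2} eps ; r = r0 + P c ; beta U = |eps|^2 / 2
  cmat <- eps %*% (t(crystal$evecs) / sqrt(crystal$evals))
  # note: (V L^{-1/2})^T = L^{-1/2} V^T, so right-multiplying eps works out
  rflat <- cmat %*% t(crystal$plane)
  rflat <- sweep(rflat, 2, crystal$r0, "+")
  frames <- supercell_frames(unflatten_coords(rflat), crystal$topology,
                             temperature = crystal$spec$temperature)
  list(frames = frames, beta_u = 0.5 * rowSums(eps^2),
       f_analytic = crystal$f_analytic, crystal = crystal)
}

#' Exact reduced potential of arbitrary frames under a harmonic crystal
#'
#' Removes the oxygen centroid, projects onto the constrained subspace and
#' evaluates the quadratic form. Works for fixture samples, flow-generated
#' samples and Einstein-crystal window samples alike.
#'
#' @param crystal a [build_harmonic_crystal()] object.
#' @param frames a [supercell_frames()] ensemble.
#' @return numeric vector of \eqn{\beta U} values.
#' @export
beta_potential <- function(crystal, frames) {
  frames <- remove_oxygen_com(frames)
  rflat <- flatten_coords(frames$coords)
  dmat <- sweep(rflat, 2, crystal$r0)
  cmat <- dmat %*% crystal$plane
  proj <- cmat %*% crystal$evecs
  0.5 * as.vector(proj^2 %*% crystal$evals)
}

#' Paired polymorph fixtures with analytic free-energy differences
#'
#' Builds two harmonic-crystal ensembles (same molecule count, different
#' geometries/stiffnesses) whose free-energy and per-molecule entropy
#' differences are known in closed form, for end-to-end recovery tests.
#' The difference convention is A minus B.
#'
#' @param spec_a,spec_b two [harmonic_crystal_spec()]s with equal `n_mol`.
#' @param n_frames frames per polymorph.
#' @param seed RNG seed (polymorph B uses `seed + 1`).
#' @return list with `a`, `b` (each as [sample_fixture()]), `delta_f`
#'   (analytic, A - B) and `delta_s_mol` (analytic).
#' @export
two_polymorph_fixture <- function(spec_a, spec_b, n_frames = 20000L, seed = 1L) {
  if (spec_a$n_mol != spec_b$n_mol) abort("polymorphs must have equal n_mol")
  a <- sample_fixture(spec_a, n_frames, seed = seed)
  b <- sample_fixture(spec_b, n_frames, seed = seed + 1L)
  # equipartition: <beta U> = n_dim / 2 exactly, so entropy differences
  # reduce to free-energy differences when dimensions match
  s_a <- entropy_per_molecule(a$crystal$n_dim / 2, a$f_analytic, spec_a$n_mol)
  s_b <- entropy_per_molecule(b$crystal$n_dim / 2, b$f_analytic, spec_b$n_mol)
  list(a = a, b = b,
       delta_f = a$f_analytic - b$f_analytic,
       delta_s_mol = s_a - s_b)
}
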