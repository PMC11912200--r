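# Einstein-crystal method (ECM): the ground-truth route to the lattice free
# energy. A lambda chain linearly interpolates between the harmonic-tether
# Hamiltonian (analytic free energy) and the physical one; neighbouring
# windows are bridged by two-state acceptance-ratio estimates and the chain
# is anchored by the analytic f0 of the Einstein crystal. All window
# sampling is COM-constrained on the 3(N-1)-dimensional subspace.

#' ECM configuration
#'
#' @param k scalar tether spring constant, kJ mol^-1 nm^-2 (default 6e3,
#'   chosen so the tether Gaussians have negligible periodic images along
#'   sub-nm box lengths).
#' @param n_lambda number of lambda windows (default 20).
#' @param half_width lambda-schedule shape (see [lambda_schedule()]).
#' @param temperature kelvin.
#' @param r0 reference configuration, a flat coordinate vector with the
#'   centre of mass removed (any static configuration works).
#' @param masses per-atom masses (amu); only the COM-removal term of `f0`
#'   uses them, the tether itself is not mass-weighted.
#' @param physical_multiplier how many times longer the lambda = 1 window is
#'   sampled than every other window (default 4).
#' @param com_tol tolerated COM drift (nm) when evaluating window energies.
#' @return object of class `ecm_config`.
#' @export
ecm_config <- function(k = 6e3, n_lambda = 20L, half_width = 7,
                       temperature = 123.15, r0 = NULL, masses = NULL,
                       physical_multiplier = 4L, com_tol = 1e-6) {
  stopifnot(k > 0, n_lambda >= 2, temperature > 0)
  structure(
    list(k = k, n_lambda = as.integer(n_lambda), half_width = half_width,
         temperature = temperature, r0 = r0, masses = masses,
         lambda = lambda_schedule(n_lambda, half_width),
         physical_multiplier = as.integer(physical_multiplier),
         com_tol = com_tol),
    class = "ecm_config"
  )
}

#' Lambda schedule for the ECM chain
#'
#' Deterministic ascending schedule with exact endpoints 0 and 1. The
#' default is logit-uniform: intermediate values satisfy
#' \eqn{\mathrm{logit}(\lambda_i)} evenly spaced on `[-half_width,
#' half_width]`, which concentrates windows near *both* endpoints. That is
#' what neighbour overlap demands when the physical Hamiltonian contains
#' modes much stiffer than the tether (covalent bonds versus a soft spring):
#' near lambda = 0 the effective stiffness of such a mode grows like
#' lambda itself, so windows must shrink geometrically there, and
#' symmetrically near lambda = 1 for modes softer than the tether.
#' Alternatively `exponent` selects a one-sided power-law schedule
#' (`exponent = 1` gives even spacing). The chain estimate is invariant
#' (within stochastic error) to the schedule shape as long as neighbouring
#' windows overlap.
#'
#' @param n number of windows (>= 2).
#' @param half_width logit-schedule shape parameter.
#' @param exponent optional power-law shape; overrides the logit schedule.
#' @return numeric vector of `n` strictly increasing lambda values.
#' @export
#' @examples
#' lambda_schedule(2)
#' lambda_schedule(5, exponent = 1)
lambda_schedule <- function(n = 20L, half_width = 7, exponent = NULL) {
  if (n < 2) abort("lambda schedule needs at least 2 windows")
  u <- seq(0, 1, length.out = n)
  lam <- if (is.null(exponent)) {
    1 / (1 + exp(-seq(-half_width, half_width, length.out = n)))
  } else {
    1 - (1 - u)^exponent
  }
  lam[1] <- 0
  lam[n] <- 1
  lam
}

#' Interpolated ECM potential energy
#'
#' \eqn{U_\lambda(r) = \lambda U(r) + (1-\lambda) U_{EC}(r)} with
#' \eqn{U_{EC} = \frac{k}{2}\sum_i |r_i - r_{0,i}|^2} the scalar-spring
#' harmonic tether (not mass-weighted; masses enter only the COM terms of
#' `f0`). Frames whose oxygen-centroid drifts beyond `com_tol` are rejected:
#' window sampling must maintain the COM-constrained subspace.
#'
#' @param lambda coupling parameter in `[0, 1]`.
#' @param frames a [supercell_frames()] ensemble.
#' @param config an [ecm_config()] with `r0` set.
#' @param U physical potential energies of the frames (kJ/mol), aligned.
#' @return numeric vector of window energies (kJ/mol).
#' @export
ecm_potential <- function(lambda, frames, config, U) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (is.null(config$r0)) abort("ecm_config$r0 is not set")
  o_idx <- atom_indices(frames, "O")
  for (d in 1:3) {
    drift <- abs(rowMeans(frames$coords[, o_idx, d, drop = FALSE][, , 1]))
    if (any(drift > config$com_tol)) {
      abort(sprintf("COM drift %.2e nm exceeds tolerance %.0e", max(drift),
                    config$com_tol))
    }
  }
  rflat <- flatten_coords(frames$coords)
  dev2 <- rowSums(sweep(rflat, 2, config$r0)^2)
  u_ec <- 0.5 * config$k * dev2
  lambda * U + (1 - lambda) * u_ec
}

#' Sample all ECM lambda windows of a harmonic crystal exactly
#'
#' For a quadratic physical potential every interpolated window ensemble is
#' Gaussian on the constrained subspace (and shares the eigenbasis of the
#' physical precision), so windows are sampled directly — independent draws,
#' no Markov chain. The tether reference is the crystal's own reference
#' configuration. The lambda = 1 window is sampled `physical_multiplier`
#' times longer, mirroring the convention that the physical ensemble also
#' feeds the flow models.
#'
#' @param crystal a [build_harmonic_crystal()] object.
#' @param config an [ecm_config()]; its temperature should match the spec's.
#' @param n_per_window samples per window (lambda = 1 gets the multiplier).
#' @param seed RNG seed.
#' @return object of class `lambda_chain`: per-window reduced potentials
#'   `beta_u` (physical) and `beta_u_ec` (tether).
#' @export
sample_ecm_windows <- function(crystal, config, n_per_window = 2000L,
                               seed = 1L) {
  set.seed(seed)
  kT <- kT_kJ_per_mol(config$temperature)
  bk <- config$k / kT
  lam <- config$lambda
  d <- crystal$n_dim
  windows <- vector("list", length(lam))
  for (i in seq_along(lam)) {
    n_i <- n_per_window *
      if (lam[i] == 1) config$physical_multiplier else 1L
    mu <- lam[i] * crystal$evals + (1 - lam[i]) * bk
    eps <- matrix(rnorm(n_i * d), n_i, d)
    proj <- sweep(eps, 2, sqrt(mu), "/")  # coordinates in the shared eigenbasis
    windows[[i]] <- list(
      beta_u = 0.5 * as.vector(proj^2 %*% crystal$evals),
      beta_u_ec = 0.5 * bk * rowSums(proj^2),
      n = n_i
    )
  }
  structure(
    list(lambda = lam, windows = windows, config = config,
         n_dim = d, n_atoms = 3L * crystal$spec$n_mol),
    class = "lambda_chain"
  )
}

#' Analytic anchor f0 of the ECM chain
#'
#' Three additive terms, all in reduced (k_B T) units: (i) the free energy
#' of the unconstrained Einstein crystal,
#' \eqn{-(3 N_{at}/2)\ln(2\pi/(\beta k))}; (ii) the correction for removing
#' the centre of mass from the Einstein crystal — in the package's
#' orthonormal-hyperplane measure convention this is
#' \eqn{+(3/2)\ln(2\pi/(\beta k))}, and in the delta-function convention it
#' carries the normalized-mass factor \eqn{\sum_i \tilde m_i^2}; (iii) the
#' volume term \eqn{-\ln V} for removing the COM constraint from the
#' physical system. Comparisons against the fixture's analytic (constrained)
#' free energy use `include_volume_term = FALSE`; the volume term is a
#' constant that cancels in polymorph differences at fixed box.
#'
#' @param config an [ecm_config()].
#' @param n_atoms number of tethered atoms.
#' @param V box volume (nm^3); required when `include_volume_term = TRUE`.
#' @param include_volume_term include term (iii).
#' @param convention `"orthonormal"` (surface measure on the hyperplane,
#'   package-wide default) or `"delta"` (mass-weighted delta-function
#'   constraint, requires `config$masses`).
#' @return scalar reduced free energy.
#' @export
analytic_f0 <- function(config, n_atoms, V = NULL,
                        include_volume_term = FALSE,
                        convention = c("orthonormal", "delta")) {
  convention <- match.arg(convention)
  if (config$k <= 0) abort("spring constant must be positive")
  bk <- config$k / kT_kJ_per_mol(config$temperature)
  term_ec <- -(3 * n_atoms / 2) * log(2 * pi / bk)
  term_com <- if (convention == "orthonormal") {
    1.5 * log(2 * pi / bk)
  } else {
    if (is.null(config$masses)) abort("delta convention requires masses")
    mt <- config$masses / sum(config$masses)
    1.5 * log(2 * pi * sum(mt^2) / bk)
  }
  term_vol <- 0
  if (include_volume_term) {
    if (is.null(V) || V <= 0) abort("V must be positive")
    term_vol <- -log(V)
  }
  term_ec + term_com + term_vol
}

#' Assemble the ECM chain free energy
#'
#' \eqn{f^{ECM}_{crys} = f_0 + \sum_{i=1}^{n_\lambda - 1} \Delta f_i}, each
#' \eqn{\Delta f_i} a two-state acceptance-ratio estimate from the cross-wise
#' energy differences of neighbouring windows. The standard error is the
#' *linear* sum of the 19 pairwise standard errors — a deliberate lower-bound
#' convention (it assumes full decorrelation and no cancellation), kept
#' because it is fast and gives an ambitious comparison target.
#'
#' @param chain a [sample_ecm_windows()] lambda chain.
#' @param f0 analytic anchor; defaults to [analytic_f0()] in the constrained
#'   convention.
#' @param min_ess per-pair overlap threshold; pairs below it are flagged.
#' @return object of class `ecm_result` with total `f`, `se`, `f0` and the
#'   per-pair tibble.
#' @export
chain_free_energy <- function(chain, f0 = NULL, min_ess = 10) {
  stopifnot(inherits(chain, "lambda_chain"))
  lam <- chain$lambda
  if (any(vapply(chain$windows, is.null, logical(1)))) {
    abort("all lambda windows must be sampled")
  }
  f0 <- f0 %||% analytic_f0(chain$config, chain$n_atoms)
  pairs <- vector("list", length(lam) - 1L)
  for (i in seq_len(length(lam) - 1L)) {
    dl <- lam[i + 1L] - lam[i]
    wi <- chain$windows[[i]]
    wj <- chain$windows[[i + 1L]]
    w_f <- dl * (wi$beta_u - wi$beta_u_ec)   # u_{i+1} - u_i on window-i samples
    w_r <- -dl * (wj$beta_u - wj$beta_u_ec)  # u_i - u_{i+1} on window-(i+1) samples
    sol <- bar_solve(w_f, w_r)
    pairs[[i]] <- tibble(
      pair = i, lambda_lo = lam[i], lambda_hi = lam[i + 1L],
      delta_f = sol$df, se = sol$se,
      ess_lo = sol$ess_f, ess_hi = sol$ess_r,
      flagged = sol$ess_f < min_ess || sol$ess_r < min_ess
    )
  }
  tbl <- dplyr::bind_rows(pairs)
  structure(
    list(f = f0 + sum(tbl$delta_f), se = sum(tbl$se), f0 = f0,
         pairs = tbl, n_dim = chain$n_dim),
    class = "ecm_result"
  )
}

#' @export
print.ecm_result <- function(x, ...) {
  cat(sprintf("<ecm_result> f = %.4f +/- %.4f kT (f0 = %.4f, %d windows)\n",
              x$f, x$se, x$f0, nrow(x$pairs) + 1L))
  invisible(x)
}

#' Fraction of MD effort spent in the physical ensemble
#'
#' With `n_lambda` windows and the lambda = 1 (physical) window sampled
#' `physical_multiplier` times longer, the physical ensemble's share of the
#' total sampling time is `mult / (n_lambda - 1 + mult)` — 4/23 for the
#' default 20-window chain, i.e. about 17.4%. This is the part of the ECM
#' budget that targeted estimation reuses, and the source of its 5-6x
#' efficiency gain.
#'
#' @param n_lambda number of windows.
#' @param physical_multiplier relative length of the physical window.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' ecm_sampling_fraction()
ecm_sampling_fraction <- function(n_lambda = 20L, physical_multiplier = 4L) {
  physical_multiplier / (n_lambda - 1L + physical_multiplier)
}
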