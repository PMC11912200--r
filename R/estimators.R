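# Free-energy estimators. The generalized work of a configuration is
# phi = beta*U + ln q; with the model normalized (free energy 0 by
# construction), the two-state acceptance-ratio estimator applied to phi on
# model samples and on held-out validation frames yields the absolute
# reduced free energy f = -ln Z of the physical ensemble (estimator BAR_V).
# Raw estimates collected during training are combined by an
# overfitting-aware weighted running average.

#' Generalized work function
#'
#' \eqn{\phi(r) = \beta U(r) + \ln q(r)}. In the perfect-map limit
#' (\eqn{q = p}) the work is the constant \eqn{f = -\ln Z}.
#'
#' @param beta_u reduced potential energies \eqn{\beta U}.
#' @param log_q model log-probabilities, aligned with `beta_u`.
#' @return numeric vector of work values.
#' @export
generalized_work <- function(beta_u, log_q) {
  if (length(beta_u) != length(log_q)) abort("beta_u / log_q length mismatch")
  beta_u + log_q
}

#' Work set for two-state reweighting
#'
#' Bundles the generalized work on validation (physical-ensemble) frames and
#' on model-generated samples. Non-finite entries are counted and excluded
#' with a report; runs excluding more than `max_excluded_frac` are flagged.
#'
#' @param phi_p work values on physical (validation) samples.
#' @param phi_q work values on model samples.
#' @param max_excluded_frac maximum tolerated non-finite fraction (default
#'   1e-3).
#' @return object of class `work_set`.
#' @export
work_set <- function(phi_p, phi_q, max_excluded_frac = 1e-3) {
  if (!length(phi_p) || !length(phi_q)) abort("both work populations must be non-empty")
  n_bad <- sum(!is.finite(phi_p)) + sum(!is.finite(phi_q))
  frac <- n_bad / (length(phi_p) + length(phi_q))
  if (frac > max_excluded_frac) {
    warn(sprintf("excluded %.3f%% non-finite work values (limit %.3f%%)",
                 100 * frac, 100 * max_excluded_frac))
  }
  structure(
    list(phi_p = phi_p[is.finite(phi_p)], phi_q = phi_q[is.finite(phi_q)],
         excluded_frac = frac),
    class = "work_set"
  )
}

# Two-state Bennett acceptance-ratio core. w_f: forward work values on
# samples from state A; w_r: reverse work values on samples from state B.
# Returns df = f_B - f_A with the Bennett analytic standard error.
bar_solve <- function(w_f, w_r) {
  n_f <- length(w_f); n_r <- length(w_r)
  M <- log(n_f / n_r)
  g <- function(df) {
    sum(1 / (1 + exp(pmin(M + w_f - df, 700)))) -
      sum(1 / (1 + exp(pmin(-M + w_r + df, 700))))
  }
  # bracket around the exponential-averaging estimates
  lo <- -log_mean_exp(-w_f)          # EXP forward
  hi <- log_mean_exp(-w_r)           # EXP reverse (other bound)
  lo0 <- min(lo, hi) - 1; hi0 <- max(lo, hi) + 1
  for (i in 1:60) {
    if (g(lo0) < 0 && g(hi0) > 0) break  # g is increasing in df
    if (g(lo0) >= 0) lo0 <- lo0 - 2^i
    if (g(hi0) <= 0) hi0 <- hi0 + 2^i
  }
  df <- uniroot(g, c(lo0, hi0), tol = 1e-10)$root
  ff <- 1 / (1 + exp(pmin(M + w_f - df, 700)))
  fr <- 1 / (1 + exp(pmin(-M + w_r + df, 700)))
  vf <- mean(ff^2) / mean(ff)^2 - 1
  vr <- mean(fr^2) / mean(fr)^2 - 1
  se <- sqrt(vf / n_f + vr / n_r)
  # overlap diagnostic: the Fermi-function mass on each side counts the
  # samples that effectively straddle the two states (N/2 per side at
  # perfect overlap, ~0 when the work distributions are disjoint)
  list(df = df, se = se, ess_f = sum(ff), ess_r = sum(fr))
}

#' BAR_V: absolute free energy from a work set
#'
#' Solves the two-state acceptance-ratio self-consistency between the model
#' ensemble (free energy 0, since q is normalized) and the physical ensemble,
#' returning the absolute reduced free energy \eqn{f_{crys} = -\ln Z} with
#' its analytic standard error. Forward work is \eqn{\phi} on model samples;
#' reverse work is \eqn{-\phi} on validation frames. When either side's
#' effective sample size drops below `min_ess` the estimate is flagged and
#' the standard error set to `Inf`.
#'
#' @param ws a [work_set()].
#' @param eval_index optional training evaluation index for bookkeeping.
#' @param min_ess overlap threshold.
#' @return one-row [tibble::tibble()] with columns `f`, `se`, `estimator`,
#'   `eval_index`, `n_p`, `n_q`, `ess_p`, `ess_q`, `flagged`.
#' @export
bar_v <- function(ws, eval_index = NA_integer_, min_ess = 10) {
  stopifnot(inherits(ws, "work_set"))
  sol <- bar_solve(ws$phi_q, -ws$phi_p)
  flagged <- sol$ess_f < min_ess || sol$ess_r < min_ess
  tibble(
    f = sol$df, se = if (flagged) Inf else sol$se,
    estimator = "BAR_V", eval_index = eval_index,
    n_p = length(ws$phi_p), n_q = length(ws$phi_q),
    ess_p = sol$ess_r, ess_q = sol$ess_f, flagged = flagged
  )
}

#' Overfitting-aware weighted running average of raw estimates
#'
#' Combines raw free-energy estimates \eqn{f_j \pm SE_j} collected during
#' training into cumulative weighted averages
#' \eqn{\bar f(i) = \sum_{j\le i} w_j f_j / \sum_{j\le i} w_j}, with the
#' standard errors averaged using the same weights. The weights are a
#' softmax over the maximum-likelihood estimates \eqn{f^{ML}_j}
#' (`w_j \propto exp(f^{ML}_j - max_k f^{ML}_k)`), which down-weights both
#' early-training evaluations (low \eqn{f^{ML}}) and late, overfit ones
#' (decayed \eqn{f^{ML}}). The average is invariant to rescaling the
#' weights and reduces to the plain running mean for constant \eqn{f^{ML}}.
#'
#' @param f raw estimates.
#' @param se their standard errors.
#' @param f_ml maximum-likelihood estimates used to derive weights; when
#'   `NULL`, explicit `weights` must be given.
#' @param weights optional explicit non-negative weights.
#' @return [tibble::tibble()] with per-evaluation `f`, `se`, `weight`,
#'   cumulative `f_bar` and `se_bar`.
#' @export
weighted_running_average <- function(f, se, f_ml = NULL, weights = NULL) {
  stopifnot(length(f) >= 1, length(se) == length(f))
  if (is.null(weights)) {
    if (is.null(f_ml)) abort("either f_ml or weights must be supplied")
    weights <- exp(f_ml - max(f_ml))
  }
  # flagged estimates (infinite SE sentinel: no overlap) carry no weight
  weights[!is.finite(se)] <- 0
  if (all(weights == 0) || !all(is.finite(weights))) {
    warn("degenerate weights; falling back to uniform")
    weights <- rep(1, length(f))
  }
  cw <- cumsum(weights)
  wf <- ifelse(weights == 0, 0, weights * f)    # avoid 0 * Inf on sentinels
  wse <- ifelse(weights == 0, 0, weights * se)
  tibble(
    eval_index = seq_along(f), f = f, se = se, weight = weights,
    f_bar = cumsum(wf) / cw,
    se_bar = cumsum(wse) / cw
  )
}

#' Per-molecule temperature-reduced entropy
#'
#' \eqn{s_{mol} = (\langle\beta U\rangle - f) / n_{mol}} in units of
#' \eqn{k_B}: the entropic part of the reduced lattice free energy, per
#' molecule. Because \eqn{\langle U \rangle} comes from the same underlying
#' configurations for every estimator, entropy comparisons are a stricter
#' accuracy test than free energies alone.
#'
#' @param mean_beta_u ensemble average of the reduced potential.
#' @param f reduced free energy of the same ensemble (k_B T units).
#' @param n_mol number of molecules.
#' @return scalar entropy per molecule (k_B).
#' @export
entropy_per_molecule <- function(mean_beta_u, f, n_mol) {
  if (n_mol <= 0) abort("n_mol must be positive")
  (mean_beta_u - f) / n_mol
}
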