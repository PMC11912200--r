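---
title: "Targeted lattice free energies of crystal polymorphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted lattice free energies of crystal polymorphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeflow)
```

## The problem

Ranking crystal polymorphs at finite temperature requires the Helmholtz
free energy of each supercell, \(f = -\ln Z\) in units of \(k_BT\), including
the full anharmonic entropic contribution. Classical routes such as the
Einstein crystal method (ECM) are exact but spend most of their sampling
budget on unphysical interpolated Hamiltonians. `latticeflow` implements the
*targeted* alternative: train an invertible map (a normalizing flow) from a
flat analytical base distribution to the Boltzmann ensemble of each
polymorph using only locally ergodic NVT samples of that polymorph, then
obtain an absolute free energy by two-state acceptance-ratio reweighting of
the learned, exactly normalized density against held-out validation data.
Because the flow is normalized, its own ensemble plays the role of the
reference state at free energy zero, and

\[
\ln q(r) \;=\; \ln p_0(z(r)) + \ln \gamma_{r\to z}(r),
\qquad
\phi(r) \;=\; \beta U(r) + \ln q(r),
\]

where \(\gamma_{r\to z}\) is the exact accumulated log-volume of the map and
\(\phi\) is the generalized work. Feeding \(\phi\) evaluated on model samples
and on validation frames into the Bennett acceptance-ratio equation yields
\(f_{\mathrm{crys}}\) directly (`bar_v()`); no intermediate Hamiltonians are
sampled.

## The two molecular representations

Both models first remove the virtual interaction site (reconstructable
exactly from the three real atoms), remove the oxygen centre of mass from
every frame, and whiten the oxygen coordinates with a PCA layer fitted on
the entire data set. The whitening eigenbasis drops exactly the three null
(COM) directions, giving the flow its \(3(N-1)\) marginal variables; a fit
that does not find exactly three null eigenvalues is a hard error rather
than a silent truncation.

* **Model C** keeps the hydrogen atoms in Cartesian coordinates.
* **Model H** decomposes each molecule into bond lengths \(d_1, d_2\), the
  bond angle \(\theta\), and a unit quaternion restricted to the
  \(q_0 \ge 0\) hemisphere of \(S^3\) (antipodal quaternions encode the same
  rotation), parametrized by hyperspherical angles
  \((\theta_0, \theta_1, \theta_2)\).

The internal-coordinate reconstruction has the closed-form log-volume
\(\ln 8 + 2\ln d_1 + 2\ln d_2 + \ln\sin\theta\) (the \(\ln 8\) converts the
\(S^3\) surface measure to the rotation-vector measure); the package treats
the numerical \(\tfrac12\sum_i\ln\lambda_i(J^\top J)\) spectrum of the
reconstruction Jacobian as ground truth and tests the closed form against
it. The hemisphere map contributes \(\ln(\sin^2\theta_0\sin\theta_1)\), with
log arguments clipped at \(10^{-8}\) near the coordinate singularities;
round-trip reports (`roundtrip_report()`) quantify the resulting, tiny,
inversion error and count affected frames.

Since the hyperspherical chart is singular at \(\theta_0 = 0\) and loses
flip symmetry at \(\theta_0 = \pi/2\), each lattice site is given one fixed
offset rotation (`align_reference_rotations()`): the chordal-mean quaternion
is rotated onto \(\theta_0 = \pi/4\), the middle of the chart. The offset is
part of the frozen representation and is applied identically to training,
validation and generated data. Rotationally diffuse sites (molten or
plastic-crystal-like) trigger a warning because no single chart centre is
then adequate.

## Trainable layers and the base distribution

Marginals are shifted and scaled into \([-1, 1]\) using the min/max over the
entire data set with a 1% margin, except the angle dimensions, which use
their full natural ranges so the model retains the capacity to generate any
rotation; \(\theta_2\) is periodic and lives on \([-1, 1)\). On top sit
monotone rational-quadratic spline coupling layers (5 knots per dimension,
4 layers for model H, 8 by default for model C) whose knots are predicted by
2-hidden-layer perceptrons of width 128. The couplings are exactly
invertible, identity at initialization (zero-initialized final layers plus a
shifted-softplus derivative parametrization), and carry analytic gradients;
outside \([-1,1]\) the non-periodic splines continue as identity tails so
the map stays bijective on the whole line. Partition masks are
deterministic: every semantic group (whitened oxygens, bonds, angles, the
three hyperspherical angles) is split across both blocks in every layer, and
the pattern alternates between layers, maximising cross-conditioning between
positional and rotational variables.

The base distribution is flat: uniform on \([-1,1]\) per dimension for model
C (\(\ln p_0 = -3(N-1)\ln 2\)); for model H, uniform on the hemisphere of
\(S^3\) per molecule (surface area \(\pi^2\)) times uniform intervals for
the remaining degrees of freedom. Model H maps its angle dimensions back to
the hemisphere on both sides of the flow, so "flat" means uniform
*rotations*, not uniform angles.

## Training and the overfitting-aware average

Training minimises the negative mean generalized work (equivalently maximum
likelihood: \(\beta U\) does not depend on the parameters) with Adam,
batches of 1000 frames, and a frame-level 3:1 training:validation split.
Every 25 batches the package draws validation frames and an equal number of
model samples, records the raw \(f^{BAR_V}(i) \pm SE(i)\) and
\(f^{ML}(i)\) (the mean validation work), and accumulates the weighted
running average

\[
\bar f(i) = \frac{\sum_{j \le i} w_j f_j}{\sum_{j \le i} w_j},
\qquad w_j \propto e^{\,f^{ML}_j - \max_k f^{ML}_k},
\]

with standard errors averaged by the same weights. \(f^{ML}\) rises toward
\(f\) as the KL divergence shrinks and decays again when the model overfits,
so the softmax weights suppress both early-training and overfit
evaluations. Evaluations whose work distributions do not yet overlap are
flagged (infinite-SE sentinel) and carry zero weight. Training stops on a
plateau of \(\bar f\) (relative change below \(10^{-3}\) over the last
quarter of evaluations, requiring a currently unflagged estimator) or at a
hard step cap. The learning rate (default `2e-3`, no schedule) and the
conditioner width are exposed in `training_config()` /
`build_flow_model()`; neither is critical, they trade steps for step cost.

## Einstein-crystal reference

`sample_ecm_windows()` + `chain_free_energy()` implement the ground-truth
chain \(f^{ECM} = f_0 + \sum_{i=1}^{n_\lambda-1} \Delta f_i\) with
\(U_\lambda = \lambda U + (1-\lambda)\,\tfrac{k}{2}\sum_i |r_i - r_{0,i}|^2\),
\(k = 6\times10^3\) kJ mol\(^{-1}\) nm\(^{-2}\) and \(n_\lambda = 20\)
windows, each pairwise \(\Delta f_i\) a Bennett estimate and the total SE
the *linear* sum of the 19 pairwise SEs — deliberately a lower bound, kept
as a deliberately ambitious comparison target. The tether is not
mass-weighted; masses enter only the COM term of \(f_0\). The physical
(\(\lambda = 1\)) window is sampled four times longer than the others, which
makes the physical share of the total effort \(4/23 \approx 17.4\%\) — the
part a targeted calculation reuses.

Two deliberate numerical choices:

* **Lambda schedule.** The default is logit-uniform (windows geometric near
  *both* endpoints). With stiff intramolecular modes the effective stiffness
  of a mode scales like \(\lambda\) near \(\lambda = 0\), so a schedule dense
  only near \(\lambda = 1\) loses neighbour overlap entirely; the
  logit-uniform chain passes the pairwise overlap diagnostic on the harmonic
  fixture for every pair, and the chain estimate is invariant to the
  schedule shape within stochastic error.
* **Measure convention.** All absolute free energies in the package are
  configurational integrals over the oxygen-centroid-zero hyperplane with
  orthonormal (surface-Lebesgue) measure — exactly the measure the whitening
  layer defines for the flow. `analytic_f0()` exposes the three standard
  terms (free Einstein crystal, EC COM-removal correction, physical volume
  term \(-\ln V\)); oracle comparisons against the fixture's analytic
  constrained free energy omit the volume term, which is a constant that
  cancels in polymorph differences at fixed box.

## The synthetic fixture: what it does and does not emulate

`harmonic_crystal_spec()` defines a true harmonic crystal: a quadratic form
in Cartesian displacements assembled per molecule from an oxygen positional
spring (default \(6\times10^3\) kJ mol\(^{-1}\) nm\(^{-2}\)), bond-stretch
stiffness (\(5\times10^5\) kJ mol\(^{-1}\) nm\(^{-2}\)), angle-bend
stiffness (400 kJ mol\(^{-1}\) rad\(^{-2}\)) and a librational stiffness (75
kJ mol\(^{-1}\) rad\(^{-2}\)) through the internal-coordinate Jacobian at
the reference geometry — magnitudes chosen once to mimic a flexible water
model in an ice-like lattice at 123 K (−150 °C), with per-site reference
orientations drawn deterministically from the spec seed. The default desk
scale is 16 molecules and 20 000 frames, sized so a full train-and-estimate
run takes minutes on one CPU; at that scale evaluation batches use the full
5 000-frame validation split rather than the 10⁴ frames appropriate to
200 000-frame production data sets.

Because the potential is exactly quadratic, the free energy is closed-form
(\(f = \tfrac12\sum_i \ln(\lambda_i/2\pi)\) over the constrained-subspace
eigenvalues), every frame carries an exact \(\beta U\), equipartition holds
exactly in expectation, and — decisive for testing — every interpolated ECM
window is itself Gaussian and is sampled directly, with no Markov chain.
What the fixture does *not* emulate: anharmonicity, inter-site
correlations, proton disorder, or the autocorrelation of real MD data. A
passing end-to-end recovery therefore validates the estimators and the
exactness of the maps, not the adequacy of any force field; real-data use
goes through the MD adapter descriptor (`md_adapter_config()`), which
encodes the full sampling protocol (PME 1e-5, cutoff 0.31 nm, switching
0.279 nm, Langevin middle scheme at 20 ps\(^{-1}\), 2 fs steps, frames every
100 fs, NPT pre-equilibration at 1 atm) but deliberately does not drive an
engine.

## Finite-size extrapolation

`extrapolate_thermo_limit()` fits \(\Delta f\) against \(1/n_{\mathrm{mol}}\)
by unweighted ordinary least squares and reports the intercept as the
thermodynamic-limit value, with the intercept SE from propagating the
per-point errors through the fixed OLS coefficients. Unweighted OLS is
deliberate: it reproduces tabulated infinite-size entries exactly from the
corresponding finite-size values, which inverse-variance weighting does not,
and it is exact on noise-free data linear in \(1/n_{\mathrm{mol}}\). The
intercept-SE convention of reference tables is not always stated; the
OLS-propagated value here is close to, but not forced onto, any particular
reported uncertainty.

## Numerical edge cases

* `sign(0) = +1` resolves the measure-zero hemisphere boundary.
* Undefined hyperspherical angles at singular points are set to 0,
  deterministically, so round-trip tests can exclude singular sets exactly.
* Spline bins have a minimum fractional width of \(10^{-3}\); derivatives
  use a shifted softplus so zero parameters give the identity.
* Non-finite generalized-work entries are excluded and reported; work sets
  excluding more than 0.1% are flagged as failures.
* The whitening fit requires *exactly* three near-null eigenvalues
  (relative threshold \(10^{-10}\)); fewer or more indicate un-centred
  input.

## Package shape

Coordinate ensembles are arrays inside lightweight S3 containers (a
`supercell_frames` holds an `n_frames x n_atoms x 3` array plus roles and
molecule ids); everything naturally tabular — training records, free-energy
estimates, lambda chains, size series — is a tibble, with `tidy()`,
`glance()` and `autoplot()` methods on the fitted objects
(`fe_training`, `ecm_result`, `thermo_limit_fit`).

## Worked example

```{r example, eval = FALSE}
library(latticeflow)

spec <- harmonic_crystal_spec(n_mol = 16, seed = 3)
fx <- sample_fixture(spec, n_frames = 20000, seed = 11)

model <- build_flow_model(fx$frames, kind = "H", seed = 2)
fit <- train_flow(model, fx$frames, fx$beta_u,
                  potential = function(fr) beta_potential(fx$crystal, fr),
                  config = training_config(eval_batch = 5000, seed = 4))
fit$final          # BAR_V weighted estimate with SE

ecm <- chain_free_energy(
  sample_ecm_windows(fx$crystal, ecm_config(temperature = spec$temperature),
                     n_per_window = 2000, seed = 8)
)
glance(ecm)        # ECM estimate with SE

fx$f_analytic      # exact closed-form reference
```

Both estimates agree with the closed form within their standard errors; the
flow reaches that accuracy using only physical-ensemble samples, while the
ECM spends 23/4 times as much sampling effort on interpolated windows.
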