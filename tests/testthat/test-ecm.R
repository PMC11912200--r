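test_that("lambda schedules are deterministic with exact endpoints", {
  expect_equal(lambda_schedule(2), c(0, 1))
  even <- lambda_schedule(5, exponent = 1)
  expect_equal(even, seq(0, 1, by = 0.25))
  lam <- lambda_schedule(20)
  expect_equal(length(lam), 20)
  expect_true(all(diff(lam) > 0))
  expect_identical(lam[c(1, 20)], c(0, 1))
  expect_error(lambda_schedule(1), "at least 2")
})

test_that("the interpolated ECM potential is the stated linear mix", {
  fx <- tiny_fixture(10)
  fr <- remove_oxygen_com(fx$frames)
  cfg <- ecm_config(r0 = latticeflow:::flatten_coords(fr$coords)[1, ],
                    temperature = fx$frames$temperature)
  U <- seq_len(10) * 1.0
  u1 <- ecm_potential(1, fr, cfg, U)
  expect_equal(u1, U)               # lambda = 1 is exactly U
  u0 <- ecm_potential(0, fr, cfg, U)
  expect_equal(u0[1], 0)            # lambda = 0 at r = r0 is zero
  u_mid <- ecm_potential(0.5, fr, cfg, U)
  expect_equal(u_mid, 0.5 * U + 0.5 * u0)
  # COM drift is rejected
  drifted <- fr
  drifted$coords <- drifted$coords + 1e-3
  expect_error(ecm_potential(0.5, drifted, cfg, U), "COM drift")
})

test_that("a degenerate chain (physical system == Einstein crystal) returns f0", {
  set.seed(2)
  # emulate U == U_EC: both reduced energies identical per window
  cfg <- ecm_config(n_lambda = 5, temperature = 100)
  chain <- structure(
    list(lambda = cfg$lambda,
         windows = lapply(1:5, function(i) {
           u <- rchisq(500, df = 30) / 2
           list(beta_u = u, beta_u_ec = u, n = 500L)
         }),
         config = cfg, n_dim = 30L, n_atoms = 11L),
    class = "lambda_chain"
  )
  res <- chain_free_energy(chain)
  expect_equal(res$f, res$f0, tolerance = 1e-10)
  expect_equal(sum(res$pairs$delta_f), 0, tolerance = 1e-10)
})

test_that("a Gaussian-to-Gaussian chain recovers the log width ratio", {
  # physical = isotropic Gaussian with twice the tether stiffness:
  # f_phys - f_EC = (d/2) ln 2, assembled through the full lambda chain
  set.seed(6)
  d <- 40L
  kT <- kT_kJ_per_mol(100)
  cfg <- ecm_config(k = 1000, n_lambda = 10, temperature = 100)
  bk <- cfg$k / kT
  lam <- cfg$lambda
  windows <- lapply(seq_along(lam), function(i) {
    prec <- lam[i] * 2 * bk + (1 - lam[i]) * bk
    x2 <- rowSums(matrix(rnorm(3000 * d, sd = sqrt(1 / prec)), 3000)^2)
    list(beta_u = bk * x2, beta_u_ec = 0.5 * bk * x2, n = 3000L)
  })
  chain <- structure(
    list(lambda = lam, windows = windows, config = cfg, n_dim = d,
         n_atoms = d / 3),
    class = "lambda_chain"
  )
  res <- chain_free_energy(chain, f0 = 0)
  expect_lt(abs(res$f - d / 2 * log(2)), 3 * res$se)
})

test_that("f0 obeys the Gaussian scaling law and mass conventions", {
  cfg1 <- ecm_config(k = 6e3, temperature = 150)
  cfg2 <- ecm_config(k = 1.2e4, temperature = 150)
  n_at <- 48L
  # doubling beta k halves every Gaussian variance: f0 rises by 3(N-1)/2 ln 2
  expect_equal(analytic_f0(cfg2, n_at) - analytic_f0(cfg1, n_at),
               (3 * (n_at - 1) / 2) * log(2), tolerance = 1e-12)
  # equal masses: the delta-convention COM term gains the 1/N factor
  cfg1$masses <- rep(18, n_at)
  expect_equal(
    analytic_f0(cfg1, n_at, convention = "delta") -
      analytic_f0(cfg1, n_at, convention = "orthonormal"),
    1.5 * log(1 / n_at), tolerance = 1e-12
  )
  # the volume term
  expect_equal(
    analytic_f0(cfg1, n_at, V = 8, include_volume_term = TRUE) -
      analytic_f0(cfg1, n_at),
    -log(8), tolerance = 1e-12
  )
  expect_error(analytic_f0(cfg1, n_at, include_volume_term = TRUE), "positive")
})

test_that("the full ECM chain recovers the analytic fixture free energy", {
  fx <- tiny_fixture(100)
  cr <- fx$crystal
  cfg <- ecm_config(temperature = cr$spec$temperature)
  ch <- sample_ecm_windows(cr, cfg, n_per_window = 1500, seed = 8)
  # the lambda = 1 window is sampled 4x longer
  expect_equal(ch$windows[[20]]$n, 4L * 1500L)
  expect_equal(ch$windows[[1]]$n, 1500L)
  res <- chain_free_energy(ch)
  expect_lt(abs(res$f - cr$f_analytic), 3 * res$se)
  expect_equal(sum(res$pairs$flagged), 0)
  # schedule-shape invariance within stochastic error
  cfg2 <- ecm_config(temperature = cr$spec$temperature, half_width = 5.5)
  res2 <- chain_free_energy(sample_ecm_windows(cr, cfg2, 1500, seed = 9))
  expect_lt(abs(res2$f - res$f), 3 * sqrt(res$se^2 + res2$se^2))
  # tidy accessors and plotting
  expect_equal(nrow(tidy(res)), 19)
  expect_equal(glance(res)$f, res$f)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})

test_that("physical-ensemble sampling fraction matches the window arithmetic", {
  expect_equal(ecm_sampling_fraction(), 4 / 23)
  expect_equal(round(100 * ecm_sampling_fraction(), 1), 17.4)
  expect_equal(ecm_sampling_fraction(2, 1), 0.5)
})

test_that("chain estimates stabilise and their errors shrink with more window data", {
  fx <- tiny_fixture(100)
  cr <- fx$crystal
  cfg <- ecm_config(temperature = cr$spec$temperature)
  small <- chain_free_energy(sample_ecm_windows(cr, cfg, 300, seed = 4))
  large <- chain_free_energy(sample_ecm_windows(cr, cfg, 1200, seed = 4))
  expect_lt(large$se, small$se)
  expect_lt(abs(large$f - cr$f_analytic), abs(small$f - cr$f_analytic) + 3 * small$se)
})
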