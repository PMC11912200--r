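# Training behaviour on a small harmonic crystal: these runs use a narrow
# conditioner and a few dozen steps so the whole file stays fast; the
# full-scale 16-molecule recovery lives in the acceptance suite.

small_training_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fx <- tiny_fixture(6000)
    mod <- build_flow_model(fx$frames, "H", seed = 2, hidden = 48)
    pot <- function(fr) beta_potential(fx$crystal, fr)
    cfg <- training_config(train_batch = 500, eval_batch = 1000,
                           max_steps = 250, eval_stride = 25, seed = 4,
                           plateau_tol = 0)
    cache <<- list(fx = fx, tr = train_flow(mod, fx$frames, fx$beta_u, pot, cfg),
                   cfg = cfg)
    cache
  }
})

test_that("the ML loss is -mean(generalized work) and shift-invariant in gradient", {
  fx <- tiny_fixture(200)
  mod <- build_flow_model(fx$frames, "H", seed = 1, hidden = 16)
  ml <- ml_loss(mod, fx$frames, fx$beta_u)
  lq <- flow_log_prob(mod, fx$frames)
  expect_equal(ml$loss, -mean(fx$beta_u + lq), tolerance = 1e-12)
  expect_equal(ml$n_nonfinite, 0L)
  # adding a constant to beta U shifts the loss by exactly that constant
  ml2 <- ml_loss(mod, fx$frames, fx$beta_u + 5)
  expect_equal(ml2$loss, ml$loss - 5, tolerance = 1e-10)
})

test_that("evaluation cadence follows the stride accounting", {
  run <- small_training_run()
  expect_equal(nrow(run$tr$records), 250 / 25)
  expect_equal(run$tr$records$step, seq(25, 250, by = 25))
})

test_that("training improves the likelihood and recovers the analytic f", {
  run <- small_training_run()
  fx <- run$fx
  rec <- run$tr$records
  # f_ML (negative validation loss) rises toward f as KL(p||q) shrinks
  expect_gt(tail(rec$f_ml, 1), rec$f_ml[1])
  expect_lt(abs(tail(rec$f_ml, 1) - fx$f_analytic), 5)
  # final weighted estimate within 3 SE of the closed form
  expect_lt(abs(run$tr$final$f - fx$f_analytic), 3 * run$tr$final$se)
  # broom accessors and plotting
  expect_s3_class(tidy(run$tr$records), "tbl_df")
  expect_equal(glance(run$tr$records)$f_bar, run$tr$final$f)
  expect_s3_class(ggplot2::autoplot(run$tr$records, true_f = fx$f_analytic),
                  "ggplot")
})

test_that("a trained flow is normalized: importance ratio against the exact density", {
  run <- small_training_run()
  fx <- run$fx
  mod <- run$tr$model
  # bridge estimator of the total mass: with mixture proposal
  # m = (p + q)/2 the ratio q/m = 2/(1 + p/q) is bounded by 2, so
  # E_m[q/m] = 1 has finite variance whenever both densities are normalized
  # (p is the fixture's exact density, q the trained flow)
  set.seed(31)
  n_half <- 2000
  s <- flow_sample(mod, n_half)
  lq_q <- s$log_q
  lp_q <- -beta_potential(fx$crystal, s$frames) + fx$f_analytic
  # fresh, fully held-out physical samples (training frames would bias the
  # expectation because q was adapted to them)
  fresh <- sample_fixture(fx$crystal, n_frames = n_half, seed = 77)
  lq_p <- flow_log_prob(mod, fresh$frames)
  lp_p <- -fresh$beta_u + fx$f_analytic
  ratio <- 2 / (1 + exp(c(lp_q - lq_q, lp_p - lq_p)))
  se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
})

test_that("training runs are bit-reproducible for a fixed seed", {
  fx <- tiny_fixture(2000)
  pot <- function(fr) beta_potential(fx$crystal, fr)
  cfg <- training_config(train_batch = 200, eval_batch = 300, max_steps = 50,
                         eval_stride = 25, seed = 7)
  t1 <- suppressWarnings(
    train_flow(build_flow_model(fx$frames, "H", seed = 3, hidden = 16),
               fx$frames, fx$beta_u, pot, cfg)
  )
  t2 <- suppressWarnings(
    train_flow(build_flow_model(fx$frames, "H", seed = 3, hidden = 16),
               fx$frames, fx$beta_u, pot, cfg)
  )
  expect_identical(t1$records$f, t2$records$f)
  expect_identical(t1$records$se, t2$records$se)
  expect_identical(t1$records$f_ml, t2$records$f_ml)
})

test_that("oversized evaluation batches fall back to sampling with replacement", {
  fx <- tiny_fixture(400)
  pot <- function(fr) beta_potential(fx$crystal, fr)
  cfg <- training_config(train_batch = 100, eval_batch = 500, max_steps = 25,
                         eval_stride = 25, seed = 2)
  suppressWarnings(expect_message(
    tr <- train_flow(build_flow_model(fx$frames, "H", seed = 3, hidden = 16),
                     fx$frames, fx$beta_u, pot, cfg),
    "replacement"
  ))
  expect_equal(tr$records$step, 25)
})

test_that("two independently trained flows recover the analytic polymorph difference", {
  spec_a <- harmonic_crystal_spec(n_mol = 4, seed = 21)
  spec_b <- harmonic_crystal_spec(n_mol = 4, seed = 22, k_pos = 9e3, k_rot = 120,
                                  spacing = 0.43)
  pair <- two_polymorph_fixture(spec_a, spec_b, n_frames = 6000, seed = 13)
  cfg <- training_config(train_batch = 500, eval_batch = 1000, max_steps = 200,
                         eval_stride = 25, seed = 5, plateau_tol = 0)
  fits <- lapply(list(pair$a, pair$b), function(fx) {
    suppressWarnings(train_flow(
      build_flow_model(fx$frames, "H", seed = 6, hidden = 48),
      fx$frames, fx$beta_u,
      potential = function(fr) beta_potential(fx$crystal, fr),
      config = cfg
    ))$final
  })
  delta_hat <- fits[[1]]$f - fits[[2]]$f
  comb_se <- sqrt(fits[[1]]$se^2 + fits[[2]]$se^2)
  expect_true(is.finite(comb_se))
  expect_lt(abs(delta_hat - pair$delta_f), 3 * comb_se)
})
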