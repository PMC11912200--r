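test_that("generalized work is the elementwise sum with strict alignment", {
  expect_equal(generalized_work(1, -3), -2)
  expect_equal(generalized_work(c(1, 2), c(-1, -2)), c(0, 0))
  expect_error(generalized_work(1:3, 1:2), "mismatch")
})

test_that("BAR recovers the closed-form Gaussian free energy within 3 SE", {
  set.seed(1)
  n <- 1e4
  # physical p: unnormalized exp(-x^2/2), Z = sqrt(2*pi), f = -ln Z
  # model q: N(0.5, 1), normalized
  ln_q <- function(x) dnorm(x, 0.5, log = TRUE)
  xq <- rnorm(n, 0.5)
  xp <- rnorm(n)
  ws <- work_set(phi_p = xp^2 / 2 + ln_q(xp), phi_q = xq^2 / 2 + ln_q(xq))
  est <- bar_v(ws)
  f_true <- -log(sqrt(2 * pi))
  expect_lt(abs(est$f - f_true), 3 * est$se)
  expect_false(est$flagged)
})

test_that("perfect-map work sets give f exactly with vanishing SE", {
  # ln q = -beta U (Z = 1): every work value equals f = 0
  ws <- work_set(phi_p = rep(0, 500), phi_q = rep(0, 400))
  est <- bar_v(ws)
  expect_equal(est$f, 0, tolerance = 1e-8)
  expect_lt(est$se, 1e-6)
})

test_that("BAR is antisymmetric under swapping the two states", {
  set.seed(3)
  w_f <- rnorm(2000, 1); w_r <- rnorm(2000, 1)
  s1 <- latticeflow:::bar_solve(w_f, w_r)
  s2 <- latticeflow:::bar_solve(w_r, w_f)
  expect_equal(s1$df, -s2$df, tolerance = 1e-8)
  expect_equal(s1$se, s2$se, tolerance = 1e-8)
})

test_that("shifting ln q by a constant shifts the BAR estimate by that constant", {
  # q e^c is unnormalized with free energy -c, so the estimated f moves by
  # +c; verified against the Gaussian pair
  set.seed(4)
  n <- 5000; c0 <- 1.7
  ln_q <- function(x) dnorm(x, 0.5, log = TRUE)
  xq <- rnorm(n, 0.5); xp <- rnorm(n)
  base <- bar_v(work_set(xp^2 / 2 + ln_q(xp), xq^2 / 2 + ln_q(xq)))
  shift <- bar_v(work_set(xp^2 / 2 + ln_q(xp) + c0, xq^2 / 2 + ln_q(xq) + c0))
  expect_equal(shift$f, base$f + c0, tolerance = 1e-6)
})

test_that("analytic BAR standard errors are calibrated", {
  set.seed(5)
  ln_q <- function(x) dnorm(x, 0.5, log = TRUE)
  reps <- vapply(1:150, function(i) {
    xq <- rnorm(800, 0.5); xp <- rnorm(800)
    s <- latticeflow:::bar_solve(xq^2 / 2 + ln_q(xq), -(xp^2 / 2 + ln_q(xp)))
    c(s$df, s$se)
  }, numeric(2))
  ratio <- sd(reps[1, ]) / mean(reps[2, ])
  expect_gt(ratio, 0.7)
  expect_lt(ratio, 1.3)
})

test_that("no-overlap work sets are flagged with an infinite-SE sentinel", {
  ws <- work_set(phi_p = rnorm(200, -60), phi_q = rnorm(200, 60))
  est <- bar_v(ws)
  expect_true(est$flagged)
  expect_identical(est$se, Inf)
})

test_that("weighted running averages combine estimates as specified", {
  one <- weighted_running_average(2.5, 0.1, f_ml = 0)
  expect_equal(one$f_bar, 2.5)
  expect_equal(one$se_bar, 0.1)
  eq <- weighted_running_average(c(1, 3), c(0.1, 0.3), weights = c(1, 1))
  expect_equal(tail(eq$f_bar, 1), 2)
  expect_equal(tail(eq$se_bar, 1), 0.2)
  wt <- weighted_running_average(c(1, 3), c(0.1, 0.3), weights = c(1, 3))
  expect_equal(tail(wt$f_bar, 1), 2.5)
  # invariant under weight rescaling
  wt2 <- weighted_running_average(c(1, 3), c(0.1, 0.3), weights = c(10, 30))
  expect_equal(wt$f_bar, wt2$f_bar)
  # constant f_ml reduces to the plain running mean
  un <- weighted_running_average(c(1, 2, 6), c(1, 1, 1), f_ml = c(5, 5, 5))
  expect_equal(un$f_bar, cumsum(c(1, 2, 6)) / 1:3)
  # softmax weighting down-weights low-f_ml (early/overfit) estimates
  sm <- weighted_running_average(c(10, 2), c(1, 1), f_ml = c(0, -20))
  expect_lt(abs(tail(sm$f_bar, 1) - 10), 1e-6)
  expect_warning(weighted_running_average(c(1, 2), c(1, 1), weights = c(0, 0)),
                 "degenerate")
})

test_that("entropy decomposition matches hand values and Gaussian closed forms", {
  expect_equal(entropy_per_molecule(10, 4, 2), 3)
  expect_equal(entropy_per_molecule(7, 7, 3), 0)
  # 1D harmonic oscillator with beta k = 2 pi: Z = 1 so f = 0, <beta U> = 1/2
  bk <- 2 * pi
  f <- 0.5 * log(bk / (2 * pi))
  expect_equal(f, 0)
  expect_equal(entropy_per_molecule(0.5, f, 1), 0.5)
  expect_error(entropy_per_molecule(1, 1, 0), "positive")
})

test_that("work sets report and exclude non-finite entries", {
  expect_warning(work_set(c(1, NaN, rep(0, 8)), rep(0, 10)), "non-finite")
  ws <- suppressWarnings(work_set(c(1, Inf), c(2, 3)))
  expect_equal(ws$phi_p, 1)
  expect_equal(ws$excluded_frac, 0.25)
})
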