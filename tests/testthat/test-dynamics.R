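test_that("map extrema agree with a dense-grid oracle and obey odd symmetry", {
  mp <- mp_default()
  for (C in c(0, 0.3)) {
    cp <- cp_auto(C = C)
    ma <- find_map_extrema(mp, cp)
    expect_false(ma$no_extremum)
    # oracle: 1e6-point grid on [0, 3] with parabolic refinement of the peak
    xs <- seq(0, 3, length.out = 1e6 + 1)
    g <- map_G(xs, mp, cp)
    i <- which.max(g)
    h <- xs[2] - xs[1]
    denom <- g[i - 1] - 2 * g[i] + g[i + 1]
    x_ref <- xs[i] + h * (g[i - 1] - g[i + 1]) / (2 * denom)
    f_ref <- map_G(x_ref, mp, cp)
    expect_equal(ma$f_max, f_ref, tolerance = 1e-6)
    expect_equal(ma$x_max, x_ref, tolerance = 1e-4)
    # odd symmetry about x_d = 0
    expect_equal(ma$f_min, -ma$f_max, tolerance = 1e-6)
  }
})

test_that("extremum search is insensitive to the coarse-grid resolution", {
  mp <- mp_default()
  cp <- cp_auto(C = 0.2)
  fine <- find_map_extrema(mp, cp, n_grid = 10001L)
  coarse <- find_map_extrema(mp, cp, n_grid = 1025L)
  expect_equal(coarse$f_max, fine$f_max, tolerance = 1e-8)
  expect_equal(coarse$f_min, fine$f_min, tolerance = 1e-8)
})

test_that("a monotone composite map yields an explicit no-extremum result", {
  # excitation only: F is strictly increasing, no interior extremum
  mp <- model_params(A = 0.01, B = 5.821, K = 0.9)
  ma <- find_map_extrema(mp, cp_auto())
  expect_true(ma$no_extremum)
  expect_true(is.na(merging_condition(mp, cp_auto())$merged))
})

test_that("RRO feedback lowers the extremal values monotonically in C", {
  mp <- mp_default()
  f <- vapply(seq(0, 0.5, by = 0.1),
              function(C) find_map_extrema(mp, cp_auto(C = C))$f_max,
              numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("merging condition flips from merged to separated as feedback grows", {
  mp <- mp_default()  # A = 13, K = 0.9
  m0 <- merging_condition(mp, cp_auto(C = 0))
  expect_true(m0$merged)
  expect_lt(m0$g_at_fmax, 0)
  expect_gt(m0$g_at_fmin, 0)
  m5 <- merging_condition(mp, cp_auto(C = 0.5))
  expect_false(m5$merged)
  expect_gt(m5$g_at_fmax, 0)
  # odd symmetry of the once-iterated extremal values
  expect_equal(m0$g_at_fmax, -m0$g_at_fmin, tolerance = 1e-6)
  expect_equal(m5$g_at_fmax, -m5$g_at_fmin, tolerance = 1e-6)
})

test_that("Lyapunov exponent separates chaotic from periodic regimes", {
  sc <- sim_config(n_transient = 1000, n_samples = 10000, seed = 3)
  le_chaos <- lyapunov_exponent(mp_default(K = 0.9), cp_auto(), sc)
  expect_gt(le_chaos$lambda, 0)
  expect_true(le_chaos$chaotic)
  le_per <- lyapunov_exponent(mp_default(K = 1.0), cp_auto(), sc)
  expect_lt(le_per$lambda, 0)
  expect_false(le_per$chaotic)
})

test_that("perturbation-method Lyapunov estimate matches the closed-form derivative oracle", {
  sc <- sim_config(n_transient = 1000, n_samples = 20000, seed = 11)
  for (pars in list(list(K = 0.9, C = 0), list(K = 0.9, C = 0.2),
                    list(K = 1.0, C = 0))) {
    mp <- mp_default(K = pars$K)
    cp <- cp_auto(C = pars$C)
    le <- lyapunov_exponent(mp, cp, sc, M = 20000, x0 = 0.61)
    # oracle: ergodic average of ln |G'(x)| along an independent orbit
    x <- 0.61
    for (i in 1:1000) x <- map_G(x, mp, cp)
    acc <- 0
    for (i in 1:20000) {
      acc <- acc + log(abs(map_G_deriv(x, mp, cp)))
      x <- map_G(x, mp, cp)
    }
    expect_equal(le$lambda, acc / 20000, tolerance = 0.01)
  }
})

test_that("Lyapunov estimator is stable under doubling M and halving d0", {
  mp <- mp_default()
  sc <- sim_config(n_transient = 1000, n_samples = 20000, seed = 7)
  base <- lyapunov_exponent(mp, cp_auto(), sc, M = 10000, d0 = 1e-8, x0 = 0.5)
  more <- lyapunov_exponent(mp, cp_auto(), sc, M = 20000, d0 = 1e-8, x0 = 0.5)
  finer <- lyapunov_exponent(mp, cp_auto(), sc, M = 10000, d0 = 5e-9, x0 = 0.5)
  expect_equal(base$lambda, more$lambda, tolerance = 0.01)
  expect_equal(base$lambda, finer$lambda, tolerance = 0.01)
})

test_that("Lyapunov estimator validates its arguments", {
  mp <- mp_default()
  sc <- sim_config(n_samples = 1000)
  expect_error(lyapunov_exponent(mp, cp_auto(), sc, d0 = 0), "d0")
  expect_error(lyapunov_exponent(mp, cp_auto(), sc, M = 2000), "exceeds")
  expect_warning(lyapunov_exponent(mp, control_params(alpha = 0.15), sc,
                                   M = 1000), "autonomous")
})

test_that("critical feedback strength is a bracketed root of G(f_max)", {
  mp <- mp_default(K = 0.9)
  cc <- critical_feedback_strength(mp, cp_auto(), tol = 1e-4)
  expect_false(cc$no_transition)
  # root property: |G(f_max)| small at C*, sign change across the bracket
  expect_lt(abs(cc$g_at_fmax), 1e-3)
  g_at <- function(C) merging_condition(mp, cp_auto(C = C))$g_at_fmax
  expect_lt(g_at(cc$C_star - 1e-3), 0)
  expect_gt(g_at(cc$C_star + 1e-3), 0)
})

test_that("no-transition C ranges are reported explicitly", {
  # K = 1.0, A = 13: attractors already separated at C = 0
  cc <- critical_feedback_strength(mp_default(K = 1.0), cp_auto())
  expect_true(cc$no_transition)
  expect_true(is.na(cc$C_star))
})

test_that("merging flag predicts orbit sign-switching behaviour", {
  mp <- mp_default()
  sc <- sim_config(n_transient = 1000, n_samples = 20000, seed = 13)
  for (C in c(0, 0.1, 0.35, 0.5)) {
    ma <- merging_condition(mp, cp_auto(C = C))
    le <- lyapunov_exponent(mp, cp_auto(C = C), sc, x0 = 0.9)
    tr <- iterate(mp, cp_auto(C = C), sc, x0 = 0.9)
    switches <- sum(diff(tr$X) != 0)
    if (!ma$merged) {
      expect_identical(switches, 0L)
    } else if (le$lambda > 1e-3) {
      expect_gt(switches, 0L)
    }
  }
})
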