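test_that("bifurcation sweep returns aligned samples and metrics per grid point", {
  mp <- mp_default()
  sc <- sc_short()
  grid <- seq(0, 0.5, by = 0.1)
  bs <- sweep_bifurcation(mp, cp_auto(), sc, "C", grid, n_keep = 50, M = 2000)
  expect_s3_class(bs, "bifurcation_sweep")
  expect_identical(nrow(bs$metrics), length(grid))
  expect_identical(nrow(bs$samples), length(grid) * 2L * 50L)
  expect_setequal(unique(bs$samples$trial), c("pos", "neg"))
  # separated attractors: positive-start and negative-start samples keep
  # their sign; merged: at least one trial mixes signs somewhere on the grid
  for (i in seq_along(grid)) {
    sub <- bs$samples[bs$samples$C == grid[i], ]
    if (!bs$metrics$merged[i]) {
      expect_true(all(sub$x[sub$trial == "pos"] > 0))
      expect_true(all(sub$x[sub$trial == "neg"] < 0))
    }
  }
  # single-point grid
  b1 <- sweep_bifurcation(mp, cp_auto(), sc, "C", 0.2, n_keep = 10, M = 1000)
  expect_identical(nrow(b1$metrics), 1L)
  expect_error(sweep_bifurcation(mp, cp_auto(), sc, "C", c(0.2, 0.1)),
               "increasing")
  expect_error(sweep_bifurcation(mp, cp_auto(), sc, "C", numeric(0)),
               "non-empty")
})

test_that("2D Lyapunov sweep covers the A-by-K grid and recovers known regimes", {
  sc <- sc_short()
  a_grid <- c(10.5, 13.0)
  k_grid <- c(0.9, 1.0)
  st <- sweep_lyapunov_2d(mp_default(), cp_auto(), sc, a_grid, k_grid,
                          M = 4000)
  expect_identical(nrow(st), 4L)
  expect_identical(nrow(unique(st[c("A", "K")])), 4L)
  cell <- function(A, K) st[st$A == A & st$K == K, ]
  expect_true(cell(13, 0.9)$cci)      # CCI territory
  expect_lt(cell(13, 1.0)$lambda, 0)  # periodic window
  expect_true(cell(10.5, 1.0)$cci)    # CCI at full feedback, lower inhibition
})

test_that("sync sweep aggregates trials and is reproducible under the master seed", {
  mp <- mp_default()
  sc <- sim_config(n_transient = 500, n_samples = 8000, n_trials = 4,
                   seed = 17)
  st <- sweep_sync_vs_C(mp, control_params(), sc, c_grid = c(0.05, 0.2))
  expect_identical(nrow(st), 2L)
  expect_identical(st$n_trials, rep(4L, 2))
  st2 <- sweep_sync_vs_C(mp, control_params(), sc, c_grid = c(0.05, 0.2))
  expect_identical(st, st2)
  # resonance: stronger sync at C = 0.2 than C = 0.05
  expect_gt(st$mean_max_corr[st$C == 0.2], st$mean_max_corr[st$C == 0.05])
  # per-trial table is internally consistent with the aggregate
  trials <- attr(st, "trials")
  expect_equal(mean(trials$max_corr[trials$C == 0.2]),
               st$mean_max_corr[st$C == 0.2])
})

test_that("adding trials never perturbs earlier trials", {
  mp <- mp_default()
  cp <- control_params()
  sc3 <- sim_config(n_transient = 500, n_samples = 4000, n_trials = 3,
                    seed = 23)
  sc5 <- sim_config(n_transient = 500, n_samples = 4000, n_trials = 5,
                    seed = 23)
  t3 <- attr(sweep_sync_vs_C(mp, cp, sc3, 0.2), "trials")
  t5 <- attr(sweep_sync_vs_C(mp, cp, sc5, 0.2), "trials")
  expect_identical(t3$max_corr, t5$max_corr[t5$trial <= 3])
})

test_that("single-trial aggregation reports SD = 0", {
  sc1 <- sim_config(n_transient = 500, n_samples = 4000, n_trials = 1)
  st <- sweep_sync_vs_C(mp_default(), control_params(), sc1, 0.2)
  expect_identical(st$sd_max_corr, 0)
  expect_identical(st$sd_theta, 0)
})

test_that("degenerate stimulus yields feedback-only Theta and undefined correlation", {
  sc <- sim_config(n_transient = 500, n_samples = 4000, n_trials = 2)
  st <- sweep_sync_vs_C(mp_default(), control_params(), sc, 0.2, alpha = 0)
  expect_true(is.na(st$mean_max_corr))
  expect_gt(st$mean_theta, 0)  # <(Cu)^2> only
  expect_identical(st$n_pinned, st$n_trials)
})

test_that("noise sweep at D = 0 reproduces the noise-free sync point", {
  mp <- mp_default()
  cp <- control_params(C = 0.2)
  sc <- sim_config(n_transient = 500, n_samples = 8000, n_trials = 4,
                   seed = 31)
  sn <- sweep_noise(mp, cp, sc, d_grid = c(0, 0.3))
  sv <- sweep_sync_vs_C(mp, cp, sc, c_grid = 0.2)
  d0 <- sn[sn$D == 0, ]
  expect_equal(d0$mean_max_corr, sv$mean_max_corr,
               tolerance = max(2 * sv$sd_max_corr, 0.05))
  # noise degrades synchronization
  expect_lt(sn$mean_max_corr[sn$D == 0.3], d0$mean_max_corr)
  expect_error(sweep_noise(mp, cp, sc, c(0.3, 0)), "increasing")
})

test_that("CCI region extraction finds the merged-and-chaotic K band at A = 13", {
  sc <- sim_config(n_transient = 1000, n_samples = 6000, seed = 2)
  grid <- seq(0.83, 0.87, by = 0.005)
  reg <- cci_regions(mp_default(), cp_auto(), sc, "K", grid, M = 6000)
  expect_gt(nrow(reg), 0)
  expect_gt(reg$start[1], 0.83)   # no CCI at the low-K end
  expect_lt(reg$start[1], 0.86)   # band opens near K = 0.85
  # refinement keeps edges inside the grid span
  expect_true(all(reg$start >= min(grid) & reg$end <= max(grid)))
})

test_that("merged flag predicts sign-switching of bifurcation samples on a C grid", {
  mp <- mp_default()
  sc <- sim_config(n_transient = 1000, n_samples = 4000, seed = 37)
  grid <- seq(0, 0.5, length.out = 20)
  bs <- sweep_bifurcation(mp, cp_auto(), sc, "C", grid, n_keep = 100,
                          M = 4000)
  for (i in seq_along(grid)) {
    sub <- bs$samples[bs$samples$C == grid[i], ]
    pos_mixed <- length(unique(sign(sub$x[sub$trial == "pos"]))) > 1
    neg_mixed <- length(unique(sign(sub$x[sub$trial == "neg"]))) > 1
    if (!bs$metrics$merged[i]) expect_false(pos_mixed || neg_mixed)
  }
})

test_that("the synchronization peak tracks the attractor-merging threshold across K", {
  # the resonance peak sits at feedback strength slightly below the
  # merging-to-separation point C*; as the attenuation K grows, C* grows
  # and the peak location moves with it
  sc <- sim_config(n_transient = 1000, n_samples = 12000, n_trials = 4,
                   seed = 41)
  cg <- seq(0.05, 0.45, by = 0.05)
  peaks <- cstars <- numeric(0)
  for (K in c(0.89, 0.91)) {
    mp <- model_params(K = K)
    st <- sweep_sync_vs_C(mp, control_params(), sc, cg)
    peaks <- c(peaks, st$C[which.max(st$mean_max_corr)])
    cstars <- c(cstars, critical_feedback_strength(
      mp, control_params(alpha = 0))$C_star)
  }
  expect_true(all(peaks < cstars))
  expect_lt(peaks[1], peaks[2])
  expect_lt(cstars[1], cstars[2])
})
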