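test_that("MSD matches hand-computed values", {
  # constant trajectory
  expect_equal(compute_msd(trajectory(rep(2, 20), 0.05), 5)$msd, rep(0, 5))
  # ballistic motion: MSD(n dt) = (v n dt)^2 exactly
  v <- 0.3; dt <- 0.1
  tr <- trajectory(v * (0:49) * dt, dt)
  expect_equal(compute_msd(tr, 10)$msd, (v * (1:10) * dt)^2, tolerance = 1e-12)
  # alternating positions
  expect_equal(compute_msd(trajectory(c(0, 1, 0, 1, 0), 1), 4)$msd,
               c(1, 0, 1, 0))
})

test_that("MSD equals the double-loop evaluation on random trajectories", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(12:40, 1)
    y <- stats::rnorm(N)
    tr <- trajectory(y, 0.05)
    n_max <- sample(3:10, 1)
    expect_equal(compute_msd(tr, n_max)$msd, msd_brute(y, n_max),
                 tolerance = 1e-12)
  }
})

test_that("MSD has the right pair counts and rejects short trajectories", {
  msd <- compute_msd(trajectory(stats::rnorm(25), 0.05), 10)
  expect_equal(msd$n_pairs, 25 - (1:10))
  expect_error(compute_msd(trajectory(stats::rnorm(10), 0.05), 10), "n_max")
})

test_that("MSD is invariant to time reversal and position offsets", {
  set.seed(32)
  y <- cumsum(stats::rnorm(60, 0, 0.1))
  m1 <- compute_msd(trajectory(y, 0.05), 10)$msd
  expect_equal(compute_msd(trajectory(rev(y), 0.05), 10)$msd, m1)
  expect_equal(compute_msd(trajectory(y + 5, 0.05), 10)$msd, m1)
})

test_that("an exact linear MSD yields slope/2 with zero intercept", {
  D0 <- 0.05; dt <- 0.05
  tr_like <- structure(list(lags = (1:10) * dt, msd = 2 * D0 * (1:10) * dt,
                            n_pairs = 100 - (1:10), frame_interval = dt,
                            molecule_id = 1L), class = "msd_curve")
  est <- fit_diffusion_coefficient(tr_like)
  expect_equal(est$diffusion_coefficient, D0, tolerance = 1e-12)
  expect_equal(est$intercept, 0, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-10)
  # adding a constant shifts only the intercept
  shifted <- tr_like; shifted$msd <- shifted$msd + 0.004
  est2 <- fit_diffusion_coefficient(shifted)
  expect_equal(est2$slope, est$slope, tolerance = 1e-12)
  expect_equal(est2$intercept, 0.004, tolerance = 1e-12)
})

test_that("a negative MSD slope is reported as D = 0 with a flag", {
  curve <- structure(list(lags = (1:5) * 0.05, msd = rev((1:5) * 1e-3),
                          n_pairs = 50 - (1:5), frame_interval = 0.05,
                          molecule_id = 1L), class = "msd_curve")
  est <- fit_diffusion_coefficient(curve)
  expect_equal(est$diffusion_coefficient, 0)
  expect_true(est$nonphysical)
})

test_that("mobility classification separates static noise from diffusion", {
  sigma <- 0.08 / 3
  # static molecule observed with localization noise only
  set.seed(33)
  tr_static <- trajectory(2 + stats::rnorm(200, 0, sigma), 0.05)
  est_static <- fit_diffusion_coefficient(compute_msd(tr_static))
  expect_false(classify_mobile(est_static, noise_sigma = sigma))
  # freely diffusing molecule
  cfg <- simulation_config(diffusion_coefficient = 0.1, n_frames = 200,
                           localization_sigma = sigma, seed = 34)
  tr_mob <- simulate_trajectory(cfg)$trajectory
  est_mob <- fit_diffusion_coefficient(compute_msd(tr_mob))
  expect_true(classify_mobile(est_mob, noise_sigma = sigma))
})

test_that("percent mobile reproduces printed count arithmetic", {
  expect_equal(percent_mobile(62, 64), 97)
  expect_equal(percent_mobile(60, 67), 90)
  expect_equal(percent_mobile(79, 81), 98)
})

test_that("condition summaries flag small samples", {
  set.seed(35)
  ests <- lapply(1:10, function(i) {
    cfg <- simulation_config(diffusion_coefficient = 0.1, n_frames = 100,
                             seed = 350 + i)
    fit_diffusion_coefficient(compute_msd(simulate_trajectory(cfg)$trajectory))
  })
  s <- summarize_condition(ests, condition = "small")
  expect_false(s$reportable)
  expect_equal(s$n_molecules, 10)
})

test_that("estimator bias shrinks with trajectory length", {
  D0 <- 0.1
  bias_at <- function(n_frames, seed0) {
    cfg <- simulation_config(diffusion_coefficient = D0, n_frames = n_frames,
                             localization_sigma = 0, dna_length = 300,
                             start_position = 150, seed = seed0)
    sims <- simulate_ensemble(cfg, 100)
    d <- vapply(sims$trajectories, function(tr)
      fit_diffusion_coefficient(compute_msd(tr))$diffusion_coefficient, 1)
    abs(mean(d) - D0) / D0
  }
  b <- c(bias_at(100, 41), bias_at(400, 42), bias_at(1600, 43))
  expect_lt(b[3], 0.05)
  expect_lt(b[3], b[1] + 0.02)
})

test_that("K-S comparison matches the brute-force ECDF oracle", {
  r <- compare_diffusion(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  r <- compare_diffusion(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 1)
  expect_true(r$significant == (r$p_value < 0.05))
  r <- compare_diffusion(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, ks_stat_brute(c(1, 2, 3), c(2, 3, 4)))
  set.seed(36)
  for (i in 1:20) {
    a <- stats::runif(sample(5:30, 1))
    b <- stats::runif(sample(5:30, 1))
    expect_equal(compare_diffusion(a, b)$statistic, ks_stat_brute(a, b),
                 tolerance = 1e-12)
  }
})
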