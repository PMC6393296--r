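test_that("zero diffusion and zero noise give a constant trajectory", {
  cfg <- simulation_config(diffusion_coefficient = 0, localization_sigma = 0,
                           n_frames = 50, start_position = 3, seed = 1)
  sim <- simulate_trajectory(cfg)
  expect_equal(sim$trajectory$positions, rep(3, 50))
  expect_equal(sim$ground_truth$true_positions, rep(3, 50))
})

test_that("per-step displacement variance matches 2 D dt", {
  cfg <- simulation_config(diffusion_coefficient = 0.1, frame_interval = 0.05,
                           localization_sigma = 0, n_frames = 10000,
                           dna_length = 100, start_position = 50, seed = 2)
  sim <- simulate_trajectory(cfg)
  v <- stats::var(diff(sim$ground_truth$true_positions))
  expect_lt(abs(v - 2 * 0.1 * 0.05) / (2 * 0.1 * 0.05), 0.05)
})

test_that("an impermeable obstacle is never crossed", {
  cfg <- simulation_config(diffusion_coefficient = 0.5, n_frames = 5000,
                           localization_sigma = 0, obstacle_positions = 6,
                           obstacle_bypass_prob = 0, start_position = 2,
                           seed = 3)
  sim <- simulate_trajectory(cfg)
  expect_true(all(sim$ground_truth$true_positions < 6))
  expect_true(all(!sim$ground_truth$crossings$crossed))
  expect_gt(nrow(sim$ground_truth$crossings), 0)
})

test_that("identical seed and config reproduce the simulation exactly", {
  cfg <- simulation_config(diffusion_coefficient = 0.3, n_frames = 200,
                           obstacle_positions = c(4, 8),
                           obstacle_bypass_prob = 0.4, seed = 7)
  a <- simulate_trajectory(cfg)
  b <- simulate_trajectory(cfg)
  expect_identical(a, b)
  ea <- simulate_ensemble(cfg, 3)
  eb <- simulate_ensemble(cfg, 3)
  expect_identical(ea, eb)
})

test_that("ensemble MSD of the free walk matches 2 D t at the first ten lags", {
  D <- 0.1; dt <- 0.05
  cfg <- simulation_config(diffusion_coefficient = D, frame_interval = dt,
                           localization_sigma = 0, n_frames = 400,
                           dna_length = 200, start_position = 100, seed = 4)
  sims <- simulate_ensemble(cfg, 100)
  per_lag <- sapply(sims$trajectories, function(tr) compute_msd(tr, 10)$msd)
  m <- rowMeans(per_lag)
  se <- apply(per_lag, 1, stats::sd) / sqrt(ncol(per_lag))
  expected <- 2 * D * (1:10) * dt
  expect_true(all(abs(m - expected) < 3 * se))
})

test_that("crossing success frequency converges to the bypass probability", {
  p0 <- 0.5
  cfg <- simulation_config(diffusion_coefficient = 1, frame_interval = 0.1,
                           localization_sigma = 0, n_frames = 10000,
                           obstacle_positions = 6.5, obstacle_bypass_prob = p0,
                           seed = 5)
  sims <- simulate_ensemble(cfg, 5)
  crossings <- do.call(rbind, lapply(sims$ground_truths, `[[`, "crossings"))
  expect_gte(nrow(crossings), 1000)
  bt <- stats::binom.test(sum(crossings$crossed), nrow(crossings), p = p0)
  expect_gt(bt$p.value, 0.01)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_config(diffusion_coefficient = -1), "diffusion")
  expect_error(simulation_config(frame_interval = 0), "frame_interval")
  expect_error(simulation_config(obstacle_bypass_prob = 1.2), "bypass_prob")
  expect_error(simulation_config(obstacle_positions = 99), "obstacle_positions")
})

test_that("a noiseless static spot peaks at the pixel containing the molecule", {
  tr <- trajectory(rep(2.03, 5), frame_interval = 0.05)
  stack <- simulate_image_stack(list(tr), noise_model = "none",
                                amplitude = 500, background = 10,
                                pixel_size = 0.1)
  img <- stack$frames[[1]]
  peak <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(peak[1, "col"]), 21)  # pixel 21 spans 2.0-2.1 um
})

test_that("zero amplitude leaves only background", {
  tr <- trajectory(rep(1, 3), frame_interval = 0.05)
  stack <- simulate_image_stack(list(tr), amplitude = 0, background = 7,
                                noise_model = "none")
  expect_true(all(vapply(stack$frames, function(f) all(f == 7), TRUE)))
})

test_that("mismatched frame counts are rejected", {
  t1 <- trajectory(rep(1, 5), frame_interval = 0.05)
  t2 <- trajectory(rep(2, 6), frame_interval = 0.05)
  expect_error(simulate_image_stack(list(t1, t2)), "mismatched")
})

test_that("a noiseless bleach trace of one fluorophore has one exact unit step", {
  tr <- simulate_bleach_trace(1, unit_intensity = 80, noise_sd = 0,
                              bleach_prob_per_frame = 0.05, n_frames = 100,
                              seed = 6)
  st <- detect_bleach_steps(tr)
  expect_equal(st$n_steps, 1L)
  expect_equal(st$step_heights, 80, tolerance = 1e-12)
  expect_equal(st$step_frames, tr$bleach_frames)
})

test_that("zero fluorophores give a flat background trace", {
  tr <- simulate_bleach_trace(0, noise_sd = 0, n_frames = 50, background = 5)
  expect_true(all(tr$intensities == 5))
})

test_that("mutation rate zero yields only mutant-free cultures", {
  fa <- simulate_fluctuation_cultures(50, 1e7, 0, seed = 8)
  expect_true(all(fa$mutant_count == 0))
})

test_that("the zero-mutant fraction matches the Poisson zero class", {
  # m = mu * N = 2, so P(no mutation event) = exp(-2)
  n <- 3000
  fa <- simulate_fluctuation_cultures(n, 2^20, 2 / 2^20, seed = 9)
  p0 <- mean(fa$mutant_count == 0)
  expect_lt(abs(p0 - exp(-2)), 3 * sqrt(exp(-2) * (1 - exp(-2)) / n))
})

test_that("mutant counts match a direct birth-process simulation", {
  # N = 2^10 cells, m = 2 expected mutations per culture
  g <- 10L; N <- 2^g; mu <- 2 / N
  fa <- simulate_fluctuation_cultures(2000, N, mu, seed = 10)
  set.seed(11)
  brute <- ld_birth_process(2000, g, mu)
  ks <- suppressWarnings(stats::ks.test(fa$mutant_count, brute))
  expect_lt(unname(ks$statistic), 0.05)
})
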