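test_that("hand-traced collisions classify as the rule dictates", {
  zones <- collision_zones(1, half_width = 0.08)
  # enters left, exits right: bypass
  rec <- segment_collisions(zone_trajectory(c(-0.2, -0.05, 0.05, 0.2)), zones)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$entry_side, "left")
  expect_equal(rec$exit_side, "right")
  expect_equal(rec$outcome, "bypass")
  # enters left, exits left: no bypass
  rec <- segment_collisions(zone_trajectory(c(-0.2, -0.05, -0.2)), zones)
  expect_equal(rec$outcome, "no_bypass")
  # never near the zone: nothing recorded
  rec <- segment_collisions(zone_trajectory(c(-0.5, -0.4, -0.5)), zones)
  expect_equal(nrow(rec), 0L)
})

test_that("excursions truncated by the trajectory ends are censored", {
  zones <- collision_zones(1, half_width = 0.08)
  rec <- segment_collisions(zone_trajectory(c(0.0, 0.2, 0.05, 0.02)), zones)
  expect_equal(rec$outcome, c("censored", "censored"))
  summ_err <- tryCatch(summarize_bypass(rec), error = function(e) e)
  expect_s3_class(summ_err, "error")
})

test_that("overlapping zones are merged into a compound zone", {
  zones <- collision_zones(c(1, 1.1), half_width = 0.08)
  expect_message(
    rec <- segment_collisions(zone_trajectory(c(-0.3, 0, 0.1, 0.4)), zones),
    "merged")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$outcome, "bypass")
})

test_that("bypass summaries give the binomial fraction and a valid CI", {
  rec <- data.frame(molecule_id = 1, nucleosome_id = 1,
                    entry_frame = 1:4, exit_frame = 2:5,
                    entry_side = "left",
                    exit_side = c("right", "right", "left", "left"),
                    outcome = c("bypass", "bypass", "no_bypass", "no_bypass"))
  s <- summarize_bypass(rec, seed = 1)
  expect_equal(s$p_bypass, 0.5)
  expect_true(s$ci_low >= 0 && s$ci_high <= 1 && s$ci_low <= s$ci_high)
  # degenerate all-bypass case
  rec$outcome <- "bypass"; rec$exit_side <- "right"
  s1 <- summarize_bypass(rec, seed = 1)
  expect_equal(s1$p_bypass, 1)
  expect_equal(c(s1$ci_low, s1$ci_high), c(1, 1))
})

test_that("the bootstrap CI reproduces an independent resampling loop", {
  set.seed(51)
  codes <- c(rep(1L, 30), rep(0L, 70))[sample.int(100)]
  rec <- data.frame(molecule_id = 1, nucleosome_id = 1,
                    entry_frame = seq_along(codes),
                    exit_frame = seq_along(codes) + 1,
                    entry_side = "left",
                    exit_side = ifelse(codes == 1, "right", "left"),
                    outcome = ifelse(codes == 1, "bypass", "no_bypass"))
  s <- summarize_bypass(rec, n_bootstrap = 500, seed = 99)
  # oracle: same RNG stream, literal loop
  set.seed(99)
  reps <- numeric(500)
  for (i in 1:500) reps[i] <- mean(codes[sample.int(100, replace = TRUE)])
  expect_equal(c(s$ci_low, s$ci_high),
               unname(stats::quantile(reps, c(0.025, 0.975))))
})

make_summary <- function(k, n) {
  rec <- data.frame(molecule_id = 1, nucleosome_id = 1,
                    entry_frame = 1:n, exit_frame = 1:n + 1,
                    entry_side = "left",
                    exit_side = c(rep("right", k), rep("left", n - k)),
                    outcome = c(rep("bypass", k), rep("no_bypass", n - k)))
  summarize_bypass(rec, n_bootstrap = 50, seed = 1)
}

test_that("logistic comparison of bypass matches a direct likelihood oracle", {
  r <- compare_bypass(make_summary(50, 100), make_summary(50, 100))
  expect_equal(r$log_odds_ratio, 0, tolerance = 1e-8)
  expect_gt(r$p_value, 0.99)
  r <- compare_bypass(make_summary(30, 100), make_summary(18, 100))
  expect_equal(r$method, "logistic")
  oracle <- logistic_wald_brute(30, 100, 18, 100)
  expect_equal(r$p_value, oracle, tolerance = 1e-3)  # 3 significant figures
})

test_that("complete separation falls back to Fisher's exact test", {
  r <- compare_bypass(make_summary(20, 20), make_summary(5, 20))
  expect_equal(r$method, "fisher")
  expect_true(is.finite(r$p_value))
})

test_that("macroscopic bypass rises monotonically with barrier permeability", {
  p_macro <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p0) {
    cfg <- simulation_config(diffusion_coefficient = 1, frame_interval = 0.1,
                             localization_sigma = 0, n_frames = 1500,
                             obstacle_positions = 48500 / 7500,
                             obstacle_bypass_prob = p0,
                             seed = 600 + round(100 * p0))
    sims <- simulate_ensemble(cfg, 30)
    zones <- collision_zones(48500 / 7500)
    recs <- do.call(rbind, lapply(sims$trajectories, segment_collisions,
                                  zones = zones))
    summarize_bypass(recs, n_bootstrap = 50, seed = 1)$p_bypass
  }, 1)
  expect_true(all(diff(p_macro) > -0.02))
  # impermeable limit: only sampling artifacts, below 2%
  expect_lt(p_macro[1], 0.02)
  # permeable barrier never exceeds the free-walk ceiling by more than noise
  expect_lt(max(p_macro), 0.55)
})

test_that("the free-walk reference rejects obstructed configs", {
  cfg <- simulation_config(obstacle_positions = 5, seed = 1)
  expect_error(free_walk_bypass_reference(config = cfg), "without obstacles")
})
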