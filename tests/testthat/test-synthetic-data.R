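test_that("min_jerk satisfies its closed-form properties", {
  tr <- min_jerk(10, 1.6, sample_rate = 1000)
  # endpoint reached exactly, from rest to rest
  expect_equal(tr$position[length(tr)], 10)
  expect_equal(tr$position[1], 0)
  expect_equal(tr$velocity[1], 0)
  expect_equal(tr$velocity[length(tr)], 0, tolerance = 1e-9)
  # peak speed 1.875 d / T at mid-movement
  expect_equal(max(tr$velocity), 1.875 * 10 / 1.6, tolerance = 1e-6)
  expect_equal(traj_time(tr)[which.max(tr$velocity)], 0.8, tolerance = 1e-3)
  # exactly one AZC
  expect_length(find_azc(tr), 1)
  expect_error(min_jerk(5, -1), "positive")
})

test_that("follower_params validates its invariants", {
  expect_error(follower_params(delay = 0.6), "delay")
  expect_error(follower_params(smooth_limit_mean = 0.4,
                               smooth_limit_sd = 0.15), "3 \\*")
  expect_error(follower_params(endpoint_noise_frac = -0.1), "non-negative")
  expect_silent(follower_params())
})

test_that("the follower is deterministic given a seed and degenerates to near-copy tracking", {
  st <- get_design_trials()[[5]]
  r1 <- simulate_follower(st, follower_params(), seed = 4)
  r2 <- simulate_follower(st, follower_params(), seed = 4)
  expect_identical(r1$position, r2$position)
  r3 <- simulate_follower(st, follower_params(), seed = 5)
  expect_false(identical(r1$position, r3$position))

  # smooth-limit -> infinity, all noise -> 0: a delayed near-copy, 100% CC
  p0 <- follower_params(smooth_limit_mean = Inf, endpoint_noise_frac = 0,
                        timing_noise_sd = 0,
                        correction_prob_per_excess_cm = 0)
  r0 <- simulate_follower(st, p0, seed = 1)
  an <- analyze_response(r0, st)
  expect_equal(an$registration$lag, p0$delay, tolerance = 0.011)
  expect_equal(summarize_trial(an)$percent_cc, 100)
  # positions match the delayed stimulus up to the min-jerk-vs-sine shape gap
  tt <- traj_time(st$trajectory)
  al <- an$registration$aligned_response
  ok <- !is.na(al$position)
  D_max <- max(st$sections$extent_cm)
  rms <- sqrt(mean((al$position[ok] - st$trajectory$position[ok])^2))
  expect_lt(rms, 0.04 * D_max)

  expect_error(simulate_follower(st$trajectory), "annotated")
})

test_that("the fraction of smooth strokes matches the truncated-normal ceiling", {
  # 0.375 Hz: half-cycle 1.333 s sits inside the ceiling distribution
  st <- single_section_trial(0.375, 30, duration = 120)
  p <- follower_params(endpoint_noise_frac = 0, timing_noise_sd = 0,
                       correction_prob_per_excess_cm = 0)
  n_smooth <- 0; n_split <- 0
  for (s in 1:10) {
    subs <- attr(simulate_follower(st, p, seed = 300 + s), "submovements")
    n_smooth <- n_smooth + sum(subs$kind == "smooth")
    n_split <- n_split + sum(subs$kind == "chained") / 2  # k = 2 splits here
  }
  p_hat <- n_smooth / (n_smooth + n_split)
  p_want <- smooth_probability(1 / (2 * 0.375), p)
  se <- sqrt(p_want * (1 - p_want) / (n_smooth + n_split))
  expect_lt(abs(p_hat - p_want), 3 * se + 0.01)

  # closed form sanity: monotone, 1 below the support, 0 above it
  expect_equal(smooth_probability(0.5, p), 1)
  expect_equal(smooth_probability(2.5, p), 0)
  expect_true(all(diff(smooth_probability(seq(0.9, 1.8, 0.1), p)) <= 0))
})

test_that("chained submovements leave a recoverable jitter signature", {
  # force splitting: ceiling ~0.55 s against 2 s half-cycles, noise-free
  st <- single_section_trial(0.25, 30, duration = 40)
  p <- follower_params(smooth_limit_mean = 0.55, smooth_limit_sd = 0.05,
                       endpoint_noise_frac = 0, timing_noise_sd = 0,
                       correction_prob_per_excess_cm = 0)
  r <- simulate_follower(st, p, seed = 8)
  an <- analyze_response(r, st)
  segs <- an$segments
  expect_true(all(!segs$is_cc))
  expect_true(all(segs$n_jitter >= 1))

  # jitter spacing: k chained submovements per 2 s half-cycle give AZCs
  # every d/(2k) (submovement peaks and junctions), so the peak jitter
  # frequency recovers k/d within one 0.05 Hz histogram bin
  subs <- attr(r, "submovements")
  k <- sum(subs$kind == "chained") / nrow(segs)
  expect_true(k >= 4)  # 2 s / 0.55 s ceiling
  jp <- jitter_frequency(an$jitter_points)
  expect_equal(jp$peak_jitter_frequency, k / 2, tolerance = 0.051)
})

test_that("cohorts are reproducible and vary between participants", {
  coh1 <- simulate_cohort(n_participants = 3, design = builtin_design()[1:2],
                          master_seed = 11)
  coh2 <- simulate_cohort(n_participants = 3, design = builtin_design()[1:2],
                          master_seed = 11)
  expect_identical(coh1$participants[[2]]$responses[[1]]$position,
                   coh2$participants[[2]]$responses[[1]]$position)
  expect_equal(length(coh1$participants), 3)
  expect_equal(length(coh1$participants[[1]]$responses), 2)
  mus <- vapply(coh1$participants, function(p) p$params$smooth_limit_mean, 0)
  expect_gt(sd(mus), 0)
  expect_true(all(abs(mus - 1.3) <= 0.2 + 1e-9))
})

test_that("free dyads cover the frequency range and stay in the workspace", {
  dy1 <- simulate_free_dyad(duration = 120, seed = 21)
  dy2 <- simulate_free_dyad(duration = 120, seed = 21)
  expect_identical(dy1$leader$trajectory$position,
                   dy2$leader$trajectory$position)

  expect_true(all(abs(dy1$leader$trajectory$position) <= 45.5 / 2 + 1e-6))

  # a degenerate frequency range puts every segment in its own bin
  dy3 <- simulate_free_dyad(duration = 60, frequency_range = c(0.5, 0.5),
                            seed = 3)
  an3 <- analyze_response(dy3$follower, dy3$leader)
  tab3 <- bin_free_motion(an3$segments)
  expect_equal(sum(tab3$n_segments[abs(tab3$bin - 0.5) > 1e-9]), 0)
  expect_gt(tab3$n_segments[abs(tab3$bin - 0.5) < 1e-9], 0)

  # a wide range populates all six design bins over three minutes
  an1 <- analyze_response(dy1$follower, dy1$leader)
  tab1 <- bin_free_motion(an1$segments)
  expect_true(all(tab1$n_segments > 0))
})
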