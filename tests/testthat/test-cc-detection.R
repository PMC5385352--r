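test_that("half-cycle segmentation tiles the trial", {
  # 20 s of 0.5 Hz -> 20 windows
  st <- single_section_trial(0.5, 20, duration = 20)
  w <- segment_by_stimulus(st)
  expect_equal(nrow(w), 20)
  expect_equal(w$t_start[1], 0)
  expect_equal(max(w$t_end), 20)
  expect_true(all(abs(w$t_end[-nrow(w)] - w$t_start[-1]) < 1e-9))

  # trial 4 (0.25/0.875/0.75 Hz at 20 s each): 2 f t per section
  w4 <- segment_by_stimulus(get_design_trials()[[4]])
  expect_equal(nrow(w4), 10 + 35 + 30)
  expect_equal(as.vector(table(w4$section)), c(10, 35, 30))

  # blend windows belong to the following half-cycle
  st4 <- get_design_trials()[[4]]
  joins <- st4$sections$t_start[-1]
  for (j in joins) {
    expect_true(any(abs(w4$t_start - (j - st4$blend_half_window)) < 1e-9))
    expect_false(any(abs(w4$t_start - j) < 1e-9))
  }

  flat <- new_trajectory(rep(0, 500), rep(0, 500), rep(0, 500), 100)
  expect_error(segment_by_stimulus(flat), "turning points")
})

test_that("AZC matching is optimal and isolates jitter points", {
  # identical lists: no jitter
  azc <- c(0.5, 1.5, 2.5)
  m <- match_azc(azc, azc)
  expect_length(m$jitter_points, 0)
  expect_equal(nrow(m$matched), 3)

  # one extra response AZC far from any stimulus AZC
  m2 <- match_azc(c(0.5, 1.0, 1.5), c(0.5, 1.5))
  expect_equal(m2$jitter_points, 1.0)

  # far-only response: everything is jitter
  m3 <- match_azc(c(5, 6), c(0.5, 1.5))
  expect_equal(m3$jitter_points, c(5, 6))

  # randomized small sets: equals exhaustive optimal assignment
  for (s in 1:25) {
    set.seed(200 + s)
    r <- sort(runif(sample(1:5, 1), 0, 3))
    st <- sort(runif(sample(1:5, 1), 0, 3))
    got <- match_azc(r, st, tolerance = 0.2)
    want <- oracle_match(r, st, tol = 0.2)
    expect_equal(nrow(got$matched), want$n, info = paste("seed", s))
    if (want$n > 0) {
      cost <- sum(abs(got$matched$response_time - got$matched$stimulus_time))
      expect_equal(cost, want$cost, tolerance = 1e-9, info = paste("seed", s))
    }
  }
})

test_that("jitter frequency is half the reciprocal of jitter spacing", {
  jp <- jitter_frequency(c(1, 2, 3))
  expect_equal(jp$interval_frequencies, c(0.5, 0.5))
  expect_equal(jp$peak_jitter_frequency, 0.5)

  jp2 <- jitter_frequency(c(0, 0.8, 1.6, 3.6))
  expect_equal(jp2$interval_frequencies, c(0.625, 0.625, 0.25))
  expect_equal(jp2$peak_jitter_frequency, 0.625)

  jp3 <- jitter_frequency(2.2)
  expect_length(jp3$interval_frequencies, 0)
  expect_true(is.na(jp3$peak_jitter_frequency))

  # injected jitter trains at known spacing recover 0.5/spacing within a bin
  for (spacing in c(0.4, 0.8, 1.25)) {
    times <- seq(0, 10, by = spacing)
    jp4 <- jitter_frequency(times)
    expect_equal(jp4$peak_jitter_frequency, 0.5 / spacing, tolerance = 0.05)
  }
})

test_that("segment metrics recover shifts and scalings in closed form", {
  st <- single_section_trial(0.5, 25, duration = 20)
  stim <- st$trajectory
  win <- list(t_start = 8, t_end = 10)

  # identical: all-zero metrics
  m0 <- segment_metrics(stim, stim, win)
  expect_equal(unname(m0), c(0, 0, 0), tolerance = 1e-9)

  # 0.1 s shift: dT = 0.1, dV ~ 0
  tt <- traj_time(stim)
  shifted <- new_trajectory(
    approx(tt, stim$position, tt - 0.1, rule = 2)$y,
    approx(tt, stim$velocity, tt - 0.1, rule = 2)$y,
    approx(tt, stim$acceleration, tt - 0.1, rule = 2)$y,
    stim$sample_rate
  )
  m1 <- segment_metrics(shifted, stim, win)
  expect_equal(m1[["dT"]], 0.1, tolerance = 0.01)
  expect_lt(m1[["dV"]], 0.01)

  # half-amplitude response: dV = RMS(0.5 v - v)/RMS(v) = 0.5
  half <- new_trajectory(stim$position * 0.5, stim$velocity * 0.5,
                         stim$acceleration * 0.5, stim$sample_rate)
  m2 <- segment_metrics(half, stim, win)
  expect_equal(m2[["dV"]], 0.5, tolerance = 1e-6)

  flat <- new_trajectory(rep(0, length(stim)), rep(0, length(stim)),
                         rep(0, length(stim)), stim$sample_rate)
  expect_error(segment_metrics(stim, flat, win), "zero-variance")
})

test_that("CC classification flips exactly at the dV and dT thresholds", {
  # dV threshold: scaled responses straddling dV = 0.95 by 1%
  st <- single_section_trial(0.5, 25, duration = 20)
  scale_for <- function(dv) 1 - dv
  for (case in list(c(0.95 * 0.99, TRUE), c(0.95 * 1.01, FALSE))) {
    a <- scale_for(case[1])
    resp <- new_trajectory(st$trajectory$position * a,
                           st$trajectory$velocity * a,
                           st$trajectory$acceleration * a,
                           st$trajectory$sample_rate)
    an <- analyze_response(resp, st)
    mid <- an$segments[8, ]  # away from edges
    expect_equal(mid$dV, case[1], tolerance = 1e-6)
    expect_equal(mid$is_cc, as.logical(case[2]))
  }

  # dT threshold at 1 kHz so 0.15 s +- 1% is on the sample grid
  st2 <- single_section_trial(0.5, 25, duration = 10, sample_rate = 1000)
  stim2 <- st2$trajectory
  tt2 <- traj_time(stim2)
  for (case in list(c(0.15 * 0.99, TRUE), c(0.15 * 1.01, FALSE))) {
    sh <- case[1]
    resp <- new_trajectory(
      approx(tt2, stim2$position, tt2 - sh, rule = 2)$y,
      approx(tt2, stim2$velocity, tt2 - sh, rule = 2)$y,
      approx(tt2, stim2$acceleration, tt2 - sh, rule = 2)$y,
      stim2$sample_rate
    )
    m <- segment_metrics(resp, stim2, list(t_start = 4, t_end = 5))
    seg <- list(response_azc_count = 1L, n_jitter = 0L,
                dV = m[["dV"]], dT = m[["dT"]])
    expect_equal(classify_cc(seg), as.logical(case[2]))
  }

  # an unmatched (jitter) AZC always kills CC
  expect_false(classify_cc(list(response_azc_count = 3L, n_jitter = 2L,
                                dV = 0.1, dT = 0.01)))
})

test_that("tracking the stimulus with itself yields 100% CC and no jitter", {
  for (st in get_design_trials()) {
    an <- analyze_response(st$trajectory, st)
    s <- summarize_trial(an)
    expect_equal(s$percent_cc, 100)
    expect_length(an$jitter_points, 0)
    expect_equal(s$dV_mean, 0, tolerance = 1e-9)
    expect_equal(s$dT_mean, 0, tolerance = 1e-9)
  }
})

test_that("injected corrective submovements destroy CC in their segment", {
  st <- single_section_trial(0.5, 25, duration = 20)
  stim <- st$trajectory
  tt <- traj_time(stim)
  # an out-and-back corrective wiggle inside half-cycle 8 ([7, 8) s)
  mjp <- function(tau) ifelse(tau <= 0, 0, ifelse(tau >= 1, 1,
                                                  10 * tau^3 - 15 * tau^4 + 6 * tau^5))
  bump <- 1.5 * (mjp((tt - 7.2) / 0.2) - mjp((tt - 7.4) / 0.2))
  dbump <- c(0, diff(bump)) * stim$sample_rate
  resp <- new_trajectory(stim$position + bump, stim$velocity + dbump,
                         c(0, diff(dbump)) * stim$sample_rate,
                         stim$sample_rate)
  an <- analyze_response(resp, st)
  seg <- an$segments
  hit <- seg$t_start <= 7.2 & seg$t_end > 7.4
  expect_true(all(!seg$is_cc[hit]))
  expect_gt(sum(seg$n_jitter[hit]), 0)
  # far-away segments unaffected
  expect_true(all(seg$is_cc[seg$t_end < 6 | seg$t_start > 9]))
})

test_that("cc_vector and trial summaries are consistent with the windows", {
  st <- single_section_trial(0.5, 25, duration = 20)
  an <- analyze_response(st$trajectory, st)
  v <- cc_vector(an)
  expect_equal(length(v), 2000)
  expect_true(all(v == 1))

  # flip every other window off and check the block pattern and percent
  an2 <- an
  an2$segments$is_cc[seq(2, nrow(an2$segments), by = 2)] <- FALSE
  v2 <- cc_vector(an2)
  expect_equal(mean(v2), 0.5, tolerance = 1e-9)
  tt <- (seq_along(v2) - 1) / 100
  in_odd <- (floor(tt) %% 2) == 0
  expect_true(all(v2[in_odd] == 1))
  expect_true(all(v2[!in_odd] == 0))
  expect_equal(summarize_trial(an2)$percent_cc, 50)

  an3 <- an
  an3$segments$is_cc <- FALSE
  expect_true(all(cc_vector(an3) == 0))
  expect_equal(summarize_trial(an3)$percent_cc, 0)
})
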