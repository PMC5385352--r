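#' Generative parameters of the simulated intermittent-control follower
#'
#' The follower tracks a rhythmic stimulus with a sensorimotor delay and
#' composes its motion from minimum-jerk submovements. A half-cycle whose
#' duration exceeds the follower's stochastic smooth-movement ceiling
#' `T_lim ~ Normal(smooth_limit_mean, smooth_limit_sd)` (truncated to
#' +-3 SD and positive) is split into chained submovements, producing
#' jitter. Endpoints and onsets carry noise; brief corrective submovements
#' are injected at a rate proportional to the momentary tracking error.
#'
#' @param delay Sensorimotor delay, s.
#' @param smooth_limit_mean,smooth_limit_sd Mean/SD of the smooth-movement
#'   duration ceiling, s. The mean must exceed 3 SD so the ceiling stays
#'   effectively positive.
#' @param endpoint_noise_frac Endpoint noise SD as a fraction of the
#'   half-cycle extent.
#' @param timing_noise_sd Onset timing noise SD, s.
#' @param correction_prob_per_excess_cm Corrective-submovement intensity per
#'   cm of momentary error (per second of exposure).
#' @param correction_duration Duration of corrective submovements, s.
#' @return List of class `follower_params`.
#' @export
follower_params <- function(delay = 0.15, smooth_limit_mean = 1.3,
                            smooth_limit_sd = 0.15,
                            endpoint_noise_frac = 0.05,
                            timing_noise_sd = 0.03,
                            correction_prob_per_excess_cm = 0.1,
                            correction_duration = 0.15) {
  if (delay <= 0 || delay >= 0.5) stop("delay must be in (0, 0.5) s")
  if (smooth_limit_mean <= 0) stop("smooth_limit_mean must be positive")
  if (smooth_limit_sd <= 0) stop("smooth_limit_sd must be positive")
  if (is.finite(smooth_limit_mean) &&
      smooth_limit_mean <= 3 * smooth_limit_sd) {
    stop("smooth_limit_mean must exceed 3 * smooth_limit_sd")
  }
  if (endpoint_noise_frac < 0 || timing_noise_sd < 0 ||
      correction_prob_per_excess_cm < 0) {
    stop("noise parameters must be non-negative")
  }
  if (correction_duration <= 0) stop("correction_duration must be positive")
  structure(
    list(delay = delay, smooth_limit_mean = smooth_limit_mean,
         smooth_limit_sd = smooth_limit_sd,
         endpoint_noise_frac = endpoint_noise_frac,
         timing_noise_sd = timing_noise_sd,
         correction_prob_per_excess_cm = correction_prob_per_excess_cm,
         correction_duration = correction_duration),
    class = "follower_params"
  )
}

# truncated-normal draw on [max(0, mu - 3 sigma), mu + 3 sigma]
rtnorm3 <- function(n, mu, sigma) {
  if (!is.finite(mu)) return(rep(mu, n))
  lo <- max(0, mu - 3 * sigma)
  hi <- mu + 3 * sigma
  u <- stats::runif(n, stats::pnorm(lo, mu, sigma),
                    stats::pnorm(hi, mu, sigma))
  stats::qnorm(u, mu, sigma)
}

#' Probability that a half-cycle of duration d can be tracked smoothly
#'
#' Closed form for `P(T_lim >= d)` under the follower's truncated-normal
#' smooth-duration ceiling; the quantity the simulator's single- vs
#' split-submovement decision realizes.
#'
#' @param d Half-cycle duration(s), s.
#' @param params A [follower_params()].
#' @return Probability vector.
#' @export
smooth_probability <- function(d, params = follower_params()) {
  mu <- params$smooth_limit_mean
  sigma <- params$smooth_limit_sd
  if (!is.finite(mu)) return(rep(1, length(d)))
  lo <- max(0, mu - 3 * sigma)
  hi <- mu + 3 * sigma
  p_lo <- stats::pnorm(lo, mu, sigma)
  p_hi <- stats::pnorm(hi, mu, sigma)
  p <- (p_hi - stats::pnorm(pmax(pmin(d, hi), lo), mu, sigma)) / (p_hi - p_lo)
  p[d <= lo] <- 1
  p[d >= hi] <- 0
  p
}

# minimum-jerk position/velocity/acceleration shape on tau in [0, 1]
mj_frac <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_vfrac <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4
mj_afrac <- function(tau) 60 * tau - 180 * tau^2 + 120 * tau^3

#' Minimum-jerk point-to-point trajectory
#'
#' The fifth-order polynomial `x(tau) = d (10 tau^3 - 15 tau^4 + 6 tau^5)`,
#' `tau = t/T`: starts and ends at rest, has a single bell-shaped velocity
#' peak of `1.875 d / T` at mid-movement, and exactly one acceleration zero
#' crossing.
#'
#' @param d Displacement, cm.
#' @param T_dur Movement duration, s.
#' @param sample_rate Sampling rate, Hz.
#' @return A [new_trajectory()] over `[0, T_dur]`.
#' @export
min_jerk <- function(d, T_dur, sample_rate = 100) {
  if (T_dur <= 0) stop("duration must be positive")
  t <- seq(0, T_dur, by = 1 / sample_rate)
  if (t[length(t)] < T_dur - 1e-9) t <- c(t, T_dur)
  tau <- t / T_dur
  new_trajectory(
    position = d * mj_frac(tau),
    velocity = d / T_dur * mj_vfrac(tau),
    acceleration = d / T_dur^2 * mj_afrac(tau),
    sample_rate = sample_rate
  )
}

# superpose a set of min-jerk submovements on a time grid
superpose_submovements <- function(subs, t_grid, x0) {
  n <- length(t_grid)
  x <- rep(x0, n)
  v <- numeric(n)
  a <- numeric(n)
  for (i in seq_len(nrow(subs))) {
    on <- subs$onset[i]
    du <- subs$duration[i]
    dp <- subs$displacement[i]
    tau <- (t_grid - on) / du
    after <- tau >= 1
    inside <- tau > 0 & tau < 1
    x[after] <- x[after] + dp
    x[inside] <- x[inside] + dp * mj_frac(tau[inside])
    v[inside] <- v[inside] + dp / du * mj_vfrac(tau[inside])
    a[inside] <- a[inside] + dp / du^2 * mj_afrac(tau[inside])
  }
  list(x = x, v = v, a = a)
}

#' Simulate an intermittent-control follower tracking a stimulus
#'
#' The displayed stimulus is decomposed into strokes — stretches between
#' consecutive stimulus turning points (velocity zero crossings of the
#' blended trajectory; within a section these are exactly the design
#' half-cycles). For each stroke (duration `d`, extent `D`, viewed with the
#' follower's sensorimotor delay) a smooth-duration ceiling `T_lim` is
#' drawn. If `d <= T_lim` the stroke is reproduced by one minimum-jerk
#' submovement; otherwise it is split into `k = ceiling(d / T_lim)` chained
#' submovements through noisy via-points on the stimulus path, adding
#' `k - 1` jitter AZCs. Submovement onsets are jittered, endpoints perturbed
#' by `Normal(0, endpoint_noise_frac * D)`, and brief corrective
#' submovements arrive as a Poisson process whose intensity is
#' `correction_prob_per_excess_cm` times the momentary planned tracking
#' error (cm). Overlapping submovement velocities superpose. The follower
#' plans against the predictable rhythm (submovements are aligned to
#' stimulus turning points), so the generator is deterministic given the
#' RNG state.
#'
#' @param stim_trial An annotated `stimulus_trial` (from [build_trial()] or
#'   [simulate_free_dyad()]); an unannotated input is an error.
#' @param params A [follower_params()].
#' @param seed Optional integer seed (otherwise the ambient RNG state is
#'   used, as in [simulate_cohort()]).
#' @return A [new_trajectory()] with the follower's response, attribute
#'   `submovements` (data frame of onset/duration/displacement/kind).
#' @export
simulate_follower <- function(stim_trial, params = follower_params(),
                              seed = NULL) {
  if (!inherits(stim_trial, "stimulus_trial") ||
      is.null(stim_trial$half_cycles)) {
    stop("stimulus must be an annotated stimulus_trial")
  }
  if (!is.null(seed)) set.seed(seed)
  stim <- stim_trial$trajectory
  rate <- stim$sample_rate
  tt <- traj_time(stim)
  p <- params

  # strokes of the displayed trajectory: turning point to turning point,
  # further split at velocity local minima (even-indexed AZCs) so that every
  # stroke carries a single speed peak — the unit a smooth submovement can
  # mirror (two-humped stretches arise where a join blend extends a
  # half-cycle)
  tp <- find_turning_points(stim)
  tp <- c(tt[1], tp, tt[length(tt)])
  tp <- tp[c(TRUE, diff(tp) > 0.04)]
  azc_all <- find_azc(stim)
  splits <- unlist(lapply(seq_len(length(tp) - 1), function(h) {
    a_in <- azc_all[azc_all > tp[h] + 0.02 & azc_all < tp[h + 1] - 0.02]
    if (length(a_in) >= 2) a_in[seq(2, length(a_in), by = 2)] else numeric(0)
  }))
  tp <- sort(c(tp, splits))
  tp <- tp[c(TRUE, diff(tp) > 0.04)]
  x_tp <- traj_interp(stim, tp, "position")
  n_str <- length(tp) - 1
  # pieces cut at a velocity minimum (not at rest) get overlapping
  # submovements so the summed velocity stays up through the junction
  is_split_pt <- tp %in% splits
  overlap_frac <- 0.25

  # The smooth-or-split decision is governed by the rhythm: a stroke that
  # stands for a design half-cycle is planned over that half-cycle's full
  # period even when a join blend trims its displayed extent. Brief
  # transit swoops (no majority overlap with any half-cycle) keep their
  # own duration.
  hc_tab <- stim_trial$half_cycles
  decision_duration <- function(t0, t1) {
    if (is.null(hc_tab)) return(t1 - t0)
    ov <- pmax(0, pmin(t1, hc_tab$t_end) - pmax(t0, hc_tab$t_start))
    best <- which.max(ov)
    hc_dur <- hc_tab$t_end[best] - hc_tab$t_start[best]
    if (ov[best] >= 0.5 * hc_dur) hc_dur else t1 - t0
  }

  subs <- vector("list", n_str * 2)
  n_subs <- 0
  push <- function(onset, duration, displacement, kind) {
    n_subs <<- n_subs + 1
    subs[[n_subs]] <<- data.frame(onset = onset, duration = duration,
                                  displacement = displacement, kind = kind)
  }

  start_pos <- stim$position[1]
  cur_pos <- start_pos

  for (h in seq_len(n_str)) {
    d <- tp[h + 1] - tp[h]
    x0 <- x_tp[h]
    x1 <- x_tp[h + 1]
    D <- abs(x1 - x0)
    if (D < 1e-9) next  # stationary stretch: nothing to mirror

    T_lim <- rtnorm3(1, p$smooth_limit_mean, p$smooth_limit_sd)
    d_dec <- decision_duration(tp[h], tp[h + 1])
    k <- if (d_dec <= T_lim) 1L else max(2L, as.integer(ceiling(d / T_lim)))
    dsub <- d / k
    tau_ends <- seq_len(k) * dsub
    # via-points on the half-sine stroke path, perturbed
    targets <- x0 + (x1 - x0) * (1 - cos(pi * tau_ends / d)) / 2 +
      stats::rnorm(k, 0, p$endpoint_noise_frac * D)
    entry_pos <- cur_pos
    starts <- c(entry_pos, targets[-k])
    # stretch across non-rest junctions at either end of the piece
    ext_lo <- if (is_split_pt[h]) overlap_frac * d else 0
    ext_hi <- if (is_split_pt[h + 1]) overlap_frac * d else 0
    for (i in seq_len(k)) {
      e_lo <- if (i == 1) ext_lo else 0
      e_hi <- if (i == k) ext_hi else 0
      onset <- tp[h] + p$delay + (i - 1) * dsub - e_lo +
        stats::rnorm(1, 0, p$timing_noise_sd)
      push(onset, dsub + e_lo + e_hi, targets[i] - cur_pos,
           if (k == 1) "smooth" else "chained")
      cur_pos <- targets[i]
    }

    # Corrective submovements: a Poisson process whose intensity is
    # c x |momentary realized error| integrated over the stroke. The error
    # the follower reacts to is the miss at its own submovement endpoints
    # (the realized endpoint noise, interpolated between checkpoints) - a
    # planned mid-flight via stop is not an error.
    if (p$correction_prob_per_excess_cm > 0) {
      path_vals <- x0 + (x1 - x0) * (1 - cos(pi * tau_ends / d)) / 2
      tau_nodes <- c(0, tau_ends)
      err_nodes <- c(entry_pos - x0, targets - path_vals)
      mean_err <- mean(abs(stats::approx(
        tau_nodes, err_nodes,
        xout = seq(0, d, length.out = 21), rule = 2
      )$y))
      lambda <- p$correction_prob_per_excess_cm * mean_err * d
      n_corr <- stats::rpois(1, lambda)
      if (n_corr > 0) {
        tau_c <- sort(stats::runif(n_corr, 0.15 * d, 0.95 * d))
        corr_accum <- 0  # earlier corrections already shifted the plan
        for (j in seq_len(n_corr)) {
          e_c <- stats::approx(tau_nodes, err_nodes, xout = tau_c[j],
                               rule = 2)$y + corr_accum
          if (abs(e_c) < 1e-9) next
          onset <- tp[h] + p$delay + tau_c[j] +
            stats::rnorm(1, 0, p$timing_noise_sd)
          push(onset, min(p$correction_duration, d / 2), -e_c, "correction")
          corr_accum <- corr_accum - e_c
          cur_pos <- cur_pos - e_c
        }
      }
    }
  }

  subs <- do.call(rbind, subs[seq_len(n_subs)])
  subs <- subs[order(subs$onset), ]
  t_grid <- seq(0, tt[length(tt)] + p$delay + 0.5, by = 1 / rate)
  ch <- superpose_submovements(subs, t_grid, start_pos)
  traj <- new_trajectory(ch$x, ch$v, ch$a, rate)
  attr(traj, "submovements") <- subs
  traj
}

#' Simulate a cohort of followers over a stimulus design
#'
#' Per-participant parameters are drawn around the defaults (smooth-limit
#' mean +- 0.1 s, delay +- 0.03 s, both truncated at 2 SD) from
#' `master_seed`; every participant then responds once to every trial.
#' Fully deterministic given `master_seed`.
#'
#' @param n_participants Cohort size.
#' @param design List of [trial_spec()]; default [builtin_design()].
#' @param base_params Central [follower_params()].
#' @param master_seed Integer seed for all randomness.
#' @param sample_rate Hz.
#' @return List of class `cohort`: `stim_trials`, `participants` (each with
#'   `params` and `responses`), `master_seed`.
#' @export
simulate_cohort <- function(n_participants = 18, design = builtin_design(),
                            base_params = follower_params(),
                            master_seed = 1, sample_rate = 100) {
  set.seed(master_seed)
  stim_trials <- lapply(design, function(spec) {
    suppressWarnings(build_trial(spec, sample_rate = sample_rate))
  })
  participants <- lapply(seq_len(n_participants), function(pp) {
    mu_p <- base_params$smooth_limit_mean +
      max(-0.2, min(0.2, stats::rnorm(1, 0, 0.1)))
    delay_p <- base_params$delay +
      max(-0.06, min(0.06, stats::rnorm(1, 0, 0.03)))
    params <- follower_params(
      delay = delay_p,
      smooth_limit_mean = mu_p,
      smooth_limit_sd = base_params$smooth_limit_sd,
      endpoint_noise_frac = base_params$endpoint_noise_frac,
      timing_noise_sd = base_params$timing_noise_sd,
      correction_prob_per_excess_cm = base_params$correction_prob_per_excess_cm,
      correction_duration = base_params$correction_duration
    )
    responses <- lapply(stim_trials, simulate_follower, params = params)
    list(id = pp, params = params, responses = responses)
  })
  structure(
    list(stim_trials = stim_trials, participants = participants,
         master_seed = master_seed, sample_rate = sample_rate),
    class = "cohort"
  )
}

#' Run the CC pipeline over a simulated (or loaded) cohort
#'
#' Registers every response, detects AZCs/jitter/CC, and stacks the
#' per-segment classifications with participant and trial labels.
#'
#' @param cohort A `cohort` from [simulate_cohort()] (or a compatible list).
#' @param ... Passed to [analyze_response()].
#' @return List of class `cohort_analysis`: `analyses[[participant]][[trial]]`
#'   (each a `cc_analysis`), `segments` (combined data frame), and
#'   `stim_trials`.
#' @export
analyze_cohort <- function(cohort, ...) {
  stim_trials <- cohort$stim_trials
  analyses <- lapply(cohort$participants, function(pt) {
    lapply(seq_along(stim_trials), function(t) {
      analyze_response(pt$responses[[t]], stim_trials[[t]], ...)
    })
  })
  segments <- do.call(rbind, lapply(seq_along(analyses), function(pp) {
    do.call(rbind, lapply(seq_along(analyses[[pp]]), function(t) {
      segs <- analyses[[pp]][[t]]$segments
      cbind(data.frame(participant = pp), segs, row.names = NULL)
    }))
  }))
  structure(
    list(analyses = analyses, segments = segments,
         stim_trials = stim_trials),
    class = "cohort_analysis"
  )
}

#' Simulate a free-motion dyad (leader plus follower)
#'
#' The leader improvises a 1-D rhythmic motion as a chain of half-sine
#' half-cycles whose frequency and peak velocity are drawn uniformly per
#' half-cycle (direction reflects off the workspace edges); the follower is
#' a [simulate_follower()] response to it. Stands in for two-player mirror
#' games where motion frequency takes arbitrary values.
#'
#' @param duration Game duration, s.
#' @param frequency_range,velocity_range Uniform ranges for per-half-cycle
#'   frequency (Hz) and peak velocity (cm/s).
#' @param params Follower parameters.
#' @param seed Integer seed.
#' @param sample_rate Hz.
#' @param workspace_width Track width, cm.
#' @return List of class `dyad`: `leader` (an annotated `stimulus_trial`),
#'   `follower` (trajectory), `params`, `seed`.
#' @export
simulate_free_dyad <- function(duration = 180,
                               frequency_range = c(0.1, 1.2),
                               velocity_range = c(10, 50),
                               params = follower_params(), seed = 1,
                               sample_rate = 100, workspace_width = 45.5) {
  set.seed(seed)
  half <- workspace_width / 2
  t_cur <- 0
  x_cur <- 0
  rows <- list()
  dir <- 1
  while (t_cur < duration) {
    f <- stats::runif(1, frequency_range[1], frequency_range[2])
    v <- stats::runif(1, velocity_range[1], velocity_range[2])
    D <- v / (pi * f)
    d <- 1 / (2 * f)
    # reflect at the workspace edge; clamp extent if it cannot fit either way
    if (abs(x_cur + dir * D) > half) dir <- -dir
    if (abs(x_cur + dir * D) > half) {
      D <- half - dir * x_cur
      v <- D * pi * f
    }
    rows[[length(rows) + 1]] <- data.frame(
      trial = 1L, section = length(rows) + 1L, hc = 1L, frequency = f,
      peak_velocity = v, t_start = t_cur, t_end = t_cur + d,
      x_start = x_cur, x_end = x_cur + dir * D
    )
    x_cur <- x_cur + dir * D
    t_cur <- t_cur + d
    dir <- -dir
  }
  hc <- do.call(rbind, rows)

  t_grid <- seq(0, max(hc$t_end), by = 1 / sample_rate)
  seg <- findInterval(t_grid, hc$t_start)
  seg[seg < 1] <- 1
  tau <- (t_grid - hc$t_start[seg]) / (hc$t_end[seg] - hc$t_start[seg])
  tau <- pmin(pmax(tau, 0), 1)
  delta <- hc$x_end[seg] - hc$x_start[seg]
  dhc <- hc$t_end[seg] - hc$t_start[seg]
  leader_traj <- new_trajectory(
    position = hc$x_start[seg] + delta * (1 - cos(pi * tau)) / 2,
    velocity = delta * pi / (2 * dhc) * sin(pi * tau),
    acceleration = delta * (pi / dhc)^2 / 2 * cos(pi * tau),
    sample_rate = sample_rate
  )
  sections <- data.frame(
    trial = 1L, section = hc$section, frequency = hc$frequency,
    peak_velocity = hc$peak_velocity, t_start = hc$t_start,
    t_end = hc$t_end, duration = hc$t_end - hc$t_start,
    extent_cm = abs(hc$x_end - hc$x_start), direction = sign(hc$x_end - hc$x_start)
  )
  leader <- structure(
    list(trajectory = leader_traj, sections = sections, half_cycles = hc,
         trial_id = 1L, blend_half_window = 0),
    class = "stimulus_trial"
  )
  follower <- simulate_follower(leader, params)
  structure(list(leader = leader, follower = follower, params = params,
                 seed = seed),
            class = "dyad")
}
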