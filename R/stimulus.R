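#' Half-sine stimulus sections and trial programs
#'
#' The tracking stimulus is a 1-D rhythmic motion built from sections, each a
#' train of half-sine speed pulses with a fixed oscillation frequency `f`
#' (Hz) and peak speed `v_peak` (cm/s). Position within a section is a
#' sinusoid of extent `D = v_peak / (pi * f)` cm: every half-cycle lasts
#' `1/(2f)` s, starts and ends at rest, and its speed profile is a half sine
#' peaking at `v_peak`.
#'
#' @param frequency Oscillation frequency in Hz (one full left-right-left
#'   cycle per `1/frequency` seconds).
#' @param peak_velocity Maximal speed in cm/s.
#' @param duration Section duration in seconds (may be `NA` until
#'   [round_section_durations()] assigns it).
#' @param start_time Section onset in seconds from trial start (filled in by
#'   [round_section_durations()] / [build_trial()]).
#' @return An object of class `stimulus_section`.
#' @export
stimulus_section <- function(frequency, peak_velocity, duration = NA_real_,
                             start_time = NA_real_) {
  if (!is.numeric(frequency) || frequency <= 0) {
    stop("frequency must be positive")
  }
  if (!is.numeric(peak_velocity) || peak_velocity <= 0) {
    stop("peak_velocity must be positive")
  }
  if (!is.na(duration) && duration <= 0) stop("duration must be positive")
  structure(
    list(
      frequency = frequency,
      peak_velocity = peak_velocity,
      duration = duration,
      start_time = start_time
    ),
    class = "stimulus_section"
  )
}

#' Movement extent of a half-sine section
#'
#' Distance between consecutive turning points, `D = v_peak / (pi * f)`.
#'
#' @param section A [stimulus_section()].
#' @return Extent in cm.
#' @export
section_extent <- function(section) {
  section$peak_velocity / (pi * section$frequency)
}

#' One trial program: an ordered list of stimulus sections
#'
#' @param trial_id Integer trial identifier.
#' @param sections List of [stimulus_section()] objects in presentation order.
#' @param total_duration Trial length in seconds.
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(trial_id, sections, total_duration = 60) {
  stopifnot(length(sections) >= 1,
            all(vapply(sections, inherits, TRUE, "stimulus_section")))
  if (total_duration <= 0) stop("total_duration must be positive")
  structure(
    list(
      trial_id = as.integer(trial_id),
      sections = sections,
      total_duration = total_duration
    ),
    class = "trial_spec"
  )
}

#' The built-in 11-trial stimulus design
#'
#' Eleven one-minute trials; nine trials have three <frequency, peak
#' velocity> sections and trials 1 and 6 have two. Frequencies are drawn
#' from {0.25, 0.375, 0.5, 0.625, 0.75, 0.875} Hz and peak velocities from
#' {20.0, 26.7, 33.3, 40.0, 46.6} cm/s, each value occurring approximately
#' equally often across the 31 sections.
#'
#' @return List of 11 [trial_spec()] objects (section durations unassigned;
#'   see [round_section_durations()]).
#' @export
builtin_design <- function() {
  tab <- list(
    list(c(0.25, 40.0), c(0.5, 26.7)),
    list(c(0.5, 20.0), c(0.25, 40.0), c(0.875, 26.7)),
    list(c(0.75, 46.6), c(0.25, 33.3), c(0.25, 46.6)),
    list(c(0.25, 26.7), c(0.875, 40.0), c(0.75, 33.3)),
    list(c(0.625, 46.6), c(0.75, 26.7), c(0.375, 40.0)),
    list(c(0.375, 20.0), c(0.625, 40.0)),
    list(c(0.375, 33.3), c(0.875, 20.0), c(0.375, 46.6)),
    list(c(0.875, 46.6), c(0.75, 20.0), c(0.625, 26.7)),
    list(c(0.5, 33.3), c(0.625, 33.3), c(0.25, 20.0)),
    list(c(0.375, 26.7), c(0.875, 33.3), c(0.5, 46.6)),
    list(c(0.75, 40.0), c(0.5, 33.3), c(0.625, 20.0))
  )
  lapply(seq_along(tab), function(i) {
    trial_spec(i, lapply(tab[[i]], function(fv) {
      stimulus_section(frequency = fv[1], peak_velocity = fv[2])
    }))
  })
}

#' Tabulate the sections of a design
#'
#' @param design List of [trial_spec()] objects, e.g. [builtin_design()].
#' @return Data frame with one row per section: `trial`, `section`,
#'   `frequency`, `peak_velocity`, `duration` (NA until assigned).
#' @export
design_sections <- function(design) {
  do.call(rbind, lapply(design, function(spec) {
    data.frame(
      trial = spec$trial_id,
      section = seq_along(spec$sections),
      frequency = vapply(spec$sections, `[[`, 0, "frequency"),
      peak_velocity = vapply(spec$sections, `[[`, 0, "peak_velocity"),
      duration = vapply(spec$sections, `[[`, 0, "duration")
    )
  }))
}

is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol

#' Assign section durations holding whole numbers of half-cycles
#'
#' Nominal durations split the trial evenly (`total / n_sections`); they are
#' adjusted minimally (within +-2 s) so that every section contains a whole
#' number of half-cycles (`2 * f * duration` integer) and the durations still
#' sum to the trial length. For three-section trials all six design
#' frequencies already satisfy this at the nominal 20 s. Ties are broken
#' toward the shorter first section, so the two-section trial at
#' (0.375, 0.625) Hz splits 28 s / 32 s.
#'
#' @param spec A [trial_spec()].
#' @param slack Maximal deviation from nominal per section, seconds.
#' @return The spec with `duration` and `start_time` filled in.
#' @export
round_section_durations <- function(spec, slack = 2) {
  stopifnot(inherits(spec, "trial_spec"))
  total <- spec$total_duration
  f <- vapply(spec$sections, `[[`, 0, "frequency")
  n <- length(f)
  nominal <- total / n

  candidates_for <- function(fk) {
    m <- seq(ceiling(2 * fk * (nominal - slack)),
             floor(2 * fk * (nominal + slack)))
    m <- m[m >= 1]
    m / (2 * fk)
  }

  durations <- NULL
  if (all(is_whole(2 * f * nominal))) {
    durations <- rep(nominal, n)
  } else if (n == 2) {
    d1 <- candidates_for(f[1])
    d2 <- total - d1
    ok <- is_whole(2 * f[2] * d2) & d2 > 0
    if (any(ok)) {
      d1 <- d1[ok]
      dev <- abs(d1 - nominal)
      best <- order(dev, d1)[1]  # minimal deviation; tie -> shorter first
      durations <- c(d1[best], total - d1[best])
    }
  } else if (n == 3) {
    d1s <- candidates_for(f[1])
    d2s <- candidates_for(f[2])
    grid <- expand.grid(d1 = d1s, d2 = d2s)
    grid$d3 <- total - grid$d1 - grid$d2
    ok <- is_whole(2 * f[3] * grid$d3) & abs(grid$d3 - nominal) <= slack &
      grid$d3 > 0
    if (any(ok)) {
      grid <- grid[ok, , drop = FALSE]
      dev <- abs(grid$d1 - nominal) + abs(grid$d2 - nominal) +
        abs(grid$d3 - nominal)
      best <- order(dev, grid$d1, grid$d2)[1]
      durations <- as.numeric(grid[best, c("d1", "d2", "d3")])
    }
  } else {
    stop("round_section_durations supports 2- or 3-section trials")
  }

  if (is.null(durations)) {
    warning(sprintf(
      "trial %d: no whole-half-cycle partition within +-%g s of nominal; %s",
      spec$trial_id, slack,
      "keeping nominal durations (sections truncated mid-cycle and blended)"
    ))
    durations <- rep(nominal, n)
  }

  starts <- cumsum(c(0, durations[-n]))
  spec$sections <- lapply(seq_len(n), function(k) {
    s <- spec$sections[[k]]
    s$duration <- durations[k]
    s$start_time <- starts[k]
    s
  })
  spec
}

#' Build the trajectory of a single half-sine section
#'
#' Position is `x(t) = start_position + dir * (D/2) * (1 - cos(2 pi f t))`:
#' the motion starts at rest at `start_position`, oscillates with extent
#' `D = v_peak/(pi f)`, and every turning point has exactly zero velocity.
#'
#' @param section A [stimulus_section()] with an assigned duration covering a
#'   whole number of half-cycles.
#' @param start_position Position of the initial turning point, cm.
#' @param start_direction +1 (first movement rightward) or -1.
#' @param sample_rate Sampling rate in Hz (>= 50).
#' @return A [new_trajectory()] object.
#' @export
build_section <- function(section, start_position = 0, start_direction = 1,
                          sample_rate = 100) {
  stopifnot(inherits(section, "stimulus_section"))
  if (is.na(section$duration) || section$duration <= 0) {
    stop("section duration must be assigned and positive")
  }
  if (!start_direction %in% c(-1, 1)) stop("start_direction must be +-1")
  if (sample_rate < 50) stop("sample_rate must be >= 50 Hz")
  f <- section$frequency
  if (!is_whole(2 * f * section$duration)) {
    stop("section duration must cover a whole number of half-cycles")
  }
  D <- section_extent(section)
  w <- 2 * pi * f
  t <- seq(0, section$duration, by = 1 / sample_rate)
  new_trajectory(
    position = start_position + start_direction * (D / 2) * (1 - cos(w * t)),
    velocity = start_direction * (D / 2) * w * sin(w * t),
    acceleration = start_direction * (D / 2) * w^2 * cos(w * t),
    sample_rate = sample_rate
  )
}

#' Blend a join with a position- and velocity-matching cubic
#'
#' Position (and its derivatives) on `[join - half_window, join +
#' half_window]` are replaced by the unique cubic that matches the position
#' and velocity at both window edges, removing any discontinuity introduced
#' where sections with different amplitude meet.
#'
#' @param traj A trajectory.
#' @param join_time Join time in seconds.
#' @param half_window Half-width of the replacement window, seconds.
#' @return The blended trajectory.
#' @export
blend_join <- function(traj, join_time, half_window = 0.25) {
  stopifnot(inherits(traj, "trajectory"))
  tt <- traj_time(traj)
  lo <- join_time - half_window
  hi <- join_time + half_window
  if (lo < tt[1] - 1e-9 || hi > tt[length(tt)] + 1e-9) {
    stop("blend window extends beyond the trace")
  }
  i0 <- max(which(tt <= lo + 1e-9))
  i1 <- min(which(tt >= hi - 1e-9))
  if (i1 - i0 < 3) stop("blend window too narrow for the sample rate")
  h <- tt[i1] - tt[i0]
  x0 <- traj$position[i0]; v0 <- traj$velocity[i0]
  x1 <- traj$position[i1]; v1 <- traj$velocity[i1]
  s <- (tt[i0:i1] - tt[i0]) / h
  # cubic Hermite basis
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  traj$position[i0:i1] <- h00 * x0 + h10 * h * v0 + h01 * x1 + h11 * h * v1
  d00 <- 6 * s^2 - 6 * s
  d10 <- 3 * s^2 - 4 * s + 1
  d01 <- -6 * s^2 + 6 * s
  d11 <- 3 * s^2 - 2 * s
  traj$velocity[i0:i1] <-
    (d00 * x0 + d01 * x1) / h + d10 * v0 + d11 * v1
  e00 <- 12 * s - 6
  e10 <- 6 * s - 4
  e01 <- -12 * s + 6
  e11 <- 6 * s - 2
  traj$acceleration[i0:i1] <-
    (e00 * x0 + e01 * x1) / h^2 + (e10 * v0 + e11 * v1) / h
  traj
}

#' Build a full stimulus trial
#'
#' Concatenates the trial's sections as sinusoids about a fixed workspace
#' center (amplitude changes are absorbed by the blend windows), blends every
#' section join with a cubic over +-`blend_half_window` s, and annotates
#' exact section and half-cycle boundaries.
#'
#' @param spec A [trial_spec()]; durations are assigned via
#'   [round_section_durations()] if missing.
#' @param sample_rate Sampling rate in Hz.
#' @param blend_half_window Half-width of the join blend, seconds.
#' @param workspace_width Physical track width in cm; a section whose extent
#'   exceeds it triggers a warning (or an error if `workspace_error`).
#' @param workspace_error Escalate the workspace warning to an error.
#' @return An object of class `stimulus_trial`: a list with elements
#'   `trajectory`, `sections` (data frame), `half_cycles` (data frame),
#'   `trial_id` and `blend_half_window`.
#' @export
build_trial <- function(spec, sample_rate = 100, blend_half_window = 0.25,
                        workspace_width = 45.5, workspace_error = FALSE) {
  stopifnot(inherits(spec, "trial_spec"))
  if (any(is.na(vapply(spec$sections, `[[`, 0, "duration")))) {
    spec <- round_section_durations(spec)
  }
  n_sec <- length(spec$sections)
  f <- vapply(spec$sections, `[[`, 0, "frequency")
  v <- vapply(spec$sections, `[[`, 0, "peak_velocity")
  d <- vapply(spec$sections, `[[`, 0, "duration")
  D <- v / (pi * f)
  starts <- cumsum(c(0, d[-n_sec]))
  total <- sum(d)

  over <- D > workspace_width
  if (any(over)) {
    msg <- sprintf(
      "trial %d: section extent %.1f cm exceeds workspace width %.1f cm",
      spec$trial_id, max(D[over]), workspace_width
    )
    if (workspace_error) stop(msg) else warning(msg)
  }

  # direction of the first movement of each section: continue the alternation
  n_half <- round(2 * f * d)
  dir <- numeric(n_sec)
  dir[1] <- 1
  if (n_sec > 1) {
    for (k in 2:n_sec) dir[k] <- dir[k - 1] * (-1)^n_half[k - 1]
  }

  t <- seq(0, total, by = 1 / sample_rate)
  sec_of <- findInterval(t, starts, rightmost.closed = FALSE)
  sec_of[sec_of > n_sec] <- n_sec
  tau <- t - starts[sec_of]
  w <- 2 * pi * f[sec_of]
  amp <- dir[sec_of] * D[sec_of] / 2
  traj <- new_trajectory(
    position = -amp * cos(w * tau),
    velocity = amp * w * sin(w * tau),
    acceleration = amp * w^2 * cos(w * tau),
    sample_rate = sample_rate
  )
  if (n_sec > 1) {
    for (k in 2:n_sec) {
      traj <- blend_join(traj, starts[k], blend_half_window)
    }
  }

  sections <- data.frame(
    trial = spec$trial_id,
    section = seq_len(n_sec),
    frequency = f,
    peak_velocity = v,
    t_start = starts,
    t_end = starts + d,
    duration = d,
    extent_cm = D,
    direction = dir
  )

  half_cycles <- do.call(rbind, lapply(seq_len(n_sec), function(k) {
    j <- seq_len(n_half[k])
    m <- dir[k] * (-1)^(j - 1)  # movement direction of each half-cycle
    data.frame(
      trial = spec$trial_id,
      section = k,
      hc = j,
      frequency = f[k],
      peak_velocity = v[k],
      t_start = starts[k] + (j - 1) / (2 * f[k]),
      t_end = starts[k] + j / (2 * f[k]),
      x_start = -m * D[k] / 2,
      x_end = m * D[k] / 2
    )
  }))

  structure(
    list(
      trajectory = traj,
      sections = sections,
      half_cycles = half_cycles,
      trial_id = spec$trial_id,
      blend_half_window = blend_half_window
    ),
    class = "stimulus_trial"
  )
}

#' @export
print.stimulus_trial <- function(x, ...) {
  cat(sprintf("<stimulus_trial %d> %d sections, %d half-cycles, %.0f s\n",
              x$trial_id, nrow(x$sections), nrow(x$half_cycles),
              max(x$sections$t_end)))
  print(x$sections[, c("section", "frequency", "peak_velocity",
                       "t_start", "t_end")])
  invisible(x)
}
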