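#' Segment a stimulus into half-cycle windows
#'
#' One window per stimulus half-cycle (turning point to turning point). For
#' annotated trials built with [build_trial()] the design boundaries are
#' used, with each join's blend window assigned to the following half-cycle
#' (the window that begins at a section join starts `blend_half_window`
#' seconds early, and the preceding window ends there). For plain
#' trajectories, turning points are detected from velocity zero crossings.
#'
#' @param stimulus A `stimulus_trial` or a plain trajectory.
#' @return Data frame of windows: `t_start`, `t_end`, plus `section`,
#'   `frequency`, `peak_velocity`, `x_start`, `x_end` when annotated.
#' @export
segment_by_stimulus <- function(stimulus) {
  if (inherits(stimulus, "stimulus_trial")) {
    hc <- stimulus$half_cycles
    hw <- stimulus$blend_half_window
    joins <- stimulus$sections$t_start[-1]
    for (j in joins) {
      hc$t_end[abs(hc$t_end - j) < 1e-9] <- j - hw
      hc$t_start[abs(hc$t_start - j) < 1e-9] <- j - hw
    }
    return(hc)
  }
  stopifnot(inherits(stimulus, "trajectory"))
  if (stats::sd(stimulus$velocity, na.rm = TRUE) == 0 ||
      all(is.na(stimulus$velocity))) {
    stop("stimulus has no well-defined turning points")
  }
  tp <- find_turning_points(stimulus)
  tp <- c(traj_time(stimulus)[1], tp, max(traj_time(stimulus)))
  tp <- tp[!duplicated(round(tp, 9))]
  if (length(tp) < 2) stop("stimulus has no well-defined turning points")
  n <- length(tp) - 1
  x_at <- traj_interp(stimulus, tp, "position")
  data.frame(
    trial = NA_integer_, section = NA_integer_, hc = seq_len(n),
    frequency = 0.5 / diff(tp), peak_velocity = NA_real_,
    t_start = tp[-length(tp)], t_end = tp[-1],
    x_start = x_at[-length(x_at)], x_end = x_at[-1]
  )
}

#' Match response AZCs to stimulus AZCs
#'
#' One-to-one matching within `+-tolerance` seconds, maximizing the number
#' of matched pairs and, among such matchings, minimizing the total time
#' mismatch (for events on a time line the optimum can always be taken
#' non-crossing, so it is found by dynamic programming over the two sorted
#' lists). Response AZCs left unmatched are the jitter points: corrective
#' accelerations with no counterpart in the stimulus.
#'
#' @param response_azc,stimulus_azc Sorted AZC time vectors (s).
#' @param tolerance Matching half-window, seconds.
#' @return List with `matched` (data frame `response_time`, `stimulus_time`)
#'   and `jitter_points` (unmatched response AZC times).
#' @export
match_azc <- function(response_azc, stimulus_azc, tolerance = 0.2) {
  response_azc <- sort(as.numeric(response_azc))
  stimulus_azc <- sort(as.numeric(stimulus_azc))
  nr <- length(response_azc)
  ns <- length(stimulus_azc)
  empty <- data.frame(response_time = numeric(0), stimulus_time = numeric(0))
  if (nr == 0 || ns == 0) {
    return(list(matched = empty, jitter_points = response_azc))
  }
  # DP over sorted lists: maximize matches, then minimize summed |dt|
  M <- matrix(0L, nr + 1, ns + 1)
  C <- matrix(0, nr + 1, ns + 1)
  for (i in seq_len(nr)) {
    for (j in seq_len(ns)) {
      m_skip <- max(M[i, j + 1], M[i + 1, j])
      c_skip <- min(
        if (M[i, j + 1] == m_skip) C[i, j + 1] else Inf,
        if (M[i + 1, j] == m_skip) C[i + 1, j] else Inf
      )
      dt <- abs(response_azc[i] - stimulus_azc[j])
      if (dt <= tolerance) {
        m_pair <- M[i, j] + 1L
        c_pair <- C[i, j] + dt
        if (m_pair > m_skip || (m_pair == m_skip && c_pair < c_skip)) {
          M[i + 1, j + 1] <- m_pair
          C[i + 1, j + 1] <- c_pair
          next
        }
      }
      M[i + 1, j + 1] <- m_skip
      C[i + 1, j + 1] <- c_skip
    }
  }
  # backtrack
  i <- nr; j <- ns
  ri <- integer(0); si <- integer(0)
  while (i > 0 && j > 0) {
    dt <- abs(response_azc[i] - stimulus_azc[j])
    if (dt <= tolerance &&
        M[i + 1, j + 1] == M[i, j] + 1L &&
        abs(C[i + 1, j + 1] - (C[i, j] + dt)) < 1e-12) {
      ri <- c(i, ri); si <- c(j, si)
      i <- i - 1; j <- j - 1
    } else if (M[i, j + 1] == M[i + 1, j + 1] &&
               C[i, j + 1] <= C[i + 1, j + 1] + 1e-12) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(
    matched = data.frame(response_time = response_azc[ri],
                         stimulus_time = stimulus_azc[si]),
    jitter_points = response_azc[setdiff(seq_len(nr), ri)]
  )
}

#' Jitter frequencies from jitter-point times
#'
#' The jitter frequency of each consecutive pair of jitter points is half
#' the reciprocal of their separation (a full correction cycle spans two
#' jitter points). The peak jitter frequency is the mode of a 0.05 Hz-binned
#' histogram of those interval frequencies, reported as the mean of the
#' frequencies in the modal bin.
#'
#' @param jitter_times Sorted jitter-point times (s).
#' @param bin_width Histogram bin width, Hz.
#' @return List of class `jitter_profile`: `jitter_times`,
#'   `interval_frequencies` (Hz), `peak_jitter_frequency` (Hz; `NA` when
#'   fewer than two jitter points).
#' @export
jitter_frequency <- function(jitter_times, bin_width = 0.05) {
  jitter_times <- sort(jitter_times)
  if (length(jitter_times) < 2) {
    return(structure(
      list(jitter_times = jitter_times,
           interval_frequencies = numeric(0),
           peak_jitter_frequency = NA_real_),
      class = "jitter_profile"
    ))
  }
  freqs <- 0.5 / diff(jitter_times)
  bins <- floor(round(freqs / bin_width, 9))
  counts <- table(bins)
  modal <- as.numeric(names(counts)[which.max(counts)])
  structure(
    list(jitter_times = jitter_times,
         interval_frequencies = freqs,
         peak_jitter_frequency = mean(freqs[bins == modal])),
    class = "jitter_profile"
  )
}

#' Per-segment similarity metrics dX, dV, dT
#'
#' Within one half-cycle window, the segment-local lag `l*` maximizes the
#' normalized cross-correlation of response and stimulus velocity over
#' `+-max_lag` s. Then `dT = |l*|`; `dV` is the RMS velocity difference (at
#' lag `l*`) relative to the stimulus RMS velocity; `dX` is the RMS position
#' difference relative to the stimulus segment extent.
#'
#' @param aligned_response Response trajectory on the stimulus grid (see
#'   [register_response()]).
#' @param stimulus Stimulus trajectory.
#' @param window List or one-row data frame with `t_start` and `t_end`.
#' @param max_lag Segment-local lag search half-range, seconds.
#' @return Named numeric vector `c(dX, dV, dT)`.
#' @export
segment_metrics <- function(aligned_response, stimulus, window,
                            max_lag = 0.5) {
  rate <- stimulus$sample_rate
  ts <- traj_time(stimulus)
  i <- which(ts >= window$t_start - 1e-9 & ts < window$t_end - 1e-9)
  if (length(i) < 4) stop("window must contain at least 4 samples")
  vs <- stimulus$velocity[i]
  xs <- stimulus$position[i]
  if (stats::sd(vs) == 0) stop("undefined metrics: zero-variance stimulus segment")
  vr_all <- aligned_response$velocity
  xr_all <- aligned_response$position
  n_all <- length(vr_all)
  K <- round(max_lag * rate)
  best_k <- NA_integer_
  best_cc <- -Inf
  ss_vs <- sum(vs^2)
  for (k in -K:K) {
    j <- i + k
    keep <- j >= 1 & j <= n_all
    b <- vr_all[j[keep]]
    ok <- !is.na(b)
    if (sum(ok) < 4) next
    a <- vs[keep][ok]
    b <- b[ok]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) next
    cc <- sum(a * b) / den
    if (cc > best_cc) {
      best_cc <- cc
      best_k <- k
    }
  }
  if (is.na(best_k)) {
    return(c(dX = NA_real_, dV = NA_real_, dT = NA_real_))
  }
  j <- i + best_k
  keep <- j >= 1 & j <= n_all
  vr <- vr_all[j[keep]]
  xr <- xr_all[j[keep]]
  ok <- !is.na(vr) & !is.na(xr)
  vs_k <- vs[keep][ok]
  xs_k <- xs[keep][ok]
  vr <- vr[ok]
  xr <- xr[ok]
  extent <- max(xs) - min(xs)
  if (extent == 0) stop("undefined metrics: zero-extent stimulus segment")
  c(
    dX = sqrt(mean((xr - xs_k)^2)) / extent,
    dV = sqrt(mean((vr - vs_k)^2)) / sqrt(mean(vs_k^2)),
    dT = abs(best_k) / rate
  )
}

#' Classify one segment as co-confident
#'
#' A segment is CC when the window contains no jitter point — every
#' response AZC in it is matched one-to-one to a stimulus AZC — and the
#' response is similar enough to the stimulus: `dV < dv_threshold` and
#' `dT < dt_threshold` s. An ordinary half-cycle holds exactly one stimulus
#' AZC (its speed peak), so for a response tracking it smoothly the rule
#' reduces to the classic "exactly one AZC, i.e. no jitter"; windows
#' containing a cubic join blend carry additional (or near-degenerate)
#' stimulus AZCs, and there only unmatched corrective AZCs count against
#' the segment. A response too dissimilar to move with the stimulus is
#' rejected by the dV threshold.
#'
#' @param segment List or one-row data frame with `response_azc_count`,
#'   `stimulus_azc_count`, `n_jitter`, `dV`, `dT`.
#' @param dv_threshold,dt_threshold Similarity thresholds.
#' @return Logical.
#' @export
classify_cc <- function(segment, dv_threshold = 0.95, dt_threshold = 0.15) {
  isTRUE(segment$n_jitter == 0) &&
    isTRUE(segment$dV < dv_threshold) &&
    isTRUE(segment$dT < dt_threshold)
}

#' Full CC analysis of one response against one stimulus trial
#'
#' Registers the response to the stimulus, finds AZCs in both, matches them
#' to isolate jitter points, computes dX/dV/dT per half-cycle window, and
#' classifies each window as CC or not.
#'
#' @param response A trajectory, or a raw time/position data frame (passed
#'   through [preprocess()]).
#' @param stim_trial A `stimulus_trial` from [build_trial()].
#' @param max_lag Registration search half-range, seconds.
#' @param azc_tolerance AZC matching tolerance, seconds.
#' @param dv_threshold,dt_threshold CC similarity thresholds.
#' @param prominence_frac AZC noise floor (see [find_azc()]).
#' @return Object of class `cc_analysis`: list with `segments` (one row per
#'   half-cycle window, all classification fields), `jitter_points`,
#'   `registration`, and `stim_trial`.
#' @export
analyze_response <- function(response, stim_trial, max_lag = 0.5,
                             azc_tolerance = 0.2, dv_threshold = 0.95,
                             dt_threshold = 0.15, prominence_frac = 0.02) {
  stopifnot(inherits(stim_trial, "stimulus_trial"))
  stim <- stim_trial$trajectory
  if (is.data.frame(response)) {
    response <- preprocess(response, sample_rate = stim$sample_rate)
  }
  reg <- register_response(response, stim, max_lag = max_lag)
  aligned <- reg$aligned_response

  azc_resp <- find_azc(aligned, prominence_frac)
  azc_stim <- find_azc(stim, prominence_frac)
  m <- match_azc(azc_resp, azc_stim, tolerance = azc_tolerance)
  jitter <- m$jitter_points

  windows <- segment_by_stimulus(stim_trial)
  n_w <- nrow(windows)
  res <- windows
  res$response_azc_count <- NA_integer_
  res$stimulus_azc_count <- NA_integer_
  res$n_jitter <- NA_integer_
  res$dX <- NA_real_
  res$dV <- NA_real_
  res$dT <- NA_real_
  res$is_cc <- FALSE

  for (w in seq_len(n_w)) {
    t0 <- windows$t_start[w]
    t1 <- windows$t_end[w]
    in_w <- azc_resp >= t0 & azc_resp < t1
    res$response_azc_count[w] <- sum(in_w)
    res$stimulus_azc_count[w] <- sum(azc_stim >= t0 & azc_stim < t1)
    res$n_jitter[w] <- sum(jitter >= t0 & jitter < t1)
    mets <- tryCatch(
      segment_metrics(aligned, stim, list(t_start = t0, t_end = t1)),
      error = function(e) c(dX = NA_real_, dV = NA_real_, dT = NA_real_)
    )
    res$dX[w] <- mets[["dX"]]
    res$dV[w] <- mets[["dV"]]
    res$dT[w] <- mets[["dT"]]
    res$is_cc[w] <- classify_cc(res[w, ], dv_threshold, dt_threshold)
  }

  structure(
    list(segments = res, jitter_points = jitter, registration = reg,
         stim_trial = stim_trial),
    class = "cc_analysis"
  )
}

#' Binary per-sample CC membership vector
#'
#' @param analysis A `cc_analysis` (or its `segments` data frame together
#'   with `sample_rate`, `t0` and `t_total`).
#' @param sample_rate,t0,t_total Timebase; defaults taken from the analysis.
#' @return Integer vector of 0/1, one entry per sample.
#' @export
cc_vector <- function(analysis, sample_rate = NULL, t0 = NULL,
                      t_total = NULL) {
  if (inherits(analysis, "cc_analysis")) {
    segs <- analysis$segments
    stim <- analysis$stim_trial$trajectory
    if (is.null(sample_rate)) sample_rate <- stim$sample_rate
    if (is.null(t0)) t0 <- stim$t0
    # half-open span [t0, t0 + t_total): the endpoint sample belongs to no window
    if (is.null(t_total)) t_total <- (length(stim) - 1) / sample_rate
  } else {
    segs <- analysis
    if (is.null(sample_rate) || is.null(t0) || is.null(t_total)) {
      stop("sample_rate, t0 and t_total required with a plain segments table")
    }
  }
  tt <- t0 + seq(0, by = 1 / sample_rate, length.out = round(t_total * sample_rate))
  v <- integer(length(tt))
  cc <- segs[segs$is_cc, , drop = FALSE]
  for (w in seq_len(nrow(cc))) {
    v[tt >= cc$t_start[w] - 1e-9 & tt < cc$t_end[w] - 1e-9] <- 1L
  }
  v
}

#' Trial-level summary of a CC analysis
#'
#' `percent_cc` is time-based: 100 x (time covered by CC windows) / (trial
#' time). Metric means are over all classified segments; the peak jitter
#' frequency is estimated from all jitter points in the trial.
#'
#' @param analysis A `cc_analysis`.
#' @return Data frame with one row: `percent_cc`, `dX_mean`, `dV_mean`,
#'   `dT_mean`, `peak_jitter_frequency`, `n_segments`, `n_cc`.
#' @export
summarize_trial <- function(analysis) {
  stopifnot(inherits(analysis, "cc_analysis"))
  segs <- analysis$segments
  total <- max(segs$t_end) - min(segs$t_start)
  cc_time <- sum((segs$t_end - segs$t_start)[segs$is_cc])
  jp <- jitter_frequency(analysis$jitter_points)
  data.frame(
    percent_cc = 100 * cc_time / total,
    dX_mean = mean(segs$dX, na.rm = TRUE),
    dV_mean = mean(segs$dV, na.rm = TRUE),
    dT_mean = mean(segs$dT, na.rm = TRUE),
    peak_jitter_frequency = jp$peak_jitter_frequency,
    n_segments = nrow(segs),
    n_cc = sum(segs$is_cc)
  )
}
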