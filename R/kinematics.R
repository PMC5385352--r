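#' Preprocess a raw time/position trace
#'
#' Resamples the trace to a uniform grid and derives velocity and
#' acceleration by Savitzky-Golay smoothing differentiation (polynomial
#' order 2, window 250 ms by default; acceleration as the cascaded smoothed
#' derivative of the smoothed velocity): low-order zero-phase local
#' polynomials pass the jitter structure of hand movements (below ~3 Hz)
#' and preserve AZC locations while keeping quantization noise in the
#' second derivative below the AZC prominence floor. Missing stretches up
#' to `max_gap` s are linearly interpolated; longer gaps or more than 5%
#' missing data are an error.
#'
#' @param raw Data frame with `time_s` and `position_cm` columns (aliases
#'   `time`/`position` accepted), or a path handled by [read_tracking_csv()].
#' @param sample_rate Target sampling rate in Hz.
#' @param smooth_window Differentiation filter window in seconds.
#' @param max_gap Longest interpolatable gap in seconds.
#' @return A [new_trajectory()] object.
#' @export
preprocess <- function(raw, sample_rate = 100, smooth_window = 0.25,
                       max_gap = 0.1) {
  if (is.character(raw)) raw <- read_tracking_csv(raw)
  nm <- names(raw)
  if ("time" %in% nm && !"time_s" %in% nm) raw$time_s <- raw$time
  if ("position" %in% nm && !"position_cm" %in% nm) raw$position_cm <- raw$position
  if (!all(c("time_s", "position_cm") %in% names(raw))) {
    stop("raw must have time_s and position_cm columns")
  }
  t_raw <- raw$time_s
  x_raw <- raw$position_cm
  if (is.unsorted(t_raw, strictly = TRUE)) {
    stop("malformed input: timestamps must be strictly increasing")
  }
  if (mean(is.na(x_raw)) > 0.05) {
    stop("malformed input: more than 5% of positions missing")
  }
  if (diff(range(t_raw)) < 2) stop("need at least 2 s of data")

  ok <- !is.na(x_raw)
  if (!all(ok)) {
    # longest NA run, in seconds
    runs <- rle(!ok)
    if (any(runs$values)) {
      ends <- cumsum(runs$lengths)
      starts_i <- ends - runs$lengths + 1
      gap_len <- vapply(which(runs$values), function(j) {
        i0 <- max(starts_i[j] - 1, 1)
        i1 <- min(ends[j] + 1, length(t_raw))
        t_raw[i1] - t_raw[i0]
      }, 0)
      if (any(gap_len > max_gap)) {
        stop(sprintf("gap of %.3f s exceeds max_gap = %.3f s",
                     max(gap_len), max_gap))
      }
    }
  }

  dt <- 1 / sample_rate
  t_grid <- seq(t_raw[1], t_raw[length(t_raw)], by = dt)
  x <- stats::approx(t_raw[ok], x_raw[ok], xout = t_grid, rule = 2)$y

  n_w <- round(smooth_window * sample_rate)
  if (n_w %% 2 == 0) n_w <- n_w + 1
  n_w <- max(n_w, 5)
  pos <- signal::sgolayfilt(x, p = 2, n = n_w, m = 0)
  vel <- signal::sgolayfilt(x, p = 2, n = n_w, m = 1, ts = dt)
  # cascade: acceleration as the smoothed derivative of the smoothed
  # velocity; a one-pass second derivative would amplify position noise far
  # beyond the AZC prominence floor
  acc <- signal::sgolayfilt(vel, p = 2, n = n_w, m = 1, ts = dt)
  new_trajectory(pos, vel, acc, sample_rate, t0 = t_grid[1])
}

#' Register a response against its stimulus
#'
#' Finds the single constant lag (positive = response late) that maximizes
#' the normalized cross-correlation of the two velocity traces over
#' `[-max_lag, +max_lag]`, and returns the response resampled onto the
#' stimulus time grid after removing that lag. Residual per-segment timing
#' differences are deliberately left in place; they are measured separately
#' as the segment timing error dT.
#'
#' @param response,stimulus Trajectories with the same sample rate.
#' @param max_lag Search half-range in seconds.
#' @return An object of class `registration`: list with `lag` (s),
#'   `quality` (peak normalized cross-correlation), and `aligned_response`
#'   (a trajectory on the stimulus grid; samples with no response data are
#'   `NA`).
#' @export
register_response <- function(response, stimulus, max_lag = 0.5) {
  stopifnot(inherits(response, "trajectory"), inherits(stimulus, "trajectory"))
  if (abs(response$sample_rate - stimulus$sample_rate) > 1e-9) {
    stop("response and stimulus must share a sample rate")
  }
  if (stats::sd(response$velocity) == 0 || stats::sd(stimulus$velocity) == 0) {
    stop("undefined registration: zero-variance velocity")
  }
  rate <- stimulus$sample_rate
  ts <- traj_time(stimulus)
  # response velocity on the stimulus grid (NA outside support)
  vr0 <- traj_interp(response, ts, "velocity")
  vs <- stimulus$velocity
  K <- round(max_lag * rate)
  n <- length(vs)
  score <- rep(NA_real_, 2 * K + 1)
  for (k in -K:K) {
    # compare vs[i] with response at ts[i] + lag, i.e. vr0 shifted left by k
    i <- seq_len(n)
    j <- i + k
    keep <- j >= 1 & j <= n
    a <- vs[i[keep]]
    b <- vr0[j[keep]]
    cc <- !is.na(b)
    if (sum(cc) < 5 * rate) next  # require >= 5 s of overlap
    a <- a[cc]; b <- b[cc]
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) next
    score[k + K + 1] <- sum(a * b) / den
  }
  if (all(is.na(score))) stop("insufficient overlap for registration")
  best <- which.max(score)
  lag <- (best - K - 1) / rate
  aligned <- new_trajectory(
    traj_interp(response, ts + lag, "position"),
    traj_interp(response, ts + lag, "velocity"),
    traj_interp(response, ts + lag, "acceleration"),
    rate, t0 = stimulus$t0
  )
  structure(
    list(lag = lag, quality = score[best], aligned_response = aligned),
    class = "registration"
  )
}

#' @export
print.registration <- function(x, ...) {
  cat(sprintf("<registration> lag = %+.3f s, peak xcorr = %.3f\n",
              x$lag, x$quality))
  invisible(x)
}

#' Find acceleration zero crossings
#'
#' Returns the times where acceleration changes sign, linearly interpolated
#' to sub-sample precision. A crossing whose flanking acceleration extrema
#' (between it and its neighboring crossings, or the trace ends) are both
#' smaller than `prominence_frac` of the trace's maximal |acceleration| is
#' suppressed as noise; the guard has no effect on noise-free traces.
#'
#' @param traj A trajectory (or a plain numeric acceleration vector together
#'   with `sample_rate`/`t0`).
#' @param prominence_frac Noise floor as a fraction of max |acceleration|.
#' @param sample_rate,t0 Used only when `traj` is a plain numeric vector.
#' @return Numeric vector of crossing times (s), strictly increasing;
#'   possibly empty.
#' @export
find_azc <- function(traj, prominence_frac = 0.02, sample_rate = NULL,
                     t0 = 0) {
  if (inherits(traj, "trajectory")) {
    a <- traj$acceleration
    tt <- traj_time(traj)
  } else {
    if (is.null(sample_rate)) stop("sample_rate required for plain vectors")
    a <- as.numeric(traj)
    tt <- t0 + (seq_along(a) - 1) / sample_rate
  }
  keep <- !is.na(a)
  a <- a[keep]; tt <- tt[keep]
  if (length(a) < 2) return(numeric(0))

  s <- sign(a)
  # carry the previous non-zero sign across exact zeros
  nz <- s != 0
  if (!any(nz)) return(numeric(0))
  idx <- cumsum(nz)
  filled <- s[nz][pmax(idx, 1)]
  filled[idx == 0] <- filled[which(idx >= 1)[1]]
  ch <- which(filled[-1] != filled[-length(filled)])
  if (length(ch) == 0) return(numeric(0))
  # linear interpolation between bracketing samples
  t_cross <- tt[ch] + (tt[ch + 1] - tt[ch]) * a[ch] / (a[ch] - a[ch + 1])

  # prominence guard: extrema of |a| between consecutive crossings
  floor_a <- prominence_frac * max(abs(a))
  bounds <- c(1, ch, length(a))
  n_cr <- length(ch)
  seg_max <- vapply(seq_len(n_cr + 1), function(j) {
    i0 <- bounds[j]
    i1 <- if (j <= n_cr) ch[j] + 1 else length(a)
    max(abs(a[i0:i1]))
  }, 0)
  keep_cr <- !(seg_max[seq_len(n_cr)] < floor_a &
                 seg_max[seq_len(n_cr) + 1] < floor_a)
  sort(t_cross[keep_cr])
}

#' Turning points of a movement trace
#'
#' Velocity zero crossings with sub-sample interpolation; used to segment
#' free motion into half-cycles when no design annotation is available.
#'
#' @inheritParams find_azc
#' @return Numeric vector of turning-point times (s).
#' @export
find_turning_points <- function(traj, prominence_frac = 0.02) {
  vtraj <- new_trajectory(traj$velocity, traj$velocity, traj$velocity,
                          traj$sample_rate, traj$t0)
  find_azc(vtraj, prominence_frac)
}
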