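#' Uniformly sampled 1-D kinematic trace
#'
#' A `trajectory` holds position, velocity and acceleration sampled on a
#' uniform time grid. Positions are in cm, velocities in cm/s, accelerations
#' in cm/s^2; the grid starts at `t0` seconds and advances by
#' `1/sample_rate`.
#'
#' @param position,velocity,acceleration Numeric vectors of equal length.
#' @param sample_rate Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(position, velocity, acceleration, sample_rate,
                           t0 = 0) {
  n <- length(position)
  if (length(velocity) != n || length(acceleration) != n) {
    stop("position, velocity and acceleration must have the same length")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("sample_rate must be a positive number")
  }
  structure(
    list(
      position = as.numeric(position),
      velocity = as.numeric(velocity),
      acceleration = as.numeric(acceleration),
      sample_rate = sample_rate,
      t0 = t0
    ),
    class = "trajectory"
  )
}

#' Time grid of a trajectory
#'
#' @param traj A [new_trajectory()] object.
#' @return Numeric vector of sample times in seconds.
#' @export
traj_time <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$t0 + (seq_along(traj$position) - 1L) / traj$sample_rate
}

#' @export
length.trajectory <- function(x) length(x$position)

#' @export
print.trajectory <- function(x, ...) {
  tt <- traj_time(x)
  cat(sprintf(
    "<trajectory> %d samples @ %g Hz, t = [%.3f, %.3f] s, x in [%.2f, %.2f] cm\n",
    length(x$position), x$sample_rate, tt[1], tt[length(tt)],
    min(x$position), max(x$position)
  ))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(
    time_s = traj_time(x),
    position_cm = x$position,
    velocity_cm_s = x$velocity,
    acceleration_cm_s2 = x$acceleration
  )
}

#' Write a trajectory as a tidy CSV time series
#'
#' Columns are `time_s`, `position_cm`, `velocity_cm_s`, `acceleration_cm_s2`,
#' the dialect shared by the stimulus builder and the synthetic follower.
#'
#' @param traj A trajectory.
#' @param path File path.
#' @param extra Optional data frame of per-sample annotation columns (e.g.
#'   trial or section labels) appended to the right of the kinematic columns.
#' @export
write_trajectory_csv <- function(traj, path, extra = NULL) {
  df <- as.data.frame(traj)
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(df))
    df <- cbind(df, extra)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a time/position table or trajectory CSV
#'
#' Accepts the CSV dialect written by [write_trajectory_csv()], or any table
#' with at least `time_s` and `position_cm` columns (alias: `time`,
#' `position`). Velocity/acceleration columns are used when present;
#' otherwise the caller should run [preprocess()].
#'
#' @param path File path.
#' @return A data frame with at least `time_s` and `position_cm`.
#' @export
read_tracking_csv <- function(path) {
  df <- utils::read.csv(path)
  nm <- names(df)
  if ("time" %in% nm && !"time_s" %in% nm) df$time_s <- df$time
  if ("position" %in% nm && !"position_cm" %in% nm) df$position_cm <- df$position
  if (!all(c("time_s", "position_cm") %in% names(df))) {
    stop("file must contain time/position columns (time_s, position_cm)")
  }
  df
}

# linear interpolation of a trajectory channel at arbitrary times; NA outside
traj_interp <- function(traj, times, channel = "position") {
  stats::approx(traj_time(traj), traj[[channel]], xout = times,
                method = "linear", rule = 1)$y
}
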