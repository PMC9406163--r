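#' Segmentation configuration
#'
#' @param velocity_threshold Hand speed threshold marking movement onset, m/s
#'   (default 0.02); chosen to exclude postural oscillation at the start point.
#' @param start_radius Radius of the start disc, cm (default 1.0): "leaving
#'   the starting point" means leaving this disc.
#' @param min_phase_duration Minimum phase duration before a return to the
#'   start disc may terminate the phase, seconds (default 0.1, below the
#'   duration of the fastest legal robot-driven traversal so genuine phase
#'   ends are never missed, yet long enough to bridge onset jitter).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(velocity_threshold = 0.02, start_radius = 1.0,
                                min_phase_duration = 0.1) {
  stopifnot(velocity_threshold > 0, start_radius > 0, min_phase_duration > 0)
  structure(list(velocity_threshold = velocity_threshold,
                 start_radius = start_radius,
                 min_phase_duration = min_phase_duration),
            class = "segmentation_config")
}

#' Segment a movement phase from a raw trajectory
#'
#' The phase starts at the first sample where the hand is outside the start
#' disc and moving at or above the velocity threshold, and ends at the first
#' later sample back inside the start disc once the minimum phase duration has
#' elapsed. If the hand never returns, the crop extends to the final sample
#' and the result is flagged (`no_return = TRUE`).
#'
#' @param traj A `trajectory` (meters, seconds).
#' @param cfg A [segmentation_config()].
#' @return The cropped `trajectory`.
#' @export
segment_phase <- function(traj, cfg = segmentation_config()) {
  n <- length(traj$t)
  if (n < 2L) stop("trajectory has fewer than 2 samples", call. = FALSE)
  xy <- cbind(traj$x, traj$y)
  speed <- finite_diff_speed(traj$t, xy)
  r_m <- cfg$start_radius / 100
  outside <- sqrt(traj$x^2 + traj$y^2) > r_m
  start_ok <- which(outside & speed >= cfg$velocity_threshold)
  if (length(start_ok) == 0L) stop("no movement detected", call. = FALSE)
  i0 <- start_ok[1L]
  t0 <- traj$t[i0]
  back <- which(!outside & traj$t > t0 + cfg$min_phase_duration &
                  seq_len(n) > i0)
  no_return <- length(back) == 0L
  i1 <- if (no_return) n else back[1L]
  out <- new_trajectory(traj$phase, traj$t[i0:i1], traj$x[i0:i1],
                        traj$y[i0:i1], truncated = isTRUE(traj$truncated))
  out$no_return <- no_return
  if (no_return) {
    warning("hand did not return to the start point; cropped at final sample",
            call. = FALSE)
  }
  out
}

#' Normalize a trajectory in time
#'
#' Resamples the x and y position signals by linear interpolation onto
#' `n_samples` uniformly spaced points over the phase's time span, discarding
#' speed differences between phases. Output is in centimeters in the
#' start-point-centered frame.
#'
#' @param traj A (cropped) `trajectory` in meters.
#' @param n_samples Number of output samples (default 1000).
#' @return An object of class `normalized_path` with fields `x` and `y` (cm).
#' @export
time_normalize <- function(traj, n_samples = 1000L) {
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  if (length(traj$t) < 2L) stop("trajectory has fewer than 2 samples",
                                call. = FALSE)
  tt <- seq(traj$t[1L], traj$t[length(traj$t)], length.out = n_samples)
  structure(list(x = stats::approx(traj$t, traj$x, xout = tt)$y * 100,
                 y = stats::approx(traj$t, traj$y, xout = tt)$y * 100,
                 n_samples = as.integer(n_samples)),
            class = "normalized_path")
}

#' @export
print.normalized_path <- function(x, ...) {
  cat("Normalized path: ", x$n_samples, " samples, extent ",
      sprintf("%.1f x %.1f", diff(range(x$x)), diff(range(x$y))), " cm\n",
      sep = "")
  invisible(x)
}
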