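#' Synthetic fly-like heading trajectory
#'
#' Generates a heading time series emulating a fruit fly circling a flight
#' arena: a slow continuous rotational drift plus rapid, quasi-regularly
#' timed body saccades, together completing one revolution per
#' `1 / dominant_freq` seconds so the power spectrum of the (wrapped)
#' heading peaks at `dominant_freq`. Saccades are smooth raised-cosine turns
#' of `saccade_amplitude` degrees; their timing follows a gamma renewal
#' process with shape `regularity` (shape 1 gives Poisson timing, larger
#' values the quasi-periodic rhythm of arena flight).
#'
#' The continuous drift carries `drift_fraction` of the net rotation; the
#' saccades carry the rest, so the default saccade rate is
#' `(1 - drift_fraction) * 360 * dominant_freq / saccade_amplitude`
#' (about 2.5 saccades/s at the defaults). Between saccades the heading is
#' nearly constant, as in straight flight segments; most of the rotation is
#' saccadic, which is what arena flight looks like.
#'
#' @param duration Trajectory length, s.
#' @param dominant_freq Net rotation frequency, Hz (default 0.916, the
#'   dominant spectral component of arena flight).
#' @param saccade_rate Mean saccade rate, 1/s; `NULL` derives it from the
#'   rotation budget (see Details).
#' @param saccade_amplitude Saccade size, degrees (default 120).
#' @param saccade_duration Saccade duration, s (default 0.08; stretched if
#'   `max_ang_speed` would be exceeded).
#' @param drift_fraction Fraction of the net rotation carried by smooth
#'   drift (default 0.1).
#' @param regularity Gamma shape of the inter-saccade intervals (default 16;
#'   1 = Poisson timing).
#' @param max_ang_speed Cap on angular speed, degrees/s; saccade duration is
#'   stretched if needed so the peak saccadic speed stays below it.
#' @param dt_traj Sampling interval of the trajectory, s (default 0.01).
#' @param seed RNG seed.
#' @return A data.frame of class `cx_trajectory`: `t` (s), `heading_deg`
#'   (wrapped to `[0, 360)`), `ang_vel_deg_s` (wrapped finite difference /
#'   dt). The unwrapped heading is kept in attribute `unwrapped`.
#' @examples
#' tr <- generate_trajectory(10, seed = 1)
#' dominant_period(tr$heading_deg, dt = 0.01)
#' @export
generate_trajectory <- function(duration = 20, dominant_freq = 0.916,
                                saccade_rate = NULL, saccade_amplitude = 120,
                                saccade_duration = 0.08, drift_fraction = 0.1,
                                regularity = 16, max_ang_speed = 2000,
                                dt_traj = 0.01, seed = NULL) {
  stopifnot(duration > 3 / dominant_freq, saccade_amplitude > 0,
            drift_fraction >= 0, drift_fraction <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  if (is.null(saccade_rate))
    saccade_rate <- (1 - drift_fraction) * 360 * dominant_freq / saccade_amplitude
  drift_speed <- drift_fraction * 360 * dominant_freq
  if (drift_speed > max_ang_speed)
    stop("drift exceeds max_ang_speed")
  # peak raised-cosine speed = A*pi/(2*tau); stretch tau so that saccade
  # plus drift stays below the cap
  tau <- max(saccade_duration,
             saccade_amplitude * pi / (2 * (max_ang_speed - drift_speed)))
  t <- seq(0, duration, by = dt_traj)
  h <- drift_speed * t
  if (saccade_rate > 0) {
    gaps <- stats::rgamma(ceiling(3 + duration * saccade_rate * 2),
                          shape = regularity,
                          rate = regularity * saccade_rate)
    gaps <- pmax(gaps, tau) # saccades may not overlap (speed cap)
    starts <- cumsum(gaps)
    starts <- starts[starts < duration - tau]
    for (s0 in starts) {
      ph <- pmin(pmax((t - s0) / tau, 0), 1)
      h <- h + saccade_amplitude * (1 - cos(pi * ph)) / 2
    }
  }
  vel <- c(diff(h) / dt_traj, 0)
  out <- data.frame(t = t, heading_deg = wrap360(h), ang_vel_deg_s = vel)
  attr(out, "unwrapped") <- h
  attr(out, "dominant_freq") <- dominant_freq
  class(out) <- c("cx_trajectory", "data.frame")
  out
}

#' Import a heading series from CSV
#'
#' Reads a two-column `(t, heading_deg)` file and resamples it to a regular
#' grid by circular (unwrapped linear) interpolation.
#'
#' @param file CSV path with columns `t` and `heading_deg` (or two unnamed
#'   columns in that order).
#' @param dt_traj Output sampling interval, s; `NULL` keeps the native grid.
#' @param max_gap Largest tolerated gap between samples, s.
#' @return A `cx_trajectory` data.frame.
#' @export
import_headings <- function(file, dt_traj = NULL, max_gap = 1) {
  df <- utils::read.csv(file)
  if (!all(c("t", "heading_deg") %in% names(df))) {
    if (ncol(df) < 2) stop("need two columns (t, heading_deg)")
    names(df)[1:2] <- c("t", "heading_deg")
  }
  df <- df[, c("t", "heading_deg")]
  if (is.unsorted(df$t, strictly = TRUE)) stop("non-monotone time column")
  if (any(diff(df$t) > max_gap)) stop("gap in time series exceeds max_gap")
  un <- unwrap_deg(wrap360(df$heading_deg))
  if (!is.null(dt_traj)) {
    t <- seq(min(df$t), max(df$t), by = dt_traj) - min(df$t)
    un <- stats::approx(df$t - min(df$t), un, xout = t)$y
  } else t <- df$t - min(df$t)
  dtm <- stats::median(diff(t))
  out <- data.frame(t = t, heading_deg = wrap360(un),
                    ang_vel_deg_s = c(diff(un) / diff(t), 0))
  attr(out, "unwrapped") <- un
  class(out) <- c("cx_trajectory", "data.frame")
  out
}

#' Write a heading series to CSV
#'
#' @param trajectory A `cx_trajectory` (or data.frame with `t`,
#'   `heading_deg`).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_headings <- function(trajectory, file) {
  utils::write.csv(as.data.frame(trajectory)[, c("t", "heading_deg")],
                   file, row.names = FALSE)
  invisible(file)
}
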