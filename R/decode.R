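#' Unwrap a circular series in degrees
#'
#' Removes 360-degree jumps so consecutive differences lie in (-180, 180].
#'
#' @param x Angles, degrees.
#' @return Unwrapped angles, degrees.
#' @export
unwrap_deg <- function(x) {
  if (length(x) < 2) return(x)
  d <- wrap180(diff(x))
  x[1] + c(0, cumsum(d))
}

#' Population-vector azimuth of the activity bump
#'
#' Circular mean of the octant center angles weighted by the E-PG rates.
#' Undefined (NA with a warning-free flag) when the resultant vector is
#' negligible, e.g. for all-zero or uniform rates.
#'
#' @param rates Vector of 8 octant rates (impulses/s), or a matrix with one
#'   row per time point.
#' @param tol Resultant length below `tol * mean(rates)` counts as undefined.
#' @return Azimuth(s) in degrees in `[0, 360)`; NA where undefined.
#' @examples
#' bump_azimuth(c(10, 0, 0, 0, 0, 0, 0, 0)) # 0 (octant-1 center)
#' @export
bump_azimuth <- function(rates, tol = 1e-6) {
  if (!is.matrix(rates)) rates <- matrix(rates, 1)
  th <- octant_centers(ncol(rates)) * pi / 180
  sx <- rates %*% cos(th)
  sy <- rates %*% sin(th)
  res <- sqrt(sx^2 + sy^2)
  az <- wrap360(atan2(sy, sx) * 180 / pi)
  az[res <= tol * pmax(rowMeans(rates), .Machine$double.eps)] <- NA_real_
  as.numeric(az)
}

#' Full width at half maximum of the bump profile
#'
#' Width of the rate profile at half of (max - min), found by circular
#' linear interpolation between the octant samples on both sides of the
#' peak. Flagged NA for flat profiles with no half-crossing.
#'
#' @param rates Vector of 8 octant rates, or a matrix (rows = time).
#' @return FWHM in degrees; NA where undefined.
#' @examples
#' r <- spatial_profile(0, fwhm = 90, peak_rate = 100, background_rate = 0)
#' bump_fwhm(r) # close to 90
#' @export
bump_fwhm <- function(rates) {
  one <- function(v) {
    n <- length(v)
    half <- min(v) + (max(v) - min(v)) / 2
    if (max(v) - min(v) <= 0) return(NA_real_)
    p <- which.max(v)
    step <- 360 / n
    cross <- function(dir) { # dir = +1 forward, -1 backward
      for (s in seq_len(n - 1)) {
        a <- v[((p - 1 + dir * (s - 1)) %% n) + 1]
        b <- v[((p - 1 + dir * s) %% n) + 1]
        if (a >= half && b < half)
          return(step * (s - 1) + step * (a - half) / (a - b))
      }
      NA_real_
    }
    d1 <- cross(+1L); d2 <- cross(-1L)
    if (is.na(d1) || is.na(d2)) return(NA_real_)
    d1 + d2
  }
  if (is.matrix(rates)) apply(rates, 1, one) else one(rates)
}

#' Decode the bump trace from a simulation
#'
#' Sliding-window E-PG rates are decoded to bump azimuth, width and
#' amplitude over time.
#'
#' @param sim A `cx_sim` from [simulate_network()].
#' @param window Rate smoothing window, s (default 0.05).
#' @param dt_out Decode grid spacing, s.
#' @param epg_units Indices of the E-PG units (default 1:8).
#' @return A data.frame of class `cx_bump_trace`: `t`, `azimuth_deg`,
#'   `fwhm_deg`, `amplitude` (peak E-PG rate, impulses/s).
#' @export
decode_bump <- function(sim, window = 0.05, dt_out = 0.005, epg_units = 1:8) {
  r <- rate_trace(sim, window = window, dt_out = dt_out)
  epg <- r$rate[, epg_units, drop = FALSE]
  out <- data.frame(t = r$t,
                    azimuth_deg = bump_azimuth(epg),
                    fwhm_deg = bump_fwhm(epg),
                    amplitude = apply(epg, 1, max))
  class(out) <- c("cx_bump_trace", "data.frame")
  out
}

#' Export a bump trace as CSV
#'
#' @param trace A `cx_bump_trace`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bump_trace_csv <- function(trace, file) {
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE)
  invisible(file)
}

#' Absolute circular heading error
#'
#' Elementwise absolute wrapped difference between the true heading and the
#' decoded bump azimuth, in `[0, 180]` degrees.
#'
#' @param true_heading True headings, degrees.
#' @param decoded Decoded azimuths, degrees (same length), or a
#'   `cx_bump_trace` whose `azimuth_deg` column is used.
#' @return Vector of absolute errors, degrees; NA where the decode was
#'   undefined.
#' @export
tracking_error <- function(true_heading, decoded) {
  if (inherits(decoded, "cx_bump_trace")) decoded <- decoded$azimuth_deg
  if (length(true_heading) != length(decoded))
    stop("length mismatch between true and decoded headings")
  abs(wrap180(decoded - true_heading))
}

#' Success criterion for a tracking trial
#'
#' A trial succeeds when the decoded heading error is below `threshold`
#' degrees for more than `min_fraction` of the (stimulus-on) samples.
#'
#' @param error Heading error series, degrees (NAs count as failures).
#' @param threshold Error bound, degrees (default 10).
#' @param min_fraction Required fraction of samples under the bound.
#' @return Logical.
#' @export
success_criterion <- function(error, threshold = 10, min_fraction = 0.5) {
  if (!length(error)) stop("empty error series")
  mean(!is.na(error) & error < threshold) > min_fraction
}

#' Tracking lag between true heading and decoded bump
#'
#' Global lag: the shift maximizing the cross-correlation between the
#' demeaned unwrapped true and decoded heading series (sub-sample refinement
#' by parabolic interpolation). Per-frequency lag: cross-spectral phase
#' divided by `2 * pi * f` at the dominant frequency components of the true
#' heading.
#'
#' @param t Common time base, s (regular grid).
#' @param true_heading True headings, degrees.
#' @param decoded Decoded azimuths, degrees (NAs interpolated over).
#' @param max_lag Largest lag searched, s.
#' @param n_freq Number of frequency bands reported.
#' @param bands Optional band edges, Hz (default `n_freq` log-spaced bands
#'   between 0.25 and 8 Hz).
#' @return List of class `cx_lag`: `lag_s` (global lag, s; positive =
#'   decoded trails the heading) and `by_frequency` (data.frame `freq_hz`,
#'   `power`, `phase_rad`, `lag_s`; one row per band).
#' @export
lag_estimate <- function(t, true_heading, decoded, max_lag = 0.5,
                         n_freq = 5L, bands = NULL) {
  stopifnot(length(t) == length(true_heading),
            length(t) == length(decoded), length(t) > 8)
  dt <- stats::median(diff(t))
  if (any(is.na(decoded))) {
    ok <- !is.na(decoded)
    if (sum(ok) < 2) stop("decoded series all-NA")
    decoded <- stats::approx(t[ok], unwrap_deg(decoded[ok]), xout = t,
                             rule = 2)$y
  } else decoded <- unwrap_deg(decoded)
  x <- unwrap_deg(true_heading)
  if (stats::sd(x) < 1e-9) stop("degenerate (constant) heading series")
  # remove the mean and the net-rotation trend: a steady angular drift
  # carries no timing information but dominates the variance of circling
  # trajectories, biasing both the cross-correlation and the spectrum
  detrend <- function(v) stats::residuals(stats::lm.fit(cbind(1, t), v))
  x <- detrend(x); y <- detrend(decoded)
  n <- length(x)
  kmax <- min(n - 2L, max(1L, round(max_lag / dt)))
  cc <- vapply(0:kmax, function(k) {
    xs <- x[1:(n - k)]; ys <- y[(1 + k):n]
    sum(xs * ys) / sqrt(sum(xs^2) * sum(ys^2))
  }, numeric(1))
  k <- which.max(cc) - 1L
  lag <- k * dt
  if (k > 0 && k < kmax) { # parabolic sub-sample refinement
    y0 <- cc[k]; y1 <- cc[k + 1]; y2 <- cc[k + 2]
    den <- y0 - 2 * y1 + y2
    if (abs(den) > 1e-12) lag <- (k + 0.5 * (y0 - y2) / den) * dt
  }
  # cross-spectral phase, power-averaged within frequency bands: individual
  # Fourier bins of a stochastic trajectory are too noisy for a stable
  # per-frequency phase, so the phase is averaged over log-spaced bands
  # weighted by cross-spectral power
  fx <- stats::fft(x); fy <- stats::fft(y)
  nf <- floor(n / 2)
  freq <- (1:nf) / (n * dt)
  cross <- Conj(fy[2:(nf + 1)]) * fx[2:(nf + 1)]
  if (is.null(bands))
    bands <- exp(seq(log(0.25), log(8), length.out = n_freq + 1L))
  bf <- do.call(rbind, lapply(seq_len(length(bands) - 1L), function(b) {
    sel <- freq >= bands[b] & freq < bands[b + 1]
    if (!any(sel)) return(NULL)
    cs <- sum(cross[sel]) # power-weighted circular mean of the phase
    f0 <- sum(freq[sel] * Mod(cross[sel])) / sum(Mod(cross[sel]))
    data.frame(freq_hz = f0, power = sum(Mod(cross[sel])),
               phase_rad = Arg(cs), lag_s = Arg(cs) / (2 * pi * f0))
  }))
  structure(list(lag_s = lag, by_frequency = bf), class = "cx_lag")
}

#' @export
print.cx_lag <- function(x, ...) {
  cat(sprintf("tracking lag: %.1f ms (cross-correlation)\n", 1e3 * x$lag_s))
  print(x$by_frequency, row.names = FALSE)
  invisible(x)
}

#' Dominant period of a heading series
#'
#' Two estimators: the periodogram peak and the first local maximum of the
#' autocovariance beyond lag zero. On clean periodic signals they agree
#' within one spectral bin. Returns NA (flagged) when no peak stands out of
#' the spectral background.
#'
#' @param x Heading series, degrees (wrapped or unwrapped).
#' @param dt Sampling interval, s.
#' @param min_peak_ratio Peak must exceed this multiple of the median
#'   spectral power to count as significant.
#' @return List of class `cx_period`: `period_psd_s`, `period_acov_s`,
#'   `freq_hz`, `significant`.
#' @export
dominant_period <- function(x, dt, min_peak_ratio = 25) {
  stopifnot(length(x) > 16, dt > 0)
  x <- x - mean(x)
  if (stats::sd(x) < 1e-9) stop("flat signal")
  n <- length(x)
  nf <- floor(n / 2)
  pow <- Mod(stats::fft(x)[2:(nf + 1)])^2
  freq <- (1:nf) / (n * dt)
  i <- which.max(pow)
  significant <- pow[i] > min_peak_ratio * stats::median(pow)
  p_psd <- if (significant) 1 / freq[i] else NA_real_
  # autocovariance: first local maximum after the initial decay
  ac <- stats::acf(x, lag.max = min(n - 2, round(3 * max(p_psd, 1, na.rm = TRUE) / dt)),
                   plot = FALSE, demean = TRUE)$acf[, 1, 1]
  p_acov <- NA_real_
  for (k in 2:(length(ac) - 1)) {
    if (ac[k] > ac[k - 1] && ac[k] >= ac[k + 1] && ac[k] > 0) {
      p_acov <- (k - 1) * dt
      break
    }
  }
  structure(list(period_psd_s = p_psd, period_acov_s = p_acov,
                 freq_hz = if (significant) freq[i] else NA_real_,
                 significant = significant),
            class = "cx_period")
}

#' @export
print.cx_period <- function(x, ...) {
  cat(sprintf("dominant period: %.4g s (PSD), %.4g s (autocovariance)%s\n",
              x$period_psd_s, x$period_acov_s,
              if (isTRUE(x$significant)) "" else " [no significant peak]"))
  invisible(x)
}
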