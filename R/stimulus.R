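#' Octant center azimuths
#'
#' Retinotopic convention: azimuth 0 degrees maps to the center of
#' octant/tile 1 and octants advance clockwise in 45 degree steps, so octant
#' `o` is centered at `(o - 1) * 45` degrees.
#'
#' @param n Number of octants (default 8).
#' @return Numeric vector of center azimuths in degrees.
#' @export
octant_centers <- function(n = 8L) (seq_len(n) - 1) * 360 / n

wrap360 <- function(x) x %% 360
wrap180 <- function(x) ((x + 180) %% 360) - 180

# kappa of the von Mises rate profile such that the above-background rate at
# +-fwhm/2 is half the peak's above-background rate, under the scaling that
# maps the profile minimum to the background and the maximum to the peak.
vm_kappa_from_fwhm <- function(fwhm_deg) {
  stopifnot(fwhm_deg > 0, fwhm_deg < 360)
  d <- fwhm_deg / 2 * pi / 180
  f <- function(k) (exp(k * cos(d)) - exp(-k)) / (exp(k) - exp(-k)) - 0.5
  stats::uniroot(f, c(1e-6, 500), tol = 1e-10)$root
}

#' Spatial stimulus profile over the eight octants
#'
#' Von Mises shaped firing-rate profile centered on the stimulus azimuth,
#' scaled so its minimum equals the background rate, its maximum the peak
#' rate, and its full width at half maximum (of the above-background rate)
#' equals `fwhm`; sampled at the eight octant centers.
#'
#' @param azimuth Stimulus azimuth, degrees.
#' @param fwhm Full width at half maximum, degrees (default 90).
#' @param peak_rate Rate at the stimulus azimuth, impulses/s.
#' @param background_rate Baseline rate, impulses/s (default 5).
#' @param n Number of octants.
#' @return Numeric vector of `n` rates (impulses/s).
#' @examples
#' r <- spatial_profile(0)
#' which.max(r) # octant 1
#' @export
spatial_profile <- function(azimuth, fwhm = 90, peak_rate = 380,
                            background_rate = 5, n = 8L) {
  kap <- vm_kappa_from_fwhm(fwhm)
  th <- (octant_centers(n) - azimuth) * pi / 180
  s <- (exp(kap * cos(th)) - exp(-kap)) / (exp(kap) - exp(-kap))
  background_rate + (peak_rate - background_rate) * s
}

#' Convert octant rates to Poisson spike trains
#'
#' Independent Poisson processes at the given rates, discretized at the
#' simulation step: per-step spike counts are drawn from
#' `Poisson(rate * dt)`.
#'
#' @param rates Either a vector of per-unit rates (impulses/s), constant in
#'   time, or a `n_steps x n_units` matrix of time-varying rates.
#' @param duration Duration, s (ignored when `rates` is a matrix with
#'   `n_steps` rows and `n_steps` is derived from it).
#' @param dt Time step, s.
#' @param seed Optional RNG seed for reproducibility.
#' @return Integer matrix of per-step spike counts (`n_steps x n_units`).
#' @export
poisson_encode <- function(rates, duration = NULL, dt = 1e-4, seed = NULL) {
  if (!is.matrix(rates)) {
    stopifnot(!is.null(duration))
    n_steps <- round(duration / dt)
    rates <- matrix(rates, n_steps, length(rates), byrow = TRUE)
  }
  if (any(rates < 0)) stop("negative rate")
  lam <- rates * dt
  if (any(lam > 1)) stop("rate * dt > 1: undersampled, decrease dt")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  matrix(stats::rpois(length(lam), lam), nrow(rates), ncol(rates))
}

new_protocol <- function(segments, fwhm, background_rate, peak_rate,
                         type = "step", headings = NULL) {
  p <- list(segments = segments, fwhm = fwhm,
            background_rate = background_rate, peak_rate = peak_rate,
            type = type, headings = headings,
            duration = max(segments$t_end))
  class(p) <- "cx_protocol"
  p
}

#' Two-step heading stimulus protocol
#'
#' The step paradigm: darkness, a stimulus at heading `h1`, darkness, a
#' stimulus at heading `h2`, darkness. With `h2 - h1 = 180` degrees this is
#' the abrupt half-turn protocol used to test attractor-state relocation.
#'
#' @param h1,h2 Stimulus azimuths, degrees.
#' @param t_stim Duration of each stimulus epoch, s.
#' @param t_dark Duration of each darkness epoch following a stimulus, s.
#' @param t_pre Leading darkness, s.
#' @param fwhm Spatial profile width, degrees.
#' @param background_rate Darkness/background rate, impulses/s.
#' @param peak_rate Peak stimulus rate, impulses/s. The default matches the
#'   peak E-PG population rate of the reference optimized circuit.
#' @return A `cx_protocol` object; its `segments` data.frame has columns
#'   `t_start`, `t_end`, `azimuth` (NA during darkness).
#' @examples
#' p <- step_protocol(0, 180)
#' p$segments
#' @export
step_protocol <- function(h1 = 0, h2 = 180, t_stim = 0.5, t_dark = 1,
                          t_pre = 0.5, fwhm = 90, background_rate = 5,
                          peak_rate = 380) {
  stopifnot(t_stim > 0, t_dark >= 0, t_pre >= 0)
  b <- cumsum(c(0, t_pre, t_stim, t_dark, t_stim, t_dark))
  seg <- data.frame(t_start = b[-length(b)], t_end = b[-1],
                    azimuth = c(NA, wrap360(h1), NA, wrap360(h2), NA))
  seg <- seg[seg$t_end > seg$t_start, ]
  rownames(seg) <- NULL
  new_protocol(seg, fwhm, background_rate, peak_rate, type = "step")
}

#' Protocol replaying a heading time series
#'
#' Piecewise-constant azimuth at simulation resolution, for driving the
#' circuit with a (synthetic or imported) trajectory.
#'
#' @param headings A `cx_trajectory` (see [generate_trajectory()]) or a
#'   data.frame with columns `t` (s) and `heading_deg`.
#' @param fwhm,background_rate,peak_rate As in [step_protocol()].
#' @return A `cx_protocol` of type `"trajectory"`.
#' @export
trajectory_protocol <- function(headings, fwhm = 90, background_rate = 5,
                                peak_rate = 380) {
  df <- as.data.frame(headings)[, c("t", "heading_deg")]
  stopifnot(nrow(df) >= 2, all(is.finite(df$t)), all(is.finite(df$heading_deg)),
            !is.unsorted(df$t))
  df$heading_deg <- wrap360(df$heading_deg)
  seg <- data.frame(t_start = 0, t_end = max(df$t), azimuth = NA)
  new_protocol(seg, fwhm, background_rate, peak_rate,
               type = "trajectory", headings = df)
}

#' Azimuth of a protocol at given times
#'
#' @param protocol A `cx_protocol`.
#' @param t Times, s.
#' @return Azimuths in degrees; NA during darkness.
#' @export
protocol_azimuth <- function(protocol, t) {
  if (protocol$type == "trajectory") {
    h <- protocol$headings
    un <- unwrap_deg(h$heading_deg)
    wrap360(stats::approx(h$t, un, xout = pmin(pmax(t, min(h$t)), max(h$t)),
                          rule = 2)$y)
  } else {
    seg <- protocol$segments
    i <- findInterval(pmin(t, protocol$duration - 1e-12), seg$t_start)
    i[i < 1] <- 1L
    seg$azimuth[i]
  }
}

#' Encode a stimulus protocol into E-PG input spike trains
#'
#' Maps the protocol's azimuth timeline through the von Mises spatial
#' profile to per-octant rates (background everywhere during darkness) and
#' draws Poisson spike trains at the simulation step. The resulting object
#' plugs into [simulate_network()].
#'
#' @param protocol A `cx_protocol`.
#' @param dt Simulation step, s.
#' @param seed RNG seed for the Poisson draw.
#' @param stim_units Indices of the stimulated units (default 1:8, the E-PG
#'   units in the standard ordering of [connectivity_matrix()]).
#' @return List of class `cx_stimulus`: `spikes` (steps x 8 integer matrix),
#'   `units`, `rates` (steps x 8), `dt`, `duration`, `protocol`.
#' @export
encode_protocol <- function(protocol, dt = 1e-4, seed = NULL,
                            stim_units = 1:8) {
  n_steps <- round(protocol$duration / dt)
  t <- (seq_len(n_steps) - 1) * dt
  az <- protocol_azimuth(protocol, t)
  n <- length(stim_units)
  rates <- matrix(protocol$background_rate, n_steps, n)
  on <- !is.na(az)
  if (any(on)) {
    kap <- vm_kappa_from_fwhm(protocol$fwhm)
    centers <- octant_centers(n)
    s <- exp(-kap) # precomputable pieces of the scaled von Mises
    for (o in seq_len(n)) {
      co <- cos((centers[o] - az[on]) * pi / 180)
      prof <- (exp(kap * co) - s) / (exp(kap) - s)
      rates[on, o] <- protocol$background_rate +
        (protocol$peak_rate - protocol$background_rate) * prof
    }
  }
  spikes <- poisson_encode(rates, dt = dt, seed = seed)
  structure(list(spikes = spikes, units = stim_units, rates = rates,
                 dt = dt, duration = protocol$duration, protocol = protocol),
            class = "cx_stimulus")
}

#' Read or write a protocol as YAML
#'
#' Step-type protocols serialize their segment table and encoding
#' parameters; trajectory protocols serialize the heading series.
#'
#' @param protocol A `cx_protocol`.
#' @param file Path to a YAML file.
#' @return `write_protocol_yaml` returns `file` invisibly;
#'   `read_protocol_yaml` returns a `cx_protocol`.
#' @export
write_protocol_yaml <- function(protocol, file) {
  x <- list(type = protocol$type, fwhm = protocol$fwhm,
            background_rate = protocol$background_rate,
            peak_rate = protocol$peak_rate)
  if (protocol$type == "trajectory") {
    x$t <- protocol$headings$t
    x$heading_deg <- protocol$headings$heading_deg
  } else {
    x$segments <- lapply(seq_len(nrow(protocol$segments)), function(i)
      as.list(protocol$segments[i, ]))
  }
  yaml::write_yaml(x, file)
  invisible(file)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(file) {
  x <- yaml::read_yaml(file)
  if (identical(x$type, "trajectory")) {
    trajectory_protocol(data.frame(t = x$t, heading_deg = x$heading_deg),
                        fwhm = x$fwhm, background_rate = x$background_rate,
                        peak_rate = x$peak_rate)
  } else {
    seg <- do.call(rbind, lapply(x$segments, function(s)
      data.frame(t_start = s$t_start, t_end = s$t_end,
                 azimuth = if (is.null(s$azimuth) || is.na(s$azimuth))
                   NA_real_ else s$azimuth)))
    new_protocol(seg, x$fwhm, x$background_rate, x$peak_rate, type = "step")
  }
}
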