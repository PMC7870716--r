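#' Simulate the spiking network
#'
#' Drives all units of the circuit through the connectivity matrix with
#' leaky integrate-and-fire dynamics (forward Euler at step `dt`), inserting
#' the stereotyped action-potential template on threshold crossing and
#' accumulating the postsynaptic-current kernel of every spike, scaled by
#' the signed synaptic weight, into its targets. External heading input
#' arrives as spike trains fed through the same unit kernel (see
#' [encode_protocol()]); a constant per-unit current injection is also
#' supported.
#'
#' The simulation is fully deterministic given its inputs; all randomness
#' lives in the stimulus encoding.
#'
#' @param M Square connectivity matrix, `M[j, i]` the signed weight of the
#'   edge from unit j to unit i (in `i_psc` unit equivalents per action
#'   potential), e.g. from [connectivity_matrix()].
#' @param stimulus Either `NULL`, or an encoded stimulus from
#'   [encode_protocol()], or a list with `spikes` (integer matrix, steps x
#'   stimulated units) and `units` (column-to-unit index map).
#' @param duration Simulated time, s. Defaults to the stimulus duration.
#' @param dt Time step, s (default `1e-4`).
#' @param params A [cx_neuron_params()] object, or a list of per-unit
#'   parameter vectors via `c_m`/`r_m` overrides (see `c_m`, `r_m`).
#' @param i_ext Constant external current per unit, nA (scalar or length-N).
#' @param c_m,r_m Optional per-unit capacitance (nF) / resistance (MOhm)
#'   vectors overriding `params` (used by the heterogeneity experiments).
#' @param record_v Record membrane traces (subsampled by `record_every`)?
#' @param record_every Subsampling stride for voltage recording.
#' @return An object of class `cx_sim`: list with `spikes` (data.frame
#'   `time`, `unit`), `unit_labels`, `n_units`, `dt`, `duration`, `n_steps`,
#'   optional `v` matrix and `v_t` times, and the `params` used.
#' @examples
#' p <- cx_neuron_params()
#' M <- matrix(0, 1, 1)
#' sim <- simulate_network(M, NULL, duration = 0.2, i_ext = 1.5)
#' nrow(sim$spikes) # periodic spiking under suprathreshold drive
#' @export
simulate_network <- function(M, stimulus = NULL, duration = NULL, dt = 1e-4,
                             params = cx_neuron_params(), i_ext = 0,
                             c_m = NULL, r_m = NULL,
                             record_v = FALSE, record_every = 10L) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), dt > 0)
  n <- nrow(M)
  if (is.null(duration)) {
    if (is.null(stimulus)) stop("duration required without a stimulus")
    duration <- stimulus$duration
  }
  n_steps <- round(duration / dt)
  if (is.null(stimulus)) {
    sp <- matrix(0L, 0, 0)
    su <- integer(0)
  } else {
    sp <- stimulus$spikes
    su <- as.integer(stimulus$units)
    if (!is.null(stimulus$dt) && abs(stimulus$dt - dt) > 1e-12)
      stop("stimulus was encoded at a different dt")
    if (nrow(sp) < n_steps) stop("stimulus shorter than simulation")
    if (any(su < 1 | su > n)) stop("stimulus unit index out of range")
  }
  # Negative values are tolerated: heterogeneity experiments may flip the
  # sign of a neuron's conductance or capacitance, which disables that
  # neuron but must not abort the network simulation.
  cmv <- rep_len(if (is.null(c_m)) params$c_m else c_m, n)
  rmv <- rep_len(if (is.null(r_m)) params$r_m else r_m, n)
  if (any(!is.finite(cmv)) || any(cmv == 0) || any(!is.finite(rmv)) || any(rmv == 0))
    stop("invalid membrane parameters")
  tpl <- as.numeric(ap_template(params, dt))
  ker <- as.numeric(psc_kernel(params, dt))
  res <- simulate_lif_cpp(M, sp, su, rep_len(as.numeric(i_ext), n),
                          cmv, rmv, params$v_0, params$v_thr, tpl, ker,
                          dt * 1e3, n_steps, record_v, as.integer(record_every))
  steps <- res$spike_steps
  counts <- lengths(steps)
  spikes <- data.frame(time = unlist(steps, use.names = FALSE) * dt,
                       unit = rep.int(seq_len(n), counts))
  labs <- rownames(M)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  out <- list(spikes = spikes, unit_labels = labs, n_units = n, dt = dt,
              duration = duration, n_steps = n_steps, params = params)
  if (record_v) {
    out$v <- res$v
    colnames(out$v) <- labs
    out$v_t <- (seq_len(nrow(res$v)) - 1L) * record_every * dt
  }
  class(out) <- "cx_sim"
  out
}

#' @export
print.cx_sim <- function(x, ...) {
  cat(sprintf("cx_sim: %d units, %.3g s at dt = %g s, %d spikes\n",
              x$n_units, x$duration, x$dt, nrow(x$spikes)))
  invisible(x)
}

#' Smoothed firing-rate traces from a spike raster
#'
#' Causal boxcar rate: for each unit, the number of spikes in `(t - window,
#' t]` divided by `window`, in impulses/s, evaluated on a regular grid.
#'
#' @param sim A `cx_sim` object, or a data.frame with `time` and `unit`.
#' @param window Smoothing window, s (default 0.05).
#' @param dt_out Output grid spacing, s (default 0.005).
#' @param n_units Number of units (required when `sim` is a raw data.frame).
#' @param t_end End of the time base (defaults to the simulation duration).
#' @return A list of class `cx_rates`: `t` (grid, s) and `rate`
#'   (length(t) x n_units matrix, impulses/s).
#' @export
rate_trace <- function(sim, window = 0.05, dt_out = 0.005, n_units = NULL,
                       t_end = NULL) {
  stopifnot(window > 0, dt_out > 0)
  if (inherits(sim, "cx_sim")) {
    spikes <- sim$spikes
    n_units <- sim$n_units
    if (is.null(t_end)) t_end <- sim$duration
    labs <- sim$unit_labels
  } else {
    spikes <- sim
    if (is.null(n_units)) stop("n_units required")
    if (is.null(t_end)) t_end <- if (nrow(spikes)) max(spikes$time) else window
    labs <- as.character(seq_len(n_units))
  }
  t <- seq(0, t_end, by = dt_out)
  rate <- matrix(0, length(t), n_units, dimnames = list(NULL, labs))
  if (nrow(spikes)) {
    for (u in unique(spikes$unit)) {
      st <- sort(spikes$time[spikes$unit == u])
      # counts in (t - window, t]
      rate[, u] <- (findInterval(t, st, left.open = FALSE) -
                      findInterval(t - window, st, left.open = FALSE)) / window
    }
  }
  structure(list(t = t, rate = rate, window = window), class = "cx_rates")
}

#' Export a spike raster as CSV
#'
#' Writes `(time_s, unit_label)` rows.
#'
#' @param sim A `cx_sim` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_raster_csv <- function(sim, file) {
  df <- data.frame(time_s = sim$spikes$time,
                   unit_label = sim$unit_labels[sim$spikes$unit])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
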