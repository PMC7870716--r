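#' Leaky integrate-and-fire neuron parameters
#'
#' Shared biophysical constants of the model neurons. All neurons in the
#' circuit use the same nominal values, consistent with intracellular
#' measurements in *Drosophila melanogaster*: a 20 ms membrane time constant
#' (`r_m * c_m`), a 7 mV distance from rest to threshold, a stereotyped 2 ms
#' action potential and a postsynaptic current of 5 nA peak decaying with a
#' 5 ms half-life.
#'
#' Units are millivolts (potentials), nanofarads (`c_m`), megaohms (`r_m`),
#' nanoamperes (currents) and seconds (durations). With this unit system
#' `r_m * c_m` is in milliseconds.
#'
#' @param c_m Membrane capacitance, nF.
#' @param r_m Membrane resistance, MOhm.
#' @param v_0 Resting potential, mV.
#' @param v_thr Action potential threshold, mV.
#' @param v_max Action potential peak, mV.
#' @param v_min Post-spike undershoot, mV.
#' @param t_ap Action potential duration, s.
#' @param i_psc Postsynaptic current peak magnitude, nA.
#' @param t_psc Postsynaptic current decay half-life, s.
#' @return An object of class `cx_neuron_params` (a named list).
#' @examples
#' p <- cx_neuron_params()
#' p$r_m * p$c_m # membrane time constant, ms
#' @export
cx_neuron_params <- function(c_m = 2, r_m = 10, v_0 = -52, v_thr = -45,
                             v_max = 20, v_min = -72, t_ap = 2e-3,
                             i_psc = 5, t_psc = 5e-3) {
  p <- list(c_m = c_m, r_m = r_m, v_0 = v_0, v_thr = v_thr, v_max = v_max,
            v_min = v_min, t_ap = t_ap, i_psc = i_psc, t_psc = t_psc)
  stopifnot(p$v_min < p$v_0, p$v_0 < p$v_thr, p$v_thr < p$v_max,
            p$t_ap > 0, p$t_psc > 0, p$c_m > 0, p$r_m > 0)
  class(p) <- "cx_neuron_params"
  p
}

#' @export
print.cx_neuron_params <- function(x, ...) {
  cat("LIF neuron parameters:\n")
  cat(sprintf("  C_m = %g nF, R_m = %g MOhm (tau = %g ms)\n",
              x$c_m, x$r_m, x$c_m * x$r_m))
  cat(sprintf("  V_0 = %g mV, V_thr = %g mV, V_max = %g mV, V_min = %g mV\n",
              x$v_0, x$v_thr, x$v_max, x$v_min))
  cat(sprintf("  t_AP = %g ms, I_PSC = %g nA, t_PSC = %g ms\n",
              1e3 * x$t_ap, x$i_psc, 1e3 * x$t_psc))
  invisible(x)
}

#' One forward-Euler step of the membrane equation
#'
#' Advances the subthreshold membrane potential
#' `dV/dt = ((V_0 - V)/R_m + I_ext + I_syn) / C_m`
#' by one step of size `dt`. This is the integration rule used (in compiled
#' form) by [simulate_network()]; it is exposed for inspection and testing.
#'
#' @param v Membrane potential(s), mV. Vectorized.
#' @param i_ext External input current, nA.
#' @param i_syn Synaptic input current, nA.
#' @param params A [cx_neuron_params()] object.
#' @param dt Time step, s. May also be a vector matching `v`.
#' @return Updated membrane potential(s), mV.
#' @examples
#' p <- cx_neuron_params()
#' membrane_step(p$v_0, 0, 0, p, 1e-4) # equilibrium: unchanged
#' @export
membrane_step <- function(v, i_ext, i_syn, params = cx_neuron_params(),
                          dt = 1e-4) {
  if (!all(is.finite(v)) || !all(is.finite(i_ext)) || !all(is.finite(i_syn)))
    stop("membrane_step: non-finite input")
  stopifnot(all(dt > 0))
  dt_ms <- dt * 1e3
  v + dt_ms / params$c_m * ((params$v_0 - v) / params$r_m + i_ext + i_syn)
}

#' Stereotyped action-potential template
#'
#' The voltage waveform inserted into the membrane trace when threshold is
#' crossed. The first half rises from `v_thr` to `v_max` following a Gaussian
#' bell centered on the midpoint (sd `t_ap/2`); the second half falls from
#' `v_max` to `v_min` along a half-sinusoid (phase pi/2 to 3*pi/2). Each
#' segment's raw shape is affinely rescaled to span exactly \[0, 1\] over its
#' own support, so the template starts at `v_thr`, peaks at `v_max` at
#' `t_ap/2` and ends at `v_min`. While a template is active no further
#' threshold crossings are honored, producing an absolute refractory period
#' of `t_ap`.
#'
#' @inheritParams membrane_step
#' @return Numeric vector of voltages (mV) sampled at `0, dt, ..., t_ap`,
#'   with attribute `t` holding the sample times in seconds.
#' @examples
#' tpl <- ap_template(dt = 1e-4)
#' range(tpl) # c(v_min, v_max)
#' @export
ap_template <- function(params = cx_neuron_params(), dt = 1e-4) {
  stopifnot(dt > 0)
  n_half <- round(params$t_ap / 2 / dt)
  if (n_half < 5) stop("ap_template: dt too coarse for t_ap (need >= 10 samples)")
  t <- seq(0, 2 * n_half) * dt
  half <- params$t_ap / 2
  rise_t <- t[t < half]
  g <- exp(-(rise_t - half)^2 / (2 * half^2))
  g01 <- (g - g[1]) / (exp(0) - g[1]) # rescale [g(0), g(half)] -> [0, 1]
  v_rise <- params$v_thr + (params$v_max - params$v_thr) * g01
  fall_t <- t[t >= half]
  s <- sin((fall_t - half) * 2 * pi / params$t_ap + pi / 2)
  s01 <- (s + 1) / 2 # sin in [-1, 1] -> [0, 1]
  v_fall <- params$v_min + (params$v_max - params$v_min) * s01
  out <- c(v_rise, v_fall)
  attr(out, "t") <- t
  class(out) <- c("cx_ap_template", class(out))
  out
}

#' Postsynaptic current kernel
#'
#' The current waveform a single presynaptic action potential injects into a
#' postsynaptic neuron: a half-sinusoid rise from 0 to `i_psc` over 2 ms,
#' followed by a base-2 exponential decay with half-life `t_psc` truncated at
#' `7 * t_psc`. Total duration `2 ms + 7 * t_psc` (37 ms at nominal
#' parameters). Inhibitory synapses use the exact negation; in the network
#' the kernel is scaled by the signed synaptic weight, expressed in `i_psc`
#' unit equivalents per action potential.
#'
#' @inheritParams membrane_step
#' @return Numeric vector of currents (nA) sampled at
#'   `0, dt, ..., 2e-3 + 7 * t_psc`, with attribute `t` (seconds).
#' @examples
#' k <- psc_kernel(dt = 1e-4)
#' max(k) # 5 nA at t = 2 ms
#' @export
psc_kernel <- function(params = cx_neuron_params(), dt = 1e-4) {
  stopifnot(dt > 0)
  t_rise <- 2e-3
  dur <- t_rise + 7 * params$t_psc
  t <- seq(0, round(dur / dt)) * dt
  k <- numeric(length(t))
  rise <- t < t_rise
  # sin(pi * t / t_rise - pi/2) spans [-1, 1]; rescaled to [0, 1]
  k[rise] <- params$i_psc * (sin(pi * t[rise] / t_rise - pi / 2) + 1) / 2
  k[!rise] <- params$i_psc * 2^(-(t[!rise] - t_rise) / params$t_psc)
  out <- k
  attr(out, "t") <- t
  class(out) <- c("cx_psc_kernel", class(out))
  out
}

#' Export a sampled waveform as a two-column CSV
#'
#' Writes `(t, value)` rows for an [ap_template()] or [psc_kernel()] (or any
#' numeric vector carrying a `t` attribute).
#'
#' @param x Waveform vector with a `t` attribute (seconds).
#' @param file Output path.
#' @param value_name Column name for the sampled values.
#' @return `file`, invisibly.
#' @export
write_waveform_csv <- function(x, file, value_name = "value") {
  t <- attr(x, "t")
  stopifnot(!is.null(t), length(t) == length(x))
  df <- data.frame(t = t, value = as.numeric(x))
  names(df)[2] <- value_name
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read and write neuron parameters as YAML
#'
#' @param params A [cx_neuron_params()] object.
#' @param file Path to a YAML file.
#' @return `write_neuron_params_yaml` returns `file` invisibly;
#'   `read_neuron_params_yaml` returns a [cx_neuron_params()] object.
#' @export
write_neuron_params_yaml <- function(params, file) {
  yaml::write_yaml(unclass(params), file)
  invisible(file)
}

#' @rdname write_neuron_params_yaml
#' @export
read_neuron_params_yaml <- function(file) {
  do.call(cx_neuron_params, yaml::read_yaml(file))
}
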