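#' Quenched multiplicative Gaussian perturbation
#'
#' Applies `v_i = v_nominal + (x/100) * v_nominal * eps_i` with
#' `eps_i ~ N(0, 1)` i.i.d. — white Gaussian noise scaled to `x` percent of
#' each nominal value. At large `x` a value may flip sign; this is permitted
#' and is part of the model of heterogeneity.
#'
#' @param nominal Numeric vector (or matrix) of nominal values.
#' @param x Noise level, percent of nominal.
#' @param seed Optional RNG seed.
#' @return Perturbed values, same shape as `nominal`.
#' @examples
#' sd(perturb(rep(1, 1e4), 50, seed = 1)) # about 0.5
#' @export
perturb <- function(nominal, x, seed = NULL) {
  stopifnot(all(is.finite(nominal)), x >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  nominal + (x / 100) * nominal * stats::rnorm(length(nominal))
}

# Entries of M belonging to one tied weight class ("w1".."w5") or to one
# edge class ("E-PG->Delta7", "P-EN->E-PG", ...).
weight_class_mask <- function(circuit, class_name) {
  wmap <- weight_class_map()
  cls <- stats::setNames(circuit$units$class, circuit$units$unit)
  ek <- paste0(cls[circuit$edges$pre], "->", cls[circuit$edges$post])
  keep <- if (class_name %in% names(wmap)) ek == class_name
          else wmap[ek] == class_name
  sel <- circuit$edges[keep, ]
  cbind(sel$pre, sel$post)
}

# One tracking trial: simulate the protocol, decode, evaluate the success
# criterion on the stimulus-on epochs. Never throws: a crashed simulation
# counts as a failed trial.
one_tracking_trial <- function(M, protocol, seed, dt = 1e-4,
                               c_m = NULL, r_m = NULL, window = 0.05,
                               dt_out = 0.01, warmup = NULL) {
  if (is.null(warmup)) warmup <- window
  res <- tryCatch({
    sim <- simulate_protocol(M, protocol, dt = dt, seed = seed,
                             c_m = c_m, r_m = r_m)
    bt <- decode_bump(sim, window = window, dt_out = dt_out)
    az <- protocol_azimuth(protocol, bt$t)
    on <- !is.na(az) & bt$t >= warmup
    err <- tracking_error(az[on], bt$azimuth_deg[on])
    list(success = success_criterion(err),
         mean_error = mean(err, na.rm = TRUE),
         frac_below = mean(!is.na(err) & err < 10), t = bt$t[on], error = err)
  }, error = function(e) list(success = FALSE, mean_error = NA_real_,
                              frac_below = 0, error = NULL,
                              message = conditionMessage(e)))
  res
}

#' Noise-sensitivity sweep
#'
#' For each perturbation target and noise level `x`, runs `n_trials`
#' independent tracking trials: parameters are perturbed once per trial
#' (quenched heterogeneity, [perturb()]), the circuit is driven by the
#' protocol (by default a seeded synthetic fly trajectory), the bump is
#' decoded, and the trial is scored by [success_criterion()] (error under 10
#' degrees for over half of the stimulated duration). Per-trial seeds are
#' derived deterministically from `base_seed`; a crashed trial is recorded
#' as a failure, not an error.
#'
#' Targets: `"weights"` (all synaptic weights, per matrix entry), `"w1"` ..
#' `"w5"` (one tied class), an edge class such as `"E-PG->P-EN"` or
#' `"E-PG->Delta7"` (the Delta7 input synapses), `"conductance"` (per-neuron
#' membrane conductance `1/R_m`), `"capacitance"` (per-neuron `C_m`).
#'
#' @param targets Character vector of perturbation targets.
#' @param x_levels Noise levels, percent of nominal (default 0-100 by 10).
#' @param n_trials Trials per condition (default 20).
#' @param weights Nominal weights (default [cx_reference_weights()]).
#' @param circuit A `cx_circuit`.
#' @param protocol A `cx_protocol`; default is a trajectory protocol built
#'   from [generate_trajectory()] with `traj_duration` seconds, seeded from
#'   `base_seed` (the same trajectory is used for every condition).
#' @param base_seed Master seed.
#' @param traj_duration Duration of the default trajectory, s.
#' @param peak_rate Stimulus peak rate, impulses/s.
#' @param params Neuron parameters.
#' @param dt Simulation step, s.
#' @return A data.frame of class `cx_sweep`: `target`, `x`, `n_trials`,
#'   `n_success`, `success_fraction`.
#' @export
run_sweep <- function(targets = "weights", x_levels = seq(0, 100, by = 10),
                      n_trials = 20, weights = cx_reference_weights(),
                      circuit = cx_circuit(), protocol = NULL, base_seed = 1L,
                      traj_duration = 10, peak_rate = 380,
                      params = cx_neuron_params(), dt = 1e-4) {
  stopifnot(n_trials >= 1, all(x_levels >= 0))
  known <- c("weights", paste0("w", 1:5), names(weight_class_map()),
             "conductance", "capacitance")
  if (!all(targets %in% known))
    stop("unknown target(s): ", paste(setdiff(targets, known), collapse = ", "))
  if (is.null(protocol)) {
    tr <- generate_trajectory(duration = traj_duration,
                              seed = (base_seed + 101L) %% .Machine$integer.max)
    protocol <- trajectory_protocol(tr, peak_rate = peak_rate)
  }
  M0 <- connectivity_matrix(circuit, weights)
  n <- nrow(M0)
  rows <- list()
  cond <- 0L
  for (target in targets) {
    mask <- if (target %in% c(paste0("w", 1:5), names(weight_class_map())))
      weight_class_mask(circuit, target) else NULL
    for (x in x_levels) {
      cond <- cond + 1L
      succ <- 0L
      for (tr_i in seq_len(n_trials)) {
        seed_t <- (base_seed + 7919L * cond + tr_i) %% .Machine$integer.max
        M <- M0
        cmv <- rmv <- NULL
        if (x > 0) {
          if (target == "weights") {
            nz <- M != 0
            M[nz] <- perturb(M0[nz], x, seed = seed_t)
          } else if (!is.null(mask)) {
            M[mask] <- perturb(M0[mask], x, seed = seed_t)
          } else if (target == "conductance") {
            g <- perturb(rep(1 / params$r_m, n), x, seed = seed_t)
            rmv <- 1 / g
          } else if (target == "capacitance") {
            cmv <- perturb(rep(params$c_m, n), x, seed = seed_t)
          }
        }
        out <- one_tracking_trial(M, protocol, seed = seed_t + 500000L,
                                  dt = dt, c_m = cmv, r_m = rmv)
        succ <- succ + as.integer(isTRUE(out$success))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        target = target, x = x, n_trials = n_trials, n_success = succ,
        success_fraction = succ / n_trials)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "base_seed") <- base_seed
  class(out) <- c("cx_sweep", "data.frame")
  out
}

#' Export a sweep result as CSV
#'
#' @param sweep A `cx_sweep` data.frame.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_sweep_csv <- function(sweep, file) {
  utils::write.csv(as.data.frame(sweep), file, row.names = FALSE)
  invisible(file)
}
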