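#' Simulate a stimulus protocol on a circuit
#'
#' Convenience wrapper: encode the protocol (seeded), run the network, and
#' return the simulation.
#'
#' @param M Connectivity matrix from [connectivity_matrix()] (or a circuit,
#'   in which case `weights` must be given).
#' @param protocol A `cx_protocol`.
#' @param weights Optional [cx_weights()] when `M` is a `cx_circuit`.
#' @param dt Time step, s.
#' @param seed Seed for the stimulus encoding.
#' @param ... Passed to [simulate_network()] (e.g. `c_m`, `r_m`,
#'   `record_v`).
#' @return A `cx_sim`.
#' @export
simulate_protocol <- function(M, protocol, weights = NULL, dt = 1e-4,
                              seed = NULL, ...) {
  if (inherits(M, "cx_circuit")) {
    if (is.null(weights)) stop("weights required with a circuit")
    M <- connectivity_matrix(M, weights)
  }
  stim <- encode_protocol(protocol, dt = dt, seed = seed)
  simulate_network(M, stim, duration = protocol$duration, dt = dt, ...)
}

weight_bounds <- function() {
  list(lower = c(w1 = 0, w2 = 0, w3 = 0, w4 = -100, w5 = -100),
       upper = c(w1 = 100, w2 = 100, w3 = 100, w4 = 0, w5 = 0))
}

#' Ring-attractor objective function
#'
#' Scores a weight vector by simulating the two-step protocol (stimulus at
#' heading A, darkness, stimulus at A + 180 degrees, darkness) and measuring
#' the bump on the time-averaged E-PG rate profile over the final
#' `t_measure` seconds before each darkness end (checkpoints t1, t2):
#'
#' `score = 4 (eH1 + eH2) + eW1 + eW2 + N p0`
#'
#' with heading errors `eH = |H_d - H_a| / 360`, width errors
#' `eW = |90 - W_a| / 360`, and the small-weight penalty
#' `p0 = mean(exp(-2 |w_i|))`, `N = 5`. A missing bump (undefined azimuth)
#' scores the worst-case `eH = 0.5` and `eW = 0.75`.
#'
#' @param weights A [cx_weights()] vector (or plain numeric of length 5).
#' @param circuit A `cx_circuit` (defaults to the fly circuit).
#' @param h1,h2 Stimulus headings, degrees.
#' @param t_stim,t_dark Protocol epoch durations, s.
#' @param t_measure Averaging window before each checkpoint, s.
#' @param peak_rate Stimulus peak rate, impulses/s.
#' @param dt Simulation step, s.
#' @param seed Stimulus-encoding seed.
#' @param n_rep Number of independent stimulus encodings averaged per
#'   evaluation (seeds `seed, seed + 1, ...`). Averaging over a few draws
#'   penalizes weight sets whose attractor behavior holds only under a
#'   particular noise realization.
#' @return List of class `cx_objective`: `score`, `eps_h1`, `eps_h2`,
#'   `eps_w1`, `eps_w2`, `p0`, `h_a`, `w_a`, `checkpoints` (component
#'   averages across repetitions).
#' @export
ring_objective <- function(weights, circuit = cx_circuit(), h1 = 0, h2 = 180,
                           t_stim = 0.5, t_dark = 1, t_measure = 0.25,
                           peak_rate = 380, dt = 1e-4, seed = 1L, n_rep = 1L) {
  if (n_rep > 1) {
    reps <- lapply(seq_len(n_rep) - 1L, function(k)
      ring_objective(weights, circuit = circuit, h1 = h1, h2 = h2,
                     t_stim = t_stim, t_dark = t_dark, t_measure = t_measure,
                     peak_rate = peak_rate, dt = dt, seed = seed + k,
                     n_rep = 1L))
    avg <- function(f) mean(vapply(reps, `[[`, numeric(1), f))
    avg2 <- function(f) { # circular for azimuths, plain for widths
      m <- do.call(rbind, lapply(reps, `[[`, f))
      if (f == "h_a") apply(m, 2, mean_circ_deg) else colMeans(m)
    }
    out <- list(score = avg("score"), eps_h1 = avg("eps_h1"),
                eps_h2 = avg("eps_h2"), eps_w1 = avg("eps_w1"),
                eps_w2 = avg("eps_w2"), p0 = reps[[1]]$p0,
                h_a = avg2("h_a"), w_a = avg2("w_a"),
                checkpoints = reps[[1]]$checkpoints)
    class(out) <- "cx_objective"
    return(out)
  }
  w <- as.numeric(weights)
  validate_weights(w)
  protocol <- step_protocol(h1, h2, t_stim = t_stim, t_dark = t_dark,
                            t_pre = 0, peak_rate = peak_rate)
  t1 <- t_stim + t_dark
  t2 <- 2 * (t_stim + t_dark)
  p0 <- mean(exp(-2 * abs(w)))
  worst <- list(score = 4 * (0.5 + 0.5) + 0.75 + 0.75 + 5 * p0,
                eps_h1 = 0.5, eps_h2 = 0.5, eps_w1 = 0.75, eps_w2 = 0.75,
                p0 = p0, h_a = c(NA, NA), w_a = c(NA, NA),
                checkpoints = c(t1, t2))
  sim <- tryCatch(
    simulate_protocol(circuit, protocol, weights = cx_weights(w[1], w[2], w[3], w[4], w[5]),
                      dt = dt, seed = seed),
    error = function(e) NULL)
  if (is.null(sim)) {
    out <- worst
    class(out) <- "cx_objective"
    return(out)
  }
  prof <- vapply(c(t1, t2), function(tc) {
    sp <- sim$spikes
    sel <- sp$time > (tc - t_measure) & sp$time <= tc & sp$unit <= 8
    tabulate(sp$unit[sel], nbins = 8) / t_measure
  }, numeric(8))
  h_a <- bump_azimuth(t(prof))
  w_a <- bump_fwhm(t(prof))
  eh <- abs(wrap180(c(h1, h2) - h_a)) / 360
  eh[is.na(eh)] <- 0.5
  ew <- abs(90 - w_a) / 360
  ew[is.na(ew)] <- 0.75
  out <- list(score = 4 * sum(eh) + sum(ew) + 5 * p0,
              eps_h1 = eh[1], eps_h2 = eh[2], eps_w1 = ew[1], eps_w2 = ew[2],
              p0 = p0, h_a = h_a, w_a = w_a, checkpoints = c(t1, t2))
  class(out) <- "cx_objective"
  out
}

#' @export
print.cx_objective <- function(x, ...) {
  cat(sprintf("objective score %.4f (eH = %.3f/%.3f, eW = %.3f/%.3f, p0 = %.3g)\n",
              x$score, x$eps_h1, x$eps_h2, x$eps_w1, x$eps_w2, x$p0))
  cat(sprintf("  bump at t1: %.1f deg, FWHM %.1f deg; t2: %.1f deg, FWHM %.1f deg\n",
              x$h_a[1], x$w_a[1], x$h_a[2], x$w_a[2]))
  invisible(x)
}

#' Optimize the five synaptic weights
#'
#' Searches the bounded five-dimensional weight space for a working ring
#' attractor under [ring_objective()], by particle swarm optimization
#' (constriction-coefficient form) or simulated annealing (bounded
#' Metropolis with geometric cooling). Excitatory weights are initialized at
#' 0.01 and inhibitory at -0.01; every candidate respects the sign and box
#' constraints exactly. All objective evaluations share one
#' stimulus-encoding seed derived from `seed` (common random numbers), so
#' the search is fully reproducible.
#'
#' Because the synaptic weights act multiplicatively over several orders of
#' magnitude, the swarm is initialized log-uniformly over the box (one
#' particle sits at the prescribed 0.01 starting point). With `restarts > 1`
#' independent swarms are run and the best result returned. A short
#' Nelder-Mead polish (`polish` evaluations, candidates clipped to the box)
#' refines the best point.
#'
#' @param method `"pso"` or `"sann"`.
#' @param budget Number of objective evaluations per restart.
#' @param seed RNG seed for the search (and, derived, the stimulus).
#' @param circuit A `cx_circuit`.
#' @param particles Swarm size (PSO).
#' @param inertia,c_cog,c_soc PSO constriction/acceleration constants.
#' @param t0,t_min Initial/final SA temperature.
#' @param step0 Initial SA proposal scale (fraction of the box).
#' @param restarts Independent searches (best kept).
#' @param polish Nelder-Mead refinement evaluations after the search
#'   (0 disables).
#' @param n_rep Stimulus repetitions averaged per evaluation (see
#'   [ring_objective()]).
#' @param ... Passed to [ring_objective()] (e.g. `peak_rate`, `dt`).
#' @return List of class `cx_fit`: `weights` ([cx_weights()]), `report`
#'   (the best `cx_objective`), `score`, `n_eval`, `method`, `seed`,
#'   `trace` (best score per iteration).
#' @export
fit_weights <- function(method = c("pso", "sann"), budget = 600, seed = 1L,
                        circuit = cx_circuit(), particles = 20,
                        inertia = 0.7298, c_cog = 1.49618, c_soc = 1.49618,
                        t0 = 1, t_min = 1e-3, step0 = 0.1, restarts = 1L,
                        polish = 0L, n_rep = 1L, ...) {
  method <- match.arg(method)
  stopifnot(budget >= 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  stim_seed <- sample.int(2^30, 1) # shared by every evaluation
  b <- weight_bounds()
  lo <- b$lower; hi <- b$upper
  init <- c(0.01, 0.01, 0.01, -0.01, -0.01)
  n_eval <- 0L
  best <- list(score = Inf, w = init, report = NULL)
  evalw <- function(w) {
    n_eval <<- n_eval + 1L
    rep <- ring_objective(w, circuit = circuit, seed = stim_seed,
                          n_rep = n_rep, ...)
    if (rep$score < best$score)
      best <<- list(score = rep$score, w = w, report = rep)
    rep$score
  }
  trace <- numeric(0)

  for (rs in seq_len(max(restarts, 1L))) {
  rs_eval0 <- n_eval # each restart gets its own evaluation budget
  if (method == "pso") {
    np <- min(particles, budget)
    sgn <- c(1, 1, 1, -1, -1)
    X <- matrix(10^stats::runif(np * 5, -2, 2), nrow = 5) * sgn
    X[, 1] <- init
    V <- matrix(stats::runif(np * 5, -(hi - lo), hi - lo) * 0.1, nrow = 5)
    Fp <- apply(X, 2, evalw)
    Pb <- X
    g <- which.min(Fp)
    trace <- c(trace, best$score)
    while (n_eval - rs_eval0 + np <= budget) {
      for (i in seq_len(np)) {
        r1 <- stats::runif(5); r2 <- stats::runif(5)
        V[, i] <- inertia * (V[, i] + c_cog * r1 * (Pb[, i] - X[, i]) +
                               c_soc * r2 * (X[, g] - X[, i]))
        X[, i] <- X[, i] + V[, i]
        clip <- X[, i] < lo | X[, i] > hi
        X[, i] <- pmin(pmax(X[, i], lo), hi)
        V[clip, i] <- 0
        f <- evalw(X[, i])
        if (f < Fp[i]) { Fp[i] <- f; Pb[, i] <- X[, i] }
      }
      g <- which.min(Fp)
      trace <- c(trace, best$score)
    }
  } else {
    x <- init
    fx <- evalw(x)
    trace <- fx
    n_iter <- max(budget - 1L, 1L)
    for (k in seq_len(n_iter)) {
      frac <- (k - 1) / max(n_iter - 1, 1)
      temp <- t0 * (t_min / t0)^frac
      scale <- step0 * (0.1)^frac
      xp <- pmin(pmax(x + stats::rnorm(5) * scale * (hi - lo), lo), hi)
      fp <- evalw(xp)
      if (fp < fx || stats::runif(1) < exp((fx - fp) / temp)) {
        x <- xp; fx <- fp
      }
      trace <- c(trace, best$score)
    }
  }
  } # restarts
  if (polish > 0) {
    f <- function(w) evalw(pmin(pmax(w, lo), hi))
    try(stats::optim(best$w, f, method = "Nelder-Mead",
                     control = list(maxit = polish, reltol = 1e-3)),
        silent = TRUE)
    trace <- c(trace, best$score)
  }
  if (is.null(best$report))
    best$report <- ring_objective(best$w, circuit = circuit, seed = stim_seed,
                                  n_rep = n_rep, ...)
  w <- best$w
  structure(list(weights = cx_weights(w[1], w[2], w[3], w[4], w[5]),
                 report = best$report, score = best$score, n_eval = n_eval,
                 method = method, seed = seed, trace = trace),
            class = "cx_fit")
}

#' @export
print.cx_fit <- function(x, ...) {
  cat(sprintf("fit_weights(%s): %d evaluations, best score %.4f\n",
              x$method, x$n_eval, x$score))
  print(round(unclass(x$weights), 4))
  invisible(x)
}

#' Serialize fitted weights with provenance
#'
#' @param fit A `cx_fit` (or a bare [cx_weights()] vector).
#' @param file JSON output path.
#' @return `file` invisibly; `read_weights_json` returns a [cx_weights()]
#'   vector (with provenance in attribute `provenance` when present).
#' @export
write_weights_json <- function(fit, file) {
  if (inherits(fit, "cx_fit")) {
    x <- list(weights = as.list(unclass(fit$weights)), method = fit$method,
              seed = fit$seed, n_eval = fit$n_eval, score = fit$score)
  } else x <- list(weights = as.list(unclass(fit)))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_weights_json
#' @export
read_weights_json <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  w <- do.call(cx_weights, as.list(x$weights))
  attr(w, "provenance") <- x[setdiff(names(x), "weights")]
  w
}

#' Silence one synapse class
#'
#' Returns the weight vector with the named class zeroed, emulating complete
#' silencing of that connection (e.g. of the P-EG to E-PG recurrence).
#' Idempotent.
#'
#' @param weights A [cx_weights()] vector.
#' @param which One of `"w1"`..`"w5"` or an alias: `"E-PG-out"` (w1),
#'   `"P-EN->E-PG"` (w2), `"P-EG->E-PG"` or `"P-EG"` (w3),
#'   `"Delta7->excitatory"` (w4), `"Delta7->Delta7"` (w5).
#' @return A [cx_weights()] vector.
#' @examples
#' lesion(cx_weights(1, 1, 1, -1, -1), "P-EG->E-PG")
#' @export
lesion <- function(weights, which) {
  alias <- c("w1" = "w1", "E-PG-out" = "w1",
             "w2" = "w2", "P-EN->E-PG" = "w2",
             "w3" = "w3", "P-EG->E-PG" = "w3", "P-EG" = "w3",
             "w4" = "w4", "Delta7->excitatory" = "w4",
             "w5" = "w5", "Delta7->Delta7" = "w5")
  if (!which %in% names(alias)) stop("unknown synapse class: ", which)
  w <- unclass(weights)
  w[alias[[which]]] <- 0
  cx_weights(w[1], w[2], w[3], w[4], w[5])
}
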