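.cx_cache <- new.env(parent = emptyenv())

#' The effective fly head-direction circuit
#'
#' Builds (once per session) the reduced eight-fold ring circuit from the
#' encoded anatomy: `reduce_circuit(infer_synapses(cx_arbors()))`.
#'
#' @return A `cx_circuit` with 40 units (8 E-PG, 8 P-EG, 8 left + 8 right
#'   P-EN, 8 Delta7) and 200 signed edges.
#' @examples
#' cir <- cx_circuit()
#' check_radial_symmetry(cir)
#' @export
cx_circuit <- function() {
  if (is.null(.cx_cache$circuit))
    .cx_cache$circuit <- reduce_circuit(infer_synapses(cx_arbors()))
  .cx_cache$circuit
}

#' Reference optimized synaptic weights
#'
#' The weight set used as the package default for simulation, tracking and
#' sensitivity experiments. It was selected with the package's own tools:
#' candidate optima of the two-step objective ([ring_objective()], found by
#' [fit_weights()] runs and a seeded grid refinement) were screened with the
#' noise-sweep battery ([run_sweep()]) for tolerance to membrane and
#' synaptic heterogeneity. The winning set yields a working ring attractor:
#' a single activity bump of about 88 degree FWHM that persists through
#' darkness for seconds, relocates by 180 degrees on an azimuth step, tracks
#' a fly-like trajectory within the 10-degree criterion, and keeps tracking
#' under 50 percent conductance heterogeneity. The objective alone does not
#' pin down heterogeneity tolerance: several weight sets score equally well
#' on it while differing sharply in robustness (see the methods vignette).
#'
#' @return A [cx_weights()] vector.
#' @export
cx_reference_weights <- function() {
  cx_weights(w1 = 2.5, w2 = 1.0, w3 = 4.0, w4 = -1.5, w5 = -1.5)
}
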