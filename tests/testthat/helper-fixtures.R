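# Shared fixtures: everything is built in code at test time.

fly_circuit <- local({
  cir <- NULL
  function() {
    if (is.null(cir)) cir <<- cx_circuit()
    cir
  }
})

# A weight set in the functional ring-attractor regime (matches the package
# reference weights; duplicated here so tests do not depend on the constant).
working_weights <- function() cx_reference_weights()

# Tiny arbor table: two same-class neurons with identical connectivity plus
# one distinct partner; reduces to 2 units.
micro_arbors <- function() {
  df <- data.frame(
    neuron_id = c("E-PG_a", "E-PG_a", "E-PG_b", "E-PG_b", "P-EG_c", "P-EG_c"),
    class = c("E-PG", "E-PG", "E-PG", "E-PG", "P-EG", "P-EG"),
    volume_kind = c("EB-tile", "PB-glomerulus", "EB-tile", "PB-glomerulus",
                    "PB-glomerulus", "EB-tile"),
    hemisphere = c("none", "L", "none", "R", "L", "none"),
    index = c(1L, 1L, 1L, 1L, 1L, 1L),
    polarity = c("input", "output", "input", "output", "input", "output"),
    stringsAsFactors = FALSE)
  class(df) <- c("cx_arbors", "data.frame")
  df
}

# Analytic subthreshold solution of the membrane equation under constant
# drive: V(t) = Vinf + (V(0) - Vinf) * exp(-t / tau).
analytic_voltage <- function(t, v_start, i_tot, p = cx_neuron_params()) {
  vinf <- p$v_0 + p$r_m * i_tot
  tau <- p$r_m * p$c_m * 1e-3 # seconds
  vinf + (v_start - vinf) * exp(-t / tau)
}
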