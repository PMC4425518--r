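# Small deterministic fixture networks with hand-checkable expected values.
# Construction never consumes random numbers.

#' Fixture: a single passive cable
#'
#' One neuron (default geometry), no junctions, uniform passive leak.
#' Useful for electrotonic-length and input-resistance checks against
#' closed-form cable theory.
#'
#' @param g_lk leak density, mS/cm^2.
#' @param axon_length axon length, um.
#' @export
fixture_single_cable <- function(g_lk = 0.25, axon_length = 1500) {
  pop <- build_population(1, 10,
                          din_morphology(axon_length = axon_length))
  network_model(pop, empty_junctions(), density_config(noise_sd = 0),
                g_lk = g_lk, passive = TRUE)
}

empty_junctions <- function() {
  data.frame(caudal = integer(0), rostral = integer(0), d_gj = numeric(0),
             coordinate = numeric(0), resistance = numeric(0))
}

#' Fixture: two neurons with one gap junction
#'
#' Somata 10 um apart; a single 600 MOhm junction 25 um along the caudal
#' neuron's axon (35 um along the rostral axon).
#'
#' @param resistance junction resistance, MOhm.
#' @param g_lk leak density, mS/cm^2.
#' @export
fixture_pair_with_junction <- function(resistance = 600, g_lk = 0.25) {
  pop <- build_population(2, 10)
  gj <- data.frame(caudal = 1L, rostral = 0L, d_gj = 25,
                   coordinate = 10 + 25, resistance = resistance)
  network_model(pop, gj, density_config(noise_sd = 0), g_lk = g_lk,
                passive = TRUE)
}

#' Fixture: three-neuron chain
#'
#' Junctions 0-1 and 1-2 only, so the outer pair is coupled indirectly via
#' the middle neuron's axon.
#'
#' @param resistance junction resistance, MOhm.
#' @param g_lk leak density, mS/cm^2.
#' @export
fixture_chain3 <- function(resistance = 600, g_lk = 0.25) {
  pop <- build_population(3, 10)
  gj <- data.frame(caudal = c(1L, 2L), rostral = c(0L, 1L),
                   d_gj = c(25, 25), coordinate = c(35, 45),
                   resistance = resistance)
  network_model(pop, gj, density_config(noise_sd = 0), g_lk = g_lk,
                passive = TRUE)
}
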