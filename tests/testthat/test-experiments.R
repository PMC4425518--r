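test_that("input resistance matches the analytic soma+cable value", {
  # soma disc (400 MOhm at 0.25 mS/cm2 x 1000 um2) in parallel with the
  # sealed finite cable R_inf * coth(L/lambda); hillock adds a few percent
  net <- fixture_single_cable()
  lam <- cable_lambda_um()
  R_m <- 4000                                  # Ohm cm^2
  r_soma <- 1 / (0.25e-3 * 1000e-8) / 1e6      # MOhm
  R_inf <- (2 / pi) * sqrt(R_m * 80) / (0.4e-4)^1.5 / 1e6
  r_cable <- R_inf / tanh(1500 / lam)
  expected <- 1 / (1 / r_soma + 1 / r_cable)
  expect_equal(input_resistance(net), expected, tolerance = 0.05)
})

test_that("junction coupling always lowers input resistance", {
  pop <- build_population(30)
  set.seed(31)
  for (rep in 1:3) {
    net <- network_model(pop, generate_density_layout(pop), passive = TRUE)
    bare <- remove_gap_junctions(net)
    for (nid in c(0L, 14L, 29L))
      expect_lt(input_resistance(net, nid), input_resistance(bare, nid))
  }
})

test_that("coupling coefficients are linear, bounded, and vanish without junctions", {
  net <- fixture_chain3()
  set.seed(41)
  cc1 <- measure_coupling(net, n_runs = 10, current_pA = -100)
  set.seed(41)
  cc2 <- measure_coupling(net, n_runs = 10, current_pA = -37)
  set.seed(41)
  cc3 <- measure_coupling(net, n_runs = 10, current_pA = +100)
  expect_equal(cc1$coefficient, cc2$coefficient, tolerance = 1e-10)
  expect_equal(cc1$coefficient, cc3$coefficient, tolerance = 1e-10)
  expect_true(all(cc1$coefficient >= 0 & cc1$coefficient <= 100))
  bare <- remove_gap_junctions(net)
  set.seed(1)
  cc0 <- measure_coupling(bare, n_runs = 5)
  expect_true(all(cc0$coefficient == 0))
})

test_that("median coupling falls as junction resistance rises", {
  pop <- build_population(30)
  meds <- vapply(c(300, 600, 900), function(rgj) {
    set.seed(51)
    gj <- generate_density_layout(pop, layout_scheme(resistance = rgj))
    net <- network_model(pop, gj, passive = TRUE)
    set.seed(52)
    stats::median(measure_coupling(net, n_runs = 30)$coefficient)
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("conduction velocity recovers a constructed propagation speed", {
  # probes every 20 um with spike times for exactly 0.2 m/s (= 200 um/ms)
  arcs <- seq(20, 400, by = 20)
  pres <- structure(list(success = TRUE,
                         probes = data.frame(arc = arcs,
                                             t_spike = 2 + arcs / 200),
                         soma_spikes = 2, neuron = 0L),
                    class = "propagation_result")
  expect_equal(conduction_velocity(pres), 0.2, tolerance = 1e-12)
  # fewer than two spiking probes is undefined
  pres$probes$t_spike <- NA_real_
  expect_error(conduction_velocity(pres), "undefined")
})

test_that("firing classification labels subthreshold responses as none", {
  pop <- build_population(1, morphology = din_morphology(axon_length = 400))
  net <- network_model(pop, axonet:::empty_junctions(),
                       density_config(c(na = 3), noise_sd = 0),
                       g_lk = 0.125)
  dens <- realise_densities(pop$compartments, net$density, REG,
                            g_lk_base = 0.125)
  cl <- classify_firing(net, 0, levels_pA = c(2, 5), duration_ms = 60,
                        densities = dens)
  expect_equal(cl$label, "none")
  expect_true(all(cl$spike_counts == 0))
})

test_that("zero-amplitude pulses never count as rebound", {
  pop <- build_population(1, morphology = din_morphology(axon_length = 400))
  net <- network_model(pop, axonet:::empty_junctions(),
                       density_config(c(na = 3), noise_sd = 0,
                                      overrides =
                                        initial_segment_overrides()),
                       g_lk = 0.125)
  dens <- realise_densities(pop$compartments, net$density, REG,
                            g_lk_base = 0.125)
  rb <- rebound_test(net, 0, background_pA = 20, pulse_pA = 0,
                     densities = dens)
  expect_false(rb$rebound)
})

test_that("density sweep grid covers the multiplier combinations", {
  pop <- build_population(2, morphology = din_morphology(axon_length = 400))
  # full tested grid size: 4 (ca) x 6 (na) x 3 x 3 x 3 combinations
  full <- attr(REG, "multipliers_tested")
  expect_equal(prod(lengths(full)), 648L)
  # scaled-down sweep evaluates every grid point; modest currents so that
  # passive depolarisation of this small high-impedance fixture cannot
  # itself cross the spike detector
  set.seed(61)
  sw <- density_sweep(pop, grid = list(na = c(0, 3)), replicates = 1,
                      noise_sd = 0, levels_pA = c(30, 60), pulse_pA = 250)
  expect_equal(nrow(sw), 2L)
  # no sodium, no spikes anywhere: classified neither single nor propagating
  none <- sw[sw$na == 0, ]
  expect_equal(none$fraction_single, 0)
  expect_equal(none$fraction_propagating, 0)
})

test_that("packaged coupling reference table is available for overlays", {
  ref <- coupling_reference()
  expect_true(all(c("distance_lo", "distance_hi", "cc_lo", "cc_hi") %in%
                    names(ref)))
  expect_true(all(ref$cc_lo <= ref$cc_hi))
})
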