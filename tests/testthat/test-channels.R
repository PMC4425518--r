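test_that("rate function reproduces hand-evaluated values", {
  # Na activation opening rate at the voltage where the exponent vanishes
  na_am <- REG$na$gates[[1]]$alpha
  expect_equal(eval_rate(na_am, 1.01), 8.67 / 2, tolerance = 1e-10)
  # fast-K closing rate has C = 0, pure exponential
  kf_bn <- REG$kf$gates[[1]]$beta
  expect_equal(eval_rate(kf_bn, -28.7), 0.505, tolerance = 1e-10)
})

test_that("calcium closing-rate branches agree near the split voltage", {
  g <- REG$ca$gates[[1]]
  lo <- eval_rate(g$beta, -25)
  hi <- eval_rate(g$beta_high, -25)
  expect_lt(abs(lo - hi) / hi, 0.02)
  # dispatch: split voltage itself uses the upper branch
  r <- axonet:::gate_rates(g, -25)
  expect_equal(r$beta, hi)
})

test_that("rates are non-negative over the working voltage range", {
  V <- seq(-100, 60, by = 0.5)
  for (ch in c("na", "kf", "ks", "ca")) {
    for (g in REG[[ch]]$gates) {
      r <- axonet:::gate_rates(g, V)
      expect_true(all(r$alpha >= 0), label = paste(ch, g$name, "alpha"))
      expect_true(all(r$beta >= 0), label = paste(ch, g$name, "beta"))
    }
  }
})

test_that("gate steady state and time constant behave", {
  g <- REG$na$gates[[1]]
  V <- seq(-80, 0, by = 0.25)
  minf <- gate_steady_state(g, V)
  expect_true(all(minf >= 0 & minf <= 1))
  expect_true(all(diff(minf) > 0))          # Na activation is monotone
  # Xinf / tau == alpha (algebraic identity)
  tau <- gate_time_constant(g, V)
  a <- axonet:::gate_rates(g, V)$alpha
  expect_equal(minf / tau, a, tolerance = 1e-12)
  # symmetric rates give 0.5 / tau = 1/(a+b)
  sym <- gate_spec("m_na", 1, rate_params(1, 0, 1, 0, 1e6),
                   rate_params(1, 0, 1, 0, 1e6))
  expect_equal(gate_steady_state(sym, 0), 0.5)
  expect_equal(gate_time_constant(sym, 0), 1 / (2 * eval_rate(sym$alpha, 0)))
})

test_that("gate variables stay in [0,1] under exponential integration", {
  set.seed(42)
  for (g in list(REG$na$gates[[1]], REG$na$gates[[2]], REG$ca$gates[[1]])) {
    x <- stats::runif(1)
    V <- stats::runif(2000, -100, 60)       # arbitrary voltage trajectory
    for (v in V) {
      xi <- gate_steady_state(g, v)
      x <- xi + (x - xi) * exp(-0.01 / gate_time_constant(g, v))
    }
    expect_true(x >= 0 && x <= 1)
  }
})

test_that("ohmic currents respect reversal, gating and linearity", {
  na <- REG$na
  expect_equal(ohmic_current(na, na$reversal_mV, list(m = 0.5, h = 0.5)), 0)
  expect_equal(ohmic_current(na, -52, list(m = 0, h = 1)), 0)
  i1 <- ohmic_current(na, -52, list(m = 0.5, h = 0.5), g = 10)
  i2 <- ohmic_current(na, -52, list(m = 0.5, h = 0.5), g = 20)
  expect_equal(i2, 2 * i1)
  expect_gt(i1, 0)                          # depolarising below reversal
})

test_that("GHK current has a removable singularity and correct sign", {
  k <- ghk_constants()
  # limit V -> 0 equals the L'Hopital value
  lim <- -2 * k$F * 0.016 * (k$Ca_internal - k$Ca_external)
  expect_equal(ghk_current(0.016, 1, 0, k), lim, tolerance = 1e-9)
  # continuity across 0 within 1e-6 relative
  left <- ghk_current(0.016, 1, -1e-7, k)
  right <- ghk_current(0.016, 1, 1e-7, k)
  expect_lt(abs(left - right) / abs(lim), 1e-6)
  # series/guard evaluation agrees with direct formula near -20 mV
  expect_equal(ghk_current(0.016, 0.3, -20, k),
               ghk_current(0.016, 0.3, -20 + 1e-9, k), tolerance = 1e-6)
  # gate closed -> no current; depolarising at physiological V
  expect_equal(ghk_current(0.016, 0, -52, k), 0)
  expect_gt(ghk_current(0.016, 0.1, -52, k), 0)
})

test_that("registry carries the tabulated base parameters", {
  expect_equal(REG$lk$base_value, 0.25)
  expect_equal(REG$na$base_value, 10.0)
  expect_equal(REG$kf$base_value, 2.5)
  expect_equal(REG$ks$base_value, 2.0)
  expect_equal(REG$ca$base_value, 0.016)
  expect_equal(REG$lk$reversal_mV, -52)
  expect_equal(REG$na$reversal_mV, 50)
  expect_equal(REG$kf$reversal_mV, -81.5)
  ch <- attr(REG, "multiplier_chosen")
  expect_equal(unname(ch[c("na", "ca", "kf", "ks", "lk")]),
               c(3.0, 1.0, 1.0, 1.0, 1.0))
})

test_that("density realisation: determinism, multipliers, overrides", {
  pop <- build_population(3)
  cmp <- pop$compartments
  # noise 0: exact base values, independent of seed
  d0 <- realise_densities(cmp, density_config(noise_sd = 0), REG)
  expect_true(all(d0[, "na"] == 10.0))
  expect_true(all(d0[, "lk"] == 0.25))
  set.seed(1); d1 <- realise_densities(cmp, density_config(noise_sd = 0), REG)
  expect_identical(d0, d1)
  # multiplier scales before noise
  d3 <- realise_densities(cmp, density_config(c(na = 3), noise_sd = 0), REG)
  expect_true(all(d3[, "na"] == 30.0))
  # initial-segment override multiplies inside [20, 70) on the axon only
  dov <- realise_densities(cmp,
    density_config(noise_sd = 0,
                   overrides = list(list(interval = c(20, 70),
                                         channel = "na", factor = 5))), REG)
  inside <- cmp$section == "axon" & !is.na(cmp$axon_arc) &
    cmp$axon_arc >= 20 & cmp$axon_arc < 70
  expect_true(all(dov[inside, "na"] == 50))
  expect_true(all(dov[!inside, "na"] == 10))
  # one noise draw per neuron x channel; never negative
  set.seed(7)
  dn <- realise_densities(cmp, density_config(noise_sd = 0.05), REG)
  for (nid in 0:2)
    expect_equal(length(unique(dn[cmp$neuron == nid, "na"])), 1L)
  expect_true(all(dn >= 0))
  # override outside the axon span errors
  expect_error(realise_densities(cmp,
    density_config(noise_sd = 0,
                   overrides = list(list(interval = c(0, 5000),
                                         channel = "na", factor = 2))), REG),
    "outside the axon")
})
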