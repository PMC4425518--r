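test_that("axial and junctional conductances match closed forms", {
  # two adjacent 5 um x 0.4 um axon compartments, R_i = 80 Ohm cm:
  # g = pi d^2 / (4 R_i l), l = 5 um total between the two centres
  g_hand <- pi * (0.4e-4)^2 / (4 * 80 * 5e-4) * 1e6     # uS
  net <- fixture_single_cable()
  sys <- assemble(net)
  ax <- which(sys$compartments$section == "axon")
  mid <- ax[10]                      # two uniform 5 um neighbours
  expect_equal(sys$gax[mid], g_hand, tolerance = 1e-10)
  # 600 MOhm junction -> 1.667 nS
  sysj <- assemble(fixture_pair_with_junction())
  expect_equal(sysj$gj$g, 1 / 600, tolerance = 1e-12)   # uS
})

test_that("conductance matrix is symmetric with leak-only row sums", {
  sys <- assemble(fixture_chain3())
  G <- sys$G
  expect_lt(max(abs(G - Matrix::t(G))), 1e-12)
  offdiag <- G; Matrix::diag(offdiag) <- 0
  expect_true(all(offdiag@x <= 0))
  expect_equal(as.numeric(Matrix::rowSums(G)), sys$glk, tolerance = 1e-9)
  # no junctions: block-diagonal by neuron (no cross-neuron entries)
  sys0 <- assemble(network_model(build_population(2),
                                 axonet:::empty_junctions()))
  per <- nrow(sys0$compartments) / 2
  expect_equal(sum(abs(sys0$G[1:per, (per + 1):(2 * per)])), 0)
})

test_that("steady state is exact, linear and charge-balanced", {
  sys <- assemble(fixture_pair_with_junction())
  I <- numeric(sys$ncomp)
  expect_equal(steady_state_solve(sys, I), I)            # zero in, zero out
  I[1] <- -0.1
  dv <- steady_state_solve(sys, I)
  expect_equal(steady_state_solve(sys, 2 * I), 2 * dv, tolerance = 1e-12)
  # net injected current equals total leak current at steady state
  expect_equal(sum(sys$glk * dv), sum(I), tolerance = 1e-9)
})

test_that("transfer resistance is reciprocal on random small networks", {
  set.seed(21)
  for (rep in 1:4) {
    n <- sample(3:5, 1)
    pop <- build_population(n, 10, din_morphology(axon_length = 600))
    k <- sample(2:4, 1)
    caudal <- sample(seq_len(n - 1), k, replace = TRUE)  # ids 1..n-1
    d <- stats::runif(k, 0, 45)
    gj <- data.frame(caudal = caudal,
                     rostral = vapply(caudal, function(cid)
                       sample.int(cid, 1) - 1L, integer(1)),
                     d_gj = d,
                     coordinate = pop$soma_positions[caudal + 1] + d,
                     resistance = stats::runif(k, 200, 1500))
    net <- network_model(pop, gj, passive = TRUE)
    R <- soma_transfer_matrix(net)
    expect_lt(max(abs(R - t(R))) / max(abs(R)), 1e-8)
    # and agrees with a dense-matrix oracle
    sys <- assemble(net)
    Idense <- numeric(sys$ncomp); Idense[1] <- 1
    dense <- solve(as.matrix(sys$G), Idense)
    expect_equal(as.numeric(steady_state_solve(sys, Idense)), dense,
                 tolerance = 1e-8)
  }
})

test_that("passive voltage decays with the cable-theory space constant", {
  net <- fixture_single_cable()
  sys <- assemble(net)
  I <- numeric(sys$ncomp); I[1] <- -0.1
  dv <- steady_state_solve(sys, I)
  cmp <- sys$compartments
  sel <- cmp$section == "axon" & cmp$axon_arc >= 300 & cmp$axon_arc <= 800
  fit <- stats::lm(log(abs(dv[sel])) ~ cmp$axon_arc[sel])
  lambda_num <- -1 / unname(stats::coef(fit)[2])
  expect_lt(abs(lambda_num - cable_lambda_um()) / cable_lambda_um(), 0.02)
})

test_that("dynamic integration relaxes to the steady-state solution", {
  net <- fixture_pair_with_junction()
  sys <- assemble(net)
  I <- numeric(sys$ncomp); I[1] <- -0.1
  dv <- steady_state_solve(sys, I)
  stim <- stimulus_protocol(0, -100, 0, 60)       # -100 pA into soma 0
  sim <- simulate_network(net, stim, t_stop = 60, dt = 0.1,
                          probes = probe_set(c(0, 1)))
  late <- nrow(sim$traces)
  expect_lt(abs(unname(sim$traces[late, 1]) + 52 - dv[1]) / abs(dv[1]),
            0.005)
  soma2 <- axonet:::soma_comp_index(net$pop, 1)
  expect_lt(abs(unname(sim$traces[late, 2]) + 52 - dv[soma2]) /
              abs(dv[soma2]), 0.005)
})

test_that("unstimulated passive model stays at the leak reversal", {
  net <- fixture_single_cable()
  sim <- simulate_network(net, t_stop = 20, dt = 0.1, probes = probe_set(0))
  expect_true(all(abs(sim$traces - (-52)) < 1e-9))
})

test_that("spike timing converges as the step is halved", {
  pop <- build_population(1, morphology = din_morphology(axon_length = 400))
  net <- network_model(pop, axonet:::empty_junctions(),
                       density_config(c(na = 3), noise_sd = 0,
                                      overrides =
                                        initial_segment_overrides()),
                       g_lk = 0.125)
  dens <- realise_densities(pop$compartments, net$density, REG,
                            g_lk_base = 0.125)
  stim <- stimulus_protocol(0, 300, 5, 50)
  t1 <- spike_times(simulate_network(net, stim, t_stop = 40, dt = 0.01,
                                     probes = probe_set(0),
                                     densities = dens))[[1]][1]
  t2 <- spike_times(simulate_network(net, stim, t_stop = 40, dt = 0.005,
                                     probes = probe_set(0),
                                     densities = dens))[[1]][1]
  expect_lt(abs(t1 - t2), 0.05)
})

test_that("spike detection honours threshold, refractory and interpolation", {
  t <- seq(0, 50, by = 0.1)
  flat <- rep(-52, length(t))
  expect_length(detect_spikes(t, flat), 0L)
  # five synthetic spikes at known times
  v <- rep(-60, length(t))
  peaks <- c(5, 15, 25, 35, 45)
  for (p in peaks) v[abs(t - p) < 0.5] <- 20
  st <- detect_spikes(t, v)
  expect_length(st, 5L)
  expect_equal(st, peaks - 0.5 + 0.1 * 80 / 80, tolerance = 0.2)
  # double crossing within the refractory interval counts once
  v2 <- rep(-60, length(t))
  v2[abs(t - 10) < 0.3] <- 20
  v2[abs(t - 11.5) < 0.3] <- 20
  expect_length(detect_spikes(t, v2, refractory = 3), 1L)
})

test_that("trace export writes one column per probe", {
  net <- fixture_single_cable()
  sim <- simulate_network(net, t_stop = 5, dt = 0.1,
                          probes = probe_set(c(0, 0), c("soma", "100")))
  p <- tempfile(fileext = ".csv")
  write_traces_csv(sim, p)
  tab <- utils::read.csv(p, check.names = FALSE)
  expect_equal(ncol(tab), 3L)
  expect_equal(nrow(tab), length(sim$time))
})
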