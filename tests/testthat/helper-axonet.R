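# shared fixtures and oracles for the suite (built in code, no stored data)

REG <- channel_registry()

# analytic passive-cable constants for the default geometry
cable_lambda_um <- function(g_lk = 0.25, d_um = 0.4, R_i = 80) {
  R_m <- 1000 / g_lk                       # Ohm cm^2
  sqrt(R_m * d_um * 1e-4 / (4 * R_i)) * 1e4
}

# density matrix without noise for the chosen final multipliers
final_densities <- function(pop, g_lk = 0.125, noise_sd = 0) {
  cfgd <- density_config(c(ca = 1, na = 3, kf = 1, ks = 1, lk = 1),
                         noise_sd = noise_sd,
                         overrides = initial_segment_overrides())
  realise_densities(pop$compartments, cfgd, REG, g_lk_base = g_lk)
}

# small coupled active network (noise-free densities unless asked)
small_final_net <- function(seed = 1, n = 30) {
  set.seed(seed)
  final_din_network(pop = build_population(n))
}

# transfer-resistance matrix between somata of a passive network
soma_transfer_matrix <- function(net, R_i = 80) {
  sys <- assemble(net, R_i = R_i)
  n <- net$pop$n
  soma <- vapply(seq_len(n) - 1L, function(k)
    axonet:::soma_comp_index(net$pop, k), numeric(1))
  I <- matrix(0, sys$ncomp, n)
  for (k in seq_len(n)) I[soma[k], k] <- 1   # 1 nA
  dv <- steady_state_solve(sys, I)
  dv[soma, , drop = FALSE]                   # MOhm
}
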