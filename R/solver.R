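# System assembly (axial + gap-junction conductance matrix, capacitances),
# passive steady-state solution, dynamic integration, and spike detection.

UM2_TO_CM2 <- 1e-8

# axial conductance (uS) between adjacent compartments: series resistance of
# the two half-compartment cylinders, R_i in Ohm cm, lengths/diameters in um
axial_conductance <- function(len1, d1, len2, d2, R_i) {
  r <- (4 * R_i / pi) * ((len1 / 2 * 1e-4) / (d1 * 1e-4)^2 +
                         (len2 / 2 * 1e-4) / (d2 * 1e-4)^2)   # Ohm
  1e6 / r
}

# global row index of the axon compartment of `neuron` nearest axon arc `arc`
axon_comp_index <- function(pop, neuron, arc) {
  per <- pop$comps_per_neuron
  base <- pop$compartments[seq_len(per), ]
  ax <- which(base$section == "axon")
  k <- ax[which.min(abs(base$axon_arc[ax] - arc))]
  neuron * per + k
}

soma_comp_index <- function(pop, neuron) neuron * pop$comps_per_neuron + 1L

#' Assemble the electrical system of a network
#'
#' Builds the per-compartment capacitance vector, the within-neuron axial
#' conductances, the gap-junction attachment (each junction connects the
#' caudal-axon compartment at `d_gj` with the rostral-axon compartment at
#' the same rostrocaudal coordinate, at compartment centres), and the
#' symmetric sparse conductance matrix `G` of the passive system
#' (leak diagonal + axial and junctional Laplacian). `G` is in uS, so
#' `G %*% dV = I` holds with deflections in mV and currents in nA.
#'
#' @param net a [network_model].
#' @param R_i intracellular resistivity, Ohm cm (default 80).
#' @param c_m specific membrane capacitance, uF/cm^2 (default 1.0).
#' @param g_lk_comp optional per-compartment leak density vector (mS/cm^2),
#'   e.g. column `lk` of [realise_densities]; defaults to the network's
#'   uniform `g_lk`.
#' @return an object of class `din_system`: list with `ncomp`, `cap` (nF),
#'   `gax` (uS; entry i couples compartments i and i+1, zero at chain ends),
#'   `glk` (uS), `gj` (compartment index pairs + conductances, uS),
#'   `G` (sparse dgCMatrix), `area_cm2`, and the compartment table.
#' @export
assemble <- function(net, R_i = 80, c_m = 1.0, g_lk_comp = NULL) {
  stopifnot(inherits(net, "din_network"), R_i > 0, c_m > 0)
  pop <- net$pop
  cmp <- pop$compartments
  n <- nrow(cmp)
  area_cm2 <- cmp$area_um2 * UM2_TO_CM2
  cap <- c_m * area_cm2 * 1e3                       # nF
  lkdens <- if (is.null(g_lk_comp)) rep(net$g_lk, n) else g_lk_comp
  stopifnot(length(lkdens) == n)
  glk <- lkdens * area_cm2 * 1e3                    # uS

  gax <- numeric(n)
  same_neuron <- cmp$neuron[-n] == cmp$neuron[-1]
  i1 <- which(same_neuron)
  gax[i1] <- axial_conductance(cmp$length[i1], cmp$mean_diameter[i1],
                               cmp$length[i1 + 1], cmp$mean_diameter[i1 + 1],
                               R_i)

  gj <- net$gap_junctions
  if (nrow(gj)) {
    soma <- pop$soma_positions
    ca <- vapply(seq_len(nrow(gj)), function(k)
      axon_comp_index(pop, gj$caudal[k], gj$d_gj[k]), numeric(1))
    ro <- vapply(seq_len(nrow(gj)), function(k)
      axon_comp_index(pop, gj$rostral[k],
                      gj$coordinate[k] - soma[gj$rostral[k] + 1L]),
      numeric(1))
    gjg <- 1e6 / (gj$resistance * 1e6)              # MOhm -> uS
    gj_idx <- data.frame(a = as.integer(ca), b = as.integer(ro), g = gjg)
  } else {
    gj_idx <- data.frame(a = integer(0), b = integer(0), g = numeric(0))
  }

  ii <- c(i1, i1 + 1L, gj_idx$a, gj_idx$b)
  jj <- c(i1 + 1L, i1, gj_idx$b, gj_idx$a)
  xx <- -c(gax[i1], gax[i1], gj_idx$g, gj_idx$g)
  dsum <- numeric(n)
  tab <- tapply(-xx, ii, sum)
  dsum[as.integer(names(tab))] <- tab
  G <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, glk + dsum), dims = c(n, n))
  structure(list(ncomp = n, cap = cap, gax = gax, glk = glk,
                 gj = gj_idx, G = G, area_cm2 = area_cm2,
                 compartments = cmp, R_i = R_i, c_m = c_m),
            class = "din_system")
}

#' Steady-state passive solution
#'
#' Solves `G dV = I` exactly for the voltage deflection of every compartment
#' under constant injected currents (passive membrane). Deflections are
#' relative to rest and linear in the currents.
#'
#' @param sys a [assemble] result.
#' @param I injected current: either a full per-compartment vector (nA) or a
#'   matrix (one column per injection pattern).
#' @return deflections, mV (vector or matrix matching `I`).
#' @export
steady_state_solve <- function(sys, I) {
  stopifnot(inherits(sys, "din_system"))
  if (is.matrix(I)) stopifnot(nrow(I) == sys$ncomp)
  else stopifnot(length(I) == sys$ncomp)
  out <- Matrix::solve(sys$G, I)
  if (is.matrix(I)) as.matrix(out) else as.numeric(out)
}

#' Stimulation protocol
#'
#' One row per current step. Sites: `"soma"` or a numeric axon arc distance
#' (um from the soma along the axon).
#'
#' @param neuron 0-based neuron ids.
#' @param amp_pA step amplitudes, pA.
#' @param onset_ms,dur_ms onset (relative to protocol time zero) and
#'   duration, ms.
#' @param site `"soma"` (default) or numeric axon arc, recycled.
#' @export
stimulus_protocol <- function(neuron, amp_pA, onset_ms, dur_ms,
                              site = "soma") {
  stopifnot(all(dur_ms >= 0))
  data.frame(neuron = neuron, amp_pA = amp_pA, onset_ms = onset_ms,
             dur_ms = dur_ms, site = rep_len(as.character(site),
                                             length(neuron)),
             stringsAsFactors = FALSE)
}

#' Recording probes
#' @param neuron 0-based neuron ids.
#' @param site `"soma"` or numeric axon arc (um), recycled.
#' @export
probe_set <- function(neuron, site = "soma") {
  data.frame(neuron = neuron,
             site = rep_len(as.character(site), length(neuron)),
             stringsAsFactors = FALSE)
}

site_to_comp <- function(pop, neuron, site) {
  vapply(seq_along(neuron), function(k) {
    if (site[k] == "soma") soma_comp_index(pop, neuron[k])
    else axon_comp_index(pop, neuron[k], as.numeric(site[k]))
  }, numeric(1))
}

registry_rate_matrix <- function(registry) {
  g <- function(kind, i) registry[[kind]]$gates[[i]]
  rows <- list(g("ca", 1)$alpha, g("ca", 1)$beta, g("ca", 1)$beta_high,
               g("kf", 1)$alpha, g("kf", 1)$beta,
               g("ks", 1)$alpha, g("ks", 1)$beta,
               g("na", 1)$alpha, g("na", 1)$beta,
               g("na", 2)$alpha, g("na", 2)$beta)
  do.call(rbind, lapply(rows, function(p) c(p$A, p$B, p$C, p$D, p$E)))
}

#' Integrate the network dynamics
#'
#' Advances the full network by an implicit first-order (backward-Euler)
#' voltage step with staggered exponential gate updates (see the compiled
#' integrator). The model starts at `V = e_lk` with gates at steady state
#' and runs a settling period before protocol time zero; recorded traces
#' start at `t = 0`.
#'
#' @param net a [network_model].
#' @param stim a [stimulus_protocol] (may have zero rows).
#' @param t_stop simulated protocol time, ms.
#' @param probes a [probe_set]; default: every soma.
#' @param dt time step, ms (default 0.01 for active models, 0.1 passive).
#' @param densities per-compartment density matrix from [realise_densities];
#'   by default realised from the network's density config (consumes RNG
#'   draws unless `noise_sd = 0`).
#' @param registry a [channel_registry].
#' @param ghk a [ghk_constants].
#' @param synapses optional synaptic drive from [synaptic_drive].
#' @param settle settling time before the protocol, ms (default 20).
#' @param record_dt recording interval, ms (default `dt`).
#' @param R_i intracellular resistivity, Ohm cm.
#' @return an object of class `din_simulation`: `time` (ms), `traces`
#'   (matrix, one column per probe, mV), `probes`, `dt`, and metadata.
#' @export
simulate_network <- function(net, stim = stimulus_protocol(integer(0),
                                                           numeric(0),
                                                           numeric(0),
                                                           numeric(0)),
                             t_stop = 100, probes = NULL, dt = NULL,
                             densities = NULL,
                             registry = channel_registry(),
                             ghk = ghk_constants(), synapses = NULL,
                             settle = 20, record_dt = NULL, R_i = 80) {
  stopifnot(inherits(net, "din_network"))
  active <- !net$passive
  if (is.null(dt)) dt <- if (active) 0.01 else 0.1
  stopifnot(dt > 0)
  if (is.null(record_dt)) record_dt <- dt
  record_every <- max(1L, as.integer(round(record_dt / dt)))
  pop <- net$pop
  if (is.null(probes)) probes <- probe_set(seq_len(pop$n) - 1L)
  if (is.null(densities))
    densities <- realise_densities(pop$compartments, net$density, registry,
                                   g_lk_base = net$g_lk)
  sys <- assemble(net, R_i = R_i,
                  g_lk_comp = densities[, "lk"])
  a3 <- sys$area_cm2 * 1e3
  zero <- numeric(sys$ncomp)
  cs <- list(ncomp = sys$ncomp, cap = sys$cap, gax = sys$gax,
             glk = sys$glk,
             gna = if (active) densities[, "na"] * a3 else zero,
             gkf = if (active) densities[, "kf"] * a3 else zero,
             gks = if (active) densities[, "ks"] * a3 else zero,
             pfca = if (active) densities[, "ca"] * a3 else zero,
             gja = sys$gj$a - 1L, gjb = sys$gj$b - 1L, gjg = sys$gj$g,
             e_na = registry$na$reversal_mV, e_k = registry$kf$reversal_mV,
             e_lk = registry$lk$reversal_mV)
  stim_comp <- if (nrow(stim)) site_to_comp(pop, stim$neuron, stim$site)
               else numeric(0)
  stim_list <- list(comp = as.integer(stim_comp) - 1L,
                    amp = stim$amp_pA * 1e-3,          # pA -> nA
                    onset = stim$onset_ms + settle,
                    dur = stim$dur_ms)
  nsteps <- as.integer(round((settle + t_stop) / dt))
  syn_list <- list()
  if (!is.null(synapses)) {
    g <- synapse_conductance_matrix(synapses, dt, nsteps, settle)
    syn_list <- list(comp = as.integer(site_to_comp(pop, synapses$targets,
                                                    rep("soma",
                                                        length(synapses$targets)))) - 1L,
                     g = g, e_rev = synapses$e_rev)
  }
  probe_comp <- as.integer(site_to_comp(pop, probes$neuron, probes$site))
  res <- cpp_integrate(cs, registry_rate_matrix(registry),
                       c(ghk$F, ghk$R, ghk$T, ghk$Ca_internal,
                         ghk$Ca_external),
                       registry$ca$gates[[1]]$split_mV,
                       stim_list, syn_list, dt, nsteps,
                       registry$lk$reversal_mV,
                       probe_comp - 1L, record_every, active)
  if (isTRUE(res$diverged))
    stop("simulate_network: integration produced a non-finite state at t = ",
         res$diverged_at - settle, " ms (protocol time)")
  keep <- res$time >= settle - 1e-9
  tt <- res$time[keep] - settle
  tr <- res$traces[keep, , drop = FALSE]
  colnames(tr) <- paste0("n", probes$neuron, "_", probes$site)
  structure(list(time = tt, traces = tr, probes = probes, dt = dt,
                 settle = settle, v_final = res$v_final),
            class = "din_simulation")
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings separated by at least the refractory interval;
#' crossing times are linearly interpolated between samples.
#'
#' @param time time base, ms (strictly increasing, uniform).
#' @param v voltage trace, mV.
#' @param threshold detection threshold, mV (default 0).
#' @param refractory minimum separation, ms (default 3).
#' @return spike times, ms (possibly empty).
#' @export
detect_spikes <- function(time, v, threshold = 0, refractory = 3) {
  stopifnot(length(time) == length(v))
  if (length(v) < 2) return(numeric(0))
  up <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  tc <- time[up] + (time[up + 1] - time[up]) *
    (threshold - v[up]) / (v[up + 1] - v[up])
  out <- tc[1]
  for (t in tc[-1]) if (t - out[length(out)] >= refractory) out <- c(out, t)
  out
}

#' Spike times for every probe of a simulation
#' @param sim a [simulate_network] result.
#' @inheritParams detect_spikes
#' @return named list of spike-time vectors, one per probe column.
#' @export
spike_times <- function(sim, threshold = 0, refractory = 3) {
  stopifnot(inherits(sim, "din_simulation"))
  out <- lapply(seq_len(ncol(sim$traces)), function(j)
    detect_spikes(sim$time, sim$traces[, j], threshold, refractory))
  names(out) <- colnames(sim$traces)
  out
}

#' Write simulation traces to CSV
#' @param sim a [simulate_network] result.
#' @param path output path.
#' @export
write_traces_csv <- function(sim, path) {
  utils::write.csv(data.frame(time_ms = sim$time, sim$traces,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
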