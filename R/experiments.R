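# Measurement protocols: coupling coefficients, input resistance, firing
# classification, rebound, action-potential propagation and conduction
# velocity, channel-density sweeps, and whole-population stimulation.

#' Measure pairwise coupling coefficients (passive)
#'
#' In each of `n_runs` runs a source neuron is chosen at random (with
#' replacement) and constant hyperpolarising current is injected into its
#' soma; the steady-state deflection of every soma is obtained from the
#' exact passive solve, and the coupling coefficient of each target is its
#' deflection as a percentage of the source's deflection.
#'
#' @param net a [network_model] (treated as passive, uniform leak).
#' @param n_runs number of random-source runs (default 50).
#' @param current_pA injected current, pA (default -100; coefficients are
#'   invariant to amplitude and sign in the linear passive model).
#' @param R_i intracellular resistivity, Ohm cm.
#' @return data frame: `run`, `source`, `target`, `separation` (um between
#'   somata), `coefficient` (%).
#' @export
measure_coupling <- function(net, n_runs = 50, current_pA = -100, R_i = 80) {
  pop <- net$pop
  sys <- assemble(net, R_i = R_i)
  sources <- sample.int(pop$n, n_runs, replace = TRUE) - 1L
  uniq <- sort(unique(sources))
  I <- matrix(0, sys$ncomp, length(uniq))
  for (k in seq_along(uniq))
    I[soma_comp_index(pop, uniq[k]), k] <- current_pA * 1e-3
  dv <- steady_state_solve(sys, I)
  soma_rows <- vapply(seq_len(pop$n) - 1L, function(nn)
    soma_comp_index(pop, nn), numeric(1))
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    s <- sources[r]
    col <- match(s, uniq)
    vs <- dv[soma_rows[s + 1L], col]
    if (abs(vs) < 1e-12)
      stop("measure_coupling: zero source deflection")
    targets <- setdiff(seq_len(pop$n) - 1L, s)
    out[[r]] <- data.frame(
      run = r, source = s, target = targets,
      separation = abs(pop$soma_positions[targets + 1L] -
                       pop$soma_positions[s + 1L]),
      coefficient = 100 * dv[soma_rows[targets + 1L], col] / vs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distance-binned coupling-coefficient summary
#'
#' @param cc a [measure_coupling] result (rows may be pooled over networks).
#' @param breaks distance bin edges, um (default 50 um bins to 300 um);
#'   bins are half-open `[a, b)`.
#' @return data frame per bin: midpoint, median, quartiles, 5/95 percentiles
#'   and pair count.
#' @export
bin_coupling <- function(cc, breaks = seq(0, 300, by = 50)) {
  bin <- cut(cc$separation, breaks, right = FALSE)
  q <- function(p) tapply(cc$coefficient, bin, stats::quantile, probs = p,
                          na.rm = TRUE)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             midpoint = (breaks[-length(breaks)] + breaks[-1]) / 2,
             n = as.integer(table(bin)),
             q05 = as.numeric(q(0.05)), q25 = as.numeric(q(0.25)),
             median = as.numeric(q(0.5)), q75 = as.numeric(q(0.75)),
             q95 = as.numeric(q(0.95)))
}

#' Somatic input resistance
#'
#' Injects a small hyperpolarising step into one soma and returns the
#' steady-state deflection divided by the current. Active channels are
#' essentially closed under hyperpolarisation, so the exact passive solve is
#' used; per-compartment leak densities (with per-neuron noise) may be
#' supplied.
#'
#' @param net a [network_model].
#' @param neuron 0-based neuron id (default: the middle neuron).
#' @param current_pA step amplitude, pA (default -100).
#' @param g_lk_comp optional leak-density vector (mS/cm^2 per compartment).
#' @param R_i intracellular resistivity, Ohm cm.
#' @return input resistance, MOhm.
#' @export
input_resistance <- function(net, neuron = NULL, current_pA = -100,
                             g_lk_comp = NULL, R_i = 80) {
  pop <- net$pop
  if (is.null(neuron)) neuron <- (pop$n - 1L) %/% 2L
  sys <- assemble(net, R_i = R_i, g_lk_comp = g_lk_comp)
  I <- numeric(sys$ncomp)
  idx <- soma_comp_index(pop, neuron)
  I[idx] <- current_pA * 1e-3
  dv <- steady_state_solve(sys, I)
  dv[idx] / (current_pA * 1e-3)                     # mV/nA = MOhm
}

#' Classify the firing response to step currents
#'
#' Runs a step-current series into one soma and counts somatic spikes per
#' level. The neuron is `single`-firing if every suprathreshold level
#' produces exactly one spike during the step; `repetitive` if any level
#' produces more; `unstable` if spikes occur before the step or persist
#' beyond it; `none` if no level reaches threshold.
#'
#' @param net a [network_model].
#' @param neuron 0-based neuron id.
#' @param levels_pA step amplitudes, pA (default 50, 100, 200, 300).
#' @param duration_ms step duration, ms (default 200).
#' @param densities realised density matrix (recommended, so the same
#'   instantiation is reused across levels); `NULL` draws one per level.
#' @param ... passed to [simulate_network].
#' @return list with `label`, per-level `spike_counts`, and `spikes`.
#' @export
classify_firing <- function(net, neuron, levels_pA = c(50, 100, 200, 300),
                            duration_ms = 200, densities = NULL, ...) {
  onset <- 20
  counts <- integer(length(levels_pA))
  all_spk <- vector("list", length(levels_pA))
  pre <- post <- FALSE
  for (k in seq_along(levels_pA)) {
    stim <- stimulus_protocol(neuron, levels_pA[k], onset, duration_ms)
    sim <- simulate_network(net, stim, t_stop = onset + duration_ms + 50,
                            probes = probe_set(neuron),
                            densities = densities, ...)
    spk <- spike_times(sim)[[1]]
    all_spk[[k]] <- spk
    counts[k] <- sum(spk >= onset & spk <= onset + duration_ms)
    pre <- pre || any(spk < onset)
    post <- post || any(spk > onset + duration_ms + 10)
  }
  label <- if (pre || post) "unstable"
  else if (all(counts == 0)) "none"
  else if (all(counts[counts > 0] == 1)) "single"
  else "repetitive"
  list(label = label, levels_pA = levels_pA, spike_counts = counts,
       spikes = all_spk)
}

#' Rheobase of a neuron in the network
#'
#' Smallest step current (scanned on `levels_pA`, assumed sorted) that
#' elicits at least one somatic spike during a 200 ms step. Bisection over
#' the level grid.
#'
#' @param net a [network_model].
#' @param neuron 0-based id.
#' @param levels_pA candidate amplitudes, pA (default 10-300 in 10 pA
#'   increments).
#' @param duration_ms step duration, ms.
#' @param densities realised density matrix to reuse across levels.
#' @param ... passed to [simulate_network].
#' @return rheobase, pA (`NA` if no level fires).
#' @export
find_rheobase <- function(net, neuron, levels_pA = seq(10, 300, by = 10),
                          duration_ms = 200, densities = NULL, ...) {
  fires <- function(amp) {
    stim <- stimulus_protocol(neuron, amp, 10, duration_ms)
    sim <- simulate_network(net, stim, t_stop = duration_ms + 20,
                            probes = probe_set(neuron),
                            densities = densities, ...)
    length(spike_times(sim)[[1]]) > 0
  }
  lo <- 1L; hi <- length(levels_pA)
  if (!fires(levels_pA[hi])) return(NA_real_)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (fires(levels_pA[mid])) hi <- mid else lo <- mid + 1L
  }
  levels_pA[hi]
}

#' Rebound-firing test
#'
#' Delivers a short hyperpolarising pulse during a longer depolarising
#' background step and checks for a spike within a window after pulse
#' offset; the same pulse delivered from rest must not fire.
#'
#' @param net a [network_model].
#' @param neuron 0-based id.
#' @param background_pA depolarising background, pA (default 100).
#' @param pulse_pA hyperpolarising pulse, pA (default -200).
#' @param pulse_ms pulse duration, ms (default 20).
#' @param window_ms rebound window after pulse offset, ms (default 20).
#' @param densities realised density matrix.
#' @param ... passed to [simulate_network].
#' @return list: `rebound` flag, `spike_after_pulse`, `fires_from_rest`,
#'   spike times of both runs.
#' @export
rebound_test <- function(net, neuron, background_pA = 100, pulse_pA = -200,
                         pulse_ms = 20, window_ms = 20, densities = NULL,
                         ...) {
  bg_on <- 20; bg_dur <- 280; p_on <- 150
  run <- function(bg) {
    rows <- stimulus_protocol(
      neuron = c(if (bg) neuron else integer(0), neuron),
      amp_pA = c(if (bg) background_pA else numeric(0), pulse_pA),
      onset_ms = c(if (bg) bg_on else numeric(0), p_on),
      dur_ms = c(if (bg) bg_dur else numeric(0), pulse_ms))
    sim <- simulate_network(net, rows, t_stop = bg_on + bg_dur + 20,
                            probes = probe_set(neuron),
                            densities = densities, ...)
    spike_times(sim)[[1]]
  }
  spk_bg <- run(TRUE)
  spk_rest <- run(FALSE)
  off <- p_on + pulse_ms
  hit <- pulse_pA != 0 &&
    any(spk_bg > off & spk_bg <= off + window_ms)
  rest_hit <- any(spk_rest > p_on & spk_rest <= off + window_ms)
  list(rebound = hit && !rest_hit, spike_after_pulse = hit,
       fires_from_rest = rest_hit, spikes_background = spk_bg,
       spikes_rest = spk_rest)
}

#' Default propagation probe arcs
#'
#' Soma plus axon probes every `fine_spacing` um over the proximal region
#' and every `coarse_spacing` um beyond, out to the axon tip.
#' @param axon_length axon length, um.
#' @param fine_to extent of the finely probed region, um (default 400).
#' @param fine_spacing,coarse_spacing probe spacings, um.
#' @export
propagation_probe_arcs <- function(axon_length, fine_to = 400,
                                   fine_spacing = 20, coarse_spacing = 100) {
  c(seq(fine_spacing, min(fine_to, axon_length), by = fine_spacing),
    if (axon_length > fine_to)
      seq(fine_to + coarse_spacing, axon_length, by = coarse_spacing))
}

#' Test action-potential propagation along one axon
#'
#' A brief suprathreshold pulse is injected into one soma and the voltage is
#' recorded at the soma and along its axon. Propagation succeeds if a spike
#' is detected at the most distal probe within `deadline_ms`.
#'
#' @param net a [network_model].
#' @param neuron 0-based id of the stimulated neuron.
#' @param pulse_pA pulse amplitude, pA (default 500).
#' @param pulse_ms pulse duration, ms (default 5).
#' @param deadline_ms detection deadline, ms (default 50).
#' @param probe_arcs axon probe positions, um; default
#'   [propagation_probe_arcs].
#' @param densities realised density matrix.
#' @param ... passed to [simulate_network].
#' @return object of class `propagation_result`: `success`, data frame
#'   `probes` (`arc` um, `t_spike` ms, `NA` if none), spike times at soma.
#' @export
propagation_test <- function(net, neuron, pulse_pA = 500, pulse_ms = 5,
                             deadline_ms = 50, probe_arcs = NULL,
                             densities = NULL, ...) {
  al <- net$pop$morphology$axon_length
  if (is.null(probe_arcs)) probe_arcs <- propagation_probe_arcs(al)
  pr <- rbind(probe_set(neuron, "soma"),
              probe_set(rep(neuron, length(probe_arcs)), probe_arcs))
  stim <- stimulus_protocol(neuron, pulse_pA, 5, pulse_ms)
  sim <- simulate_network(net, stim, t_stop = deadline_ms + 10, probes = pr,
                          densities = densities, ...)
  spk <- spike_times(sim)
  first <- vapply(spk, function(s)
    if (length(s)) s[1] else NA_real_, numeric(1))
  probes_df <- data.frame(arc = probe_arcs, t_spike = first[-1])
  distal <- probes_df$t_spike[nrow(probes_df)]
  structure(list(success = is.finite(distal) && distal <= deadline_ms + 5,
                 probes = probes_df, soma_spikes = spk[[1]],
                 neuron = neuron),
            class = "propagation_result")
}

#' Conduction velocity over an axon region
#'
#' Linear fit of probe distance against first-spike time over the probes in
#' `region`; the slope converts um/ms to m/s.
#'
#' @param presult a [propagation_test] result.
#' @param region arc interval, um (default the proximal 0-400 um).
#' @return velocity, m/s.
#' @export
conduction_velocity <- function(presult, region = c(0, 400)) {
  p <- presult$probes
  sel <- p$arc >= region[1] & p$arc <= region[2] & is.finite(p$t_spike)
  if (sum(sel) < 2)
    stop("conduction_velocity: fewer than 2 probes with spikes in region ",
         "(undefined velocity)")
  fit <- stats::lm(arc ~ t_spike, data = p[sel, ])
  unname(stats::coef(fit)[2]) / 1000                # um/ms -> m/s
}

#' Channel-density parameter sweep
#'
#' Evaluates firing classification, propagation and rebound at every point
#' of a multiplier grid, in the full coupled-network scenario with fresh
#' layout and density noise per replicate.
#'
#' @param pop a [build_population] result.
#' @param scheme a [layout_scheme].
#' @param grid named list of multiplier vectors per channel kind; defaults
#'   to the packaged tested multipliers (a large grid — scale down for
#'   interactive use).
#' @param replicates evaluations per grid point (default 10).
#' @param g_lk leak density in force, mS/cm^2 (default 0.125, coupled mode).
#' @param noise_sd density noise (default 0.05).
#' @param overrides regional overrides applied at every point.
#' @param levels_pA step levels for the firing classification, pA.
#' @param pulse_pA propagation test pulse, pA.
#' @param ... passed to [simulate_network] (e.g. `dt`).
#' @return data frame: multipliers, `fraction_single`,
#'   `fraction_propagating`, `fraction_rebound`.
#' @export
density_sweep <- function(pop, scheme = layout_scheme(),
                          grid = NULL, replicates = 10, g_lk = 0.125,
                          noise_sd = 0.05, overrides = list(),
                          levels_pA = c(50, 100, 200, 300),
                          pulse_pA = 500, ...) {
  if (is.null(grid)) {
    reg <- channel_registry()
    grid <- attr(reg, "multipliers_tested")
  }
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    mult <- unlist(pts[i, , drop = FALSE])
    single <- propag <- reb <- logical(replicates)
    for (r in seq_len(replicates)) {
      gj <- generate_gap_junctions(pop, scheme)
      net <- network_model(pop, gj,
                           density_config(mult, noise_sd, overrides),
                           g_lk = g_lk)
      dens <- realise_densities(pop$compartments, net$density,
                                g_lk_base = g_lk)
      nid <- sample.int(pop$n, 1) - 1L
      cl <- classify_firing(net, nid, levels_pA = levels_pA,
                            densities = dens, ...)
      single[r] <- cl$label == "single"
      propag[r] <- propagation_test(net, nid, pulse_pA = pulse_pA,
                                    densities = dens, ...)$success
      reb[r] <- rebound_test(net, nid, densities = dens, ...)$rebound
    }
    res[[i]] <- cbind(pts[i, , drop = FALSE],
                      data.frame(fraction_single = mean(single),
                                 fraction_propagating = mean(propag),
                                 fraction_rebound = mean(reb)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Population step stimulation
#'
#' Injects the same step current into every soma and summarises the
#' population response: per-neuron firing frequency from inter-spike
#' intervals within the step (neurons with fewer than two spikes contribute
#' none), whether firing is repetitive through the step, and a voltage-based
#' synchrony index (ratio of the temporal variance of the population-mean
#' trace to the mean single-neuron variance, square-rooted; 1 for identical
#' traces, near 0 for asynchronous firing).
#'
#' @param net a [network_model].
#' @param level_pA common step amplitude, pA.
#' @param duration_ms step duration, ms (default 200).
#' @param densities realised density matrix.
#' @param ... passed to [simulate_network].
#' @return list: `spikes` (per neuron), `mean_frequency` (Hz), `synchrony`,
#'   `repetitive` (logical: majority of neurons fire >= 3 spikes spanning
#'   the step), `fraction_firing`.
#' @export
population_step <- function(net, level_pA, duration_ms = 200,
                            densities = NULL, ...) {
  n <- net$pop$n
  onset <- 20
  stim <- stimulus_protocol(seq_len(n) - 1L, rep(level_pA, n),
                            rep(onset, n), rep(duration_ms, n))
  sim <- simulate_network(net, stim, t_stop = onset + duration_ms + 30,
                          densities = densities, ...)
  spk <- spike_times(sim)
  in_step <- lapply(spk, function(s) s[s >= onset & s <= onset + duration_ms])
  freq <- vapply(in_step, function(s)
    if (length(s) >= 2) 1000 * (length(s) - 1) / (s[length(s)] - s[1])
    else NA_real_, numeric(1))
  sustained <- vapply(in_step, function(s)
    length(s) >= 3 && s[length(s)] >= onset + 0.8 * duration_ms, logical(1))
  win <- sim$time >= onset & sim$time <= onset + duration_ms
  V <- sim$traces[win, , drop = FALSE]
  vbar <- rowMeans(V)
  chi2 <- stats::var(vbar) / mean(apply(V, 2, stats::var))
  list(spikes = in_step,
       mean_frequency = mean(freq, na.rm = TRUE),
       synchrony = sqrt(max(0, chi2)),
       repetitive = mean(sustained) > 0.5,
       fraction_firing = mean(vapply(in_step, length, numeric(1)) > 0))
}

#' Find the population firing threshold
#'
#' Smallest common step current on a level grid at which the whole coupled
#' population fires repetitively (see [population_step]).
#'
#' @param net a [network_model].
#' @param levels_pA sorted candidate levels, pA.
#' @param densities realised density matrix.
#' @param ... passed to [population_step].
#' @return list: `level_pA` (`NA` if never repetitive), `result`.
#' @export
find_population_threshold <- function(net, levels_pA = seq(20, 200, by = 20),
                                      densities = NULL, ...) {
  for (lv in levels_pA) {
    r <- population_step(net, lv, densities = densities, ...)
    if (r$repetitive && r$fraction_firing >= 0.9)
      return(list(level_pA = lv, result = r))
  }
  list(level_pA = NA_real_, result = NULL)
}

#' Packaged experimental coupling-coefficient reference
#'
#' Distance-binned summary of the coupling coefficients reported for
#' neighbouring reticulospinal neurons in paired recordings (median roughly
#' 10-15% for somata 0-50 um apart, falling to about 5% at 150-200 um),
#' packaged for overlay on model coupling profiles.
#'
#' @return data frame: `distance_lo`, `distance_hi` (um), `cc_lo`, `cc_hi`
#'   (%), `source`.
#' @export
coupling_reference <- function() {
  utils::read.csv(system.file("extdata", "coupling_reference.csv",
                              package = "axonet"),
                  stringsAsFactors = FALSE)
}
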