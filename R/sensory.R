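# Stochastic sensory-pathway (tIN) spike-time model of head-skin drive, the
# glutamatergic synapse onto the dIN population, and the recruitment
# experiment.

#' Sensory interneuron (tIN) spike model
#'
#' Spike counts are drawn from `p(N = n | S = s)` where `s` is the skin
#' stimulus strength normalised so that 100% is the swimming threshold. The
#' single-spike probability is anchored at `p(1|95) = 0.5`, `p(1|100) = 1`,
#' and `p(1|s > 120) = 0.3` with piecewise-linear interpolation: below 100%
#' the remaining mass is on zero spikes (rising from 0 at `s_floor`); above
#' 100% zero-spike mass vanishes and the remainder is multi-spike, with
#' counts 2-5 weighted by `multi_weights`. Spike times are per-index
#' normals `t_k ~ N(mu_k, sigma_k)`, sorted ascending.
#'
#' @param s_floor stimulus (%) below which no spikes occur (default 83,
#'   about two threshold standard deviations below the mean threshold).
#' @param multi_weights weights over 2-5 spikes for the multi-spike mass.
#' @param mu_k,sigma_k per-spike-index timing means and SDs, ms.
#' @param population number of tINs driving the population (default 20).
#' @return an object of class `tin_model`.
#' @export
tin_model <- function(s_floor = 83,
                      multi_weights = c(0.5, 0.3, 0.15, 0.05),
                      mu_k = 5 + 10 * (0:4), sigma_k = rep(2, 5),
                      population = 20) {
  stopifnot(s_floor < 95, all(multi_weights >= 0), sum(multi_weights) > 0,
            length(mu_k) == length(sigma_k), all(sigma_k >= 0),
            population >= 1)
  structure(list(s_floor = s_floor,
                 multi_weights = multi_weights / sum(multi_weights),
                 mu_k = mu_k, sigma_k = sigma_k, population = population),
            class = "tin_model")
}

p_single <- function(model, s) {
  ifelse(s <= model$s_floor, 0,
  ifelse(s <= 95, 0.5 * (s - model$s_floor) / (95 - model$s_floor),
  ifelse(s <= 100, 0.5 + 0.5 * (s - 95) / 5,
  ifelse(s <= 120, 1 - 0.7 * (s - 100) / 20, 0.3))))
}

#' Spike-count distribution of a tIN
#'
#' @param model a [tin_model].
#' @param s stimulus strength, % of swimming threshold.
#' @return named numeric: probability of firing 0-5 spikes (sums to 1).
#' @export
spike_count_distribution <- function(model, s) {
  stopifnot(s >= 0)
  p1 <- p_single(model, s)
  if (s <= 100) {
    p <- c(1 - p1, p1, rep(0, length(model$multi_weights)))
  } else {
    p <- c(0, p1, (1 - p1) * model$multi_weights)
  }
  stats::setNames(p, as.character(seq_along(p) - 1L))
}

#' Sample a tIN spike count
#' @inheritParams spike_count_distribution
#' @return integer spike count (uses the session RNG).
#' @export
sample_spike_count <- function(model, s) {
  p <- spike_count_distribution(model, s)
  sample(seq_along(p) - 1L, 1, prob = p)
}

#' Sample tIN spike times
#'
#' @param model a [tin_model].
#' @param n spike count (must not exceed the configured spike-index table).
#' @return sorted spike times, ms (empty for `n = 0`).
#' @export
sample_spike_times <- function(model, n) {
  stopifnot(n >= 0)
  if (n > length(model$mu_k))
    stop("sample_spike_times: n exceeds the configured spike-index table")
  if (n == 0) return(numeric(0))
  sort(stats::rnorm(n, model$mu_k[seq_len(n)], model$sigma_k[seq_len(n)]))
}

#' Sample the spike trains of the whole tIN population
#' @param model a [tin_model].
#' @param s stimulus strength, %.
#' @return list of spike-time vectors, one per tIN.
#' @export
sample_tin_population <- function(model, s) {
  lapply(seq_len(model$population), function(i)
    sample_spike_times(model, sample_spike_count(model, s)))
}

#' Glutamatergic synapse specification
#'
#' Difference-of-exponentials conductance transient
#' `g(t) = g_peak * (exp(-t/tau_decay) - exp(-t/tau_rise)) / norm`,
#' normalised so the maximum equals `g_peak`.
#'
#' @param tau_rise,tau_decay time constants, ms (defaults 1 and 4).
#' @param peak_nS peak conductance per tIN-dIN contact, nS (default 0.4;
#'   see [calibrate_synapse_peak]).
#' @param e_rev reversal potential, mV (default 0, glutamatergic).
#' @export
synapse_spec <- function(tau_rise = 1, tau_decay = 4, peak_nS = 0.4,
                         e_rev = 0) {
  stopifnot(tau_rise > 0, tau_decay > tau_rise, peak_nS >= 0)
  tpk <- tau_rise * tau_decay / (tau_decay - tau_rise) *
    log(tau_decay / tau_rise)
  norm <- exp(-tpk / tau_decay) - exp(-tpk / tau_rise)
  structure(list(tau_rise = tau_rise, tau_decay = tau_decay,
                 peak_nS = peak_nS, e_rev = e_rev, norm = norm),
            class = "synapse_spec")
}

#' Synaptic drive onto the dIN population
#'
#' Every tIN contacts every dIN with an identical [synapse_spec] (same time
#' constants, peak and reversal). `trains` may be a single set of tIN spike
#' trains — all targets then share one summed conductance waveform — or a
#' list with one train set per target, giving each dIN its own stochastic
#' realisation of the drive (see [sample_population_drive]).
#'
#' @param trains list of tIN spike trains (ms), e.g.
#'   [sample_tin_population], or a list of such lists, one per target.
#' @param synapse a [synapse_spec].
#' @param targets 0-based dIN ids receiving the drive.
#' @param per_target logical: interpret `trains` as one train set per
#'   target.
#' @return an object of class `synaptic_drive` consumed by
#'   [simulate_network].
#' @export
synaptic_drive <- function(trains, synapse, targets, per_target = FALSE) {
  events <- if (per_target) {
    stopifnot(length(trains) == length(targets))
    lapply(trains, function(tr) sort(unlist(tr)))
  } else {
    rep(list(sort(unlist(trains))), length(targets))
  }
  structure(list(events = events, synapse = synapse,
                 targets = targets, e_rev = synapse$e_rev),
            class = "synaptic_drive")
}

#' Per-target stochastic drive for the whole population
#'
#' Samples an independent realisation of the 20-tIN spike-train set for
#' every target dIN, modelling heterogeneity of the synaptic input each
#' cell receives at a given stimulus.
#'
#' @param tin a [tin_model].
#' @param s stimulus strength, %.
#' @param synapse a [synapse_spec].
#' @param targets 0-based dIN ids.
#' @export
sample_population_drive <- function(tin, s, synapse, targets) {
  synaptic_drive(lapply(targets, function(i) sample_tin_population(tin, s)),
                 synapse, targets, per_target = TRUE)
}

# conductance matrix (targets x steps, uS) sampled on the solver grid;
# event times are protocol times and get shifted by the settling period
synapse_conductance_matrix <- function(drive, dt, nsteps, settle) {
  syn <- drive$synapse
  tt <- (seq_len(nsteps) - 1L) * dt - settle
  wave <- function(events) {
    g <- numeric(nsteps)
    for (te in events) {
      rel <- tt - te
      on <- rel > 0 & rel < 10 * syn$tau_decay
      g[on] <- g[on] + (exp(-rel[on] / syn$tau_decay) -
                        exp(-rel[on] / syn$tau_rise)) / syn$norm
    }
    g * syn$peak_nS * 1e-3                           # nS -> uS
  }
  do.call(rbind, lapply(drive$events, wave))
}

#' Recruitment of the dIN population by sensory drive
#'
#' For each stimulus level and replicate, samples an independent tIN
#' spike-train realisation for every dIN, converts them to synaptic
#' conductance waveforms on the somata, integrates the network, and records
#' the fraction of dINs firing at least one spike.
#'
#' @param net a [network_model] (coupled or uncoupled variant).
#' @param tin a [tin_model].
#' @param synapse a [synapse_spec].
#' @param stimuli stimulus levels, % (default 5 evenly spaced levels,
#'   80-100 in steps of 5, resolving the transition region around the
#'   swimming threshold; even spacing keeps the slope quantisation of the
#'   grid identical wherever the recruitment jump lands).
#' @param replicates replicates per level (default 3).
#' @param t_stop simulated time per trial, ms (default 80, covering the
#'   spike-time table).
#' @param ... passed to [simulate_network].
#' @return data frame: `stimulus`, `replicate`, `fraction` of dINs firing.
#' @export
recruitment_experiment <- function(net, tin = tin_model(),
                                   synapse = synapse_spec(),
                                   stimuli = seq(80, 100, by = 5),
                                   replicates = 3, t_stop = 80, ...) {
  n <- net$pop$n
  out <- list()
  for (s in stimuli) {
    for (r in seq_len(replicates)) {
      drive <- sample_population_drive(tin, s, synapse, seq_len(n) - 1L)
      sim <- simulate_network(net, t_stop = t_stop, synapses = drive, ...)
      spk <- spike_times(sim)
      out[[length(out) + 1L]] <-
        data.frame(stimulus = s, replicate = r,
                   fraction = mean(vapply(spk, length, numeric(1)) > 0))
    }
  }
  do.call(rbind, out)
}

#' Maximum slope of a recruitment curve
#'
#' Steepness of the mean fraction-recruited versus stimulus curve
#' (max of successive differences divided by the stimulus increment).
#'
#' @param rec a [recruitment_experiment] result.
#' @return max slope, fraction per % stimulus.
#' @export
recruitment_steepness <- function(rec) {
  m <- tapply(rec$fraction, rec$stimulus, mean)
  s <- as.numeric(names(m))
  o <- order(s)
  max(diff(m[o]) / diff(s[o]))
}

#' Calibrate the synaptic peak conductance
#'
#' Smallest peak conductance on a candidate grid for which the
#' threshold-level stimulus (`s = 100`) recruits at least `target_fraction`
#' of the coupled population (single replicate per candidate; the value is
#' recorded in configs rather than hard-coded).
#'
#' @param net the coupled [network_model].
#' @param tin a [tin_model].
#' @param peaks_nS candidate peak conductances, nS.
#' @param target_fraction required recruited fraction (default 0.9).
#' @param ... passed to [simulate_network].
#' @return peak conductance, nS (`NA` if no candidate suffices).
#' @export
calibrate_synapse_peak <- function(net, tin = tin_model(),
                                   peaks_nS = seq(0.2, 1.2, by = 0.2),
                                   target_fraction = 0.9, ...) {
  n <- net$pop$n
  for (p in peaks_nS) {
    drive <- sample_population_drive(tin, 100, synapse_spec(peak_nS = p),
                                     seq_len(n) - 1L)
    sim <- simulate_network(net, t_stop = 80, synapses = drive, ...)
    spk <- spike_times(sim)
    if (mean(vapply(spk, length, numeric(1)) > 0) >= target_fraction)
      return(p)
  }
  NA_real_
}
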