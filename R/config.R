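# Experiment configuration, seed handling, the final-model builder, and the
# thin command-line entry point used by inst/cli/axonet.R.

#' Default experiment configuration
#'
#' The packaged defaults reproduce the chosen final model: 30 neurons at
#' 10 um spacing; density gap-junction layout (0.015 um^-1 over the first
#' 50 um of each axon, 1 um bins, at most 6 partners per bin, 600 MOhm);
#' chosen channel multipliers (Na x3, others x1) with 5% per-neuron density
#' noise and the initial-segment overrides (Na x5, K x0.5 over 20-70 um);
#' coupled-mode leak 0.125 mS/cm^2 (0.25 uncoupled).
#'
#' @return nested named list (schema version 1).
#' @export
default_config <- function() {
  list(
    schema_version = 1,
    morphology = list(soma_area = 1000, axon_diameter = 0.4,
                      axon_length = 1500, hillock_lengths = c(5, 5),
                      hillock_proximal_diameter = 2.0),
    discretisation = list(hillock = 5, axon_proximal = 5, axon_switch = 400,
                          axon_distal = 100),
    population = list(n = 30, spacing = 10),
    layout = list(variant = "density", probability_density = 0.015,
                  probability = 0.5, min_dist = 0, max_dist = 50,
                  bin_width = 1, max_neighbours = 6, fixed_dist = 25,
                  resistance = 600),
    channels = list(multipliers = list(ca = 1.0, na = 3.0, kf = 1.0,
                                       ks = 1.0, lk = 1.0),
                    noise_sd = 0.05,
                    initial_segment = list(interval = c(20, 70),
                                           na_factor = 5, k_factor = 0.5),
                    g_lk_coupled = 0.125, g_lk_uncoupled = 0.25),
    solver = list(dt_active = 0.01, dt_passive = 0.1, settle = 20,
                  R_i = 80),
    sensory = list(s_floor = 83,
                   multi_weights = c(0.5, 0.3, 0.15, 0.05),
                   mu_k = 5 + 10 * (0:4), sigma_k = rep(2, 5),
                   population = 20,
                   synapse = list(tau_rise = 1, tau_decay = 4,
                                  peak_nS = 0.4, e_rev = 0)))
}

merge_validate <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("load_config: unknown key", if (length(unknown) > 1) "s", " ",
         paste0("'", path, unknown, "'", collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_validate(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

validate_config <- function(cfg) {
  m <- cfg$morphology
  if (m$axon_diameter <= 0 || m$soma_area <= 0 || m$axon_length <= 0)
    stop("config: morphology dimensions must be positive")
  if (cfg$population$n < 1) stop("config: population.n must be >= 1")
  if (cfg$layout$min_dist >= cfg$layout$max_dist)
    stop("config: layout.min_dist must be below layout.max_dist")
  if (any(unlist(cfg$channels$multipliers) < 0))
    stop("config: channel multipliers must be non-negative")
  if (cfg$solver$dt_active <= 0 || cfg$solver$dt_passive <= 0)
    stop("config: solver time steps must be positive")
  cfg
}

#' Load an experiment configuration
#'
#' Reads a YAML file, fills every missing entry from [default_config],
#' rejects unknown keys (naming the offending key), and validates values.
#' An empty file yields the full defaults.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(merge_validate(default_config(), user))
}

#' Save a configuration to YAML
#' @param cfg configuration list.
#' @param path output path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Derive labelled child seeds from one master seed
#'
#' One master seed spawns a named set of independent child seeds (layout,
#' density noise, protocol, sensory, ...) so that sub-experiments are
#' individually reproducible.
#'
#' @param master integer master seed.
#' @param labels character vector of consumer labels.
#' @return named integer vector of seeds (all below 2^31).
#' @export
derive_seeds <- function(master, labels) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(labels)),
                  labels)
}

config_population <- function(cfg) {
  build_population(cfg$population$n, cfg$population$spacing,
                   din_morphology(cfg$morphology$soma_area,
                                  cfg$morphology$axon_diameter,
                                  cfg$morphology$axon_length,
                                  cfg$morphology$hillock_lengths,
                                  cfg$morphology$hillock_proximal_diameter),
                   discretisation_rules(cfg$discretisation$hillock,
                                        cfg$discretisation$axon_proximal,
                                        cfg$discretisation$axon_switch,
                                        cfg$discretisation$axon_distal))
}

config_scheme <- function(cfg) {
  l <- cfg$layout
  layout_scheme(l$variant, l$probability_density, l$probability,
                l$min_dist, l$max_dist, l$bin_width, l$max_neighbours,
                l$fixed_dist, l$resistance)
}

#' Build the final coupled dIN network
#'
#' Convenience builder for the chosen model: density gap-junction layout,
#' chosen channel multipliers with per-neuron noise, initial-segment
#' overrides, and the coupled-mode leak. Uses the session RNG for the
#' layout; density noise is drawn later, when densities are realised.
#'
#' @param cfg configuration (default [default_config]).
#' @param coupled logical: `FALSE` deletes every junction while keeping the
#'   coupled-mode leak (the "junctions removed" comparison).
#' @param passive logical: build as a passive model.
#' @param g_lk overrides the leak density, mS/cm^2.
#' @param pop optional pre-built population (saves rebuilding in sweeps).
#' @return a [network_model].
#' @export
final_din_network <- function(cfg = default_config(), coupled = TRUE,
                              passive = FALSE, g_lk = NULL, pop = NULL) {
  if (is.null(pop)) pop <- config_population(cfg)
  gj <- generate_gap_junctions(pop, config_scheme(cfg))
  ch <- cfg$channels
  dens <- density_config(unlist(ch$multipliers), ch$noise_sd,
                         initial_segment_overrides(
                           ch$initial_segment$interval,
                           ch$initial_segment$na_factor,
                           ch$initial_segment$k_factor))
  # junction removal keeps the coupled-mode leak: the comparison isolates
  # the shunting effect of the junctions themselves
  if (is.null(g_lk)) g_lk <- ch$g_lk_coupled
  net <- network_model(pop, gj, dens, g_lk = g_lk, passive = passive)
  if (!coupled) net <- remove_gap_junctions(net)
  net
}

config_tin <- function(cfg) {
  s <- cfg$sensory
  tin_model(s$s_floor, s$multi_weights, s$mu_k, s$sigma_k, s$population)
}

config_synapse <- function(cfg) {
  s <- cfg$sensory$synapse
  synapse_spec(s$tau_rise, s$tau_decay, s$peak_nS, s$e_rev)
}

#' Run a named experiment and write its outputs
#'
#' Thin driver used by the command-line script: builds the model from the
#' configuration, runs one protocol, and writes CSV results plus a JSON
#' manifest (config hash, master seed, package version) sufficient to
#' reproduce the stochastic outputs byte-identically.
#'
#' @param cfg configuration list (see [load_config]).
#' @param subcommand one of `coupling`, `layout`, `fire`, `rebound`,
#'   `propagate`, `population-step`, `recruit`.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @return named list of written file paths, invisibly.
#' @export
run_experiment <- function(cfg, subcommand, out_dir, seed = 1) {
  known <- c("coupling", "layout", "fire", "rebound", "propagate",
             "population-step", "recruit")
  if (!subcommand %in% known)
    stop("run_experiment: unknown subcommand '", subcommand,
         "' (usage: one of ", paste(known, collapse = ", "), ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, c("layout", "noise", "protocol", "sensory"))
  files <- list()
  w <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    files[[name]] <<- p
  }
  set.seed(seeds[["layout"]])
  if (subcommand == "coupling") {
    pop <- config_population(cfg)
    net <- network_model(pop, generate_gap_junctions(pop,
                                                     config_scheme(cfg)),
                         g_lk = cfg$channels$g_lk_uncoupled, passive = TRUE)
    set.seed(seeds[["protocol"]])
    cc <- measure_coupling(net, R_i = cfg$solver$R_i)
    w(cc, "coupling_coefficients")
    w(bin_coupling(cc), "coupling_binned")
  } else if (subcommand == "layout") {
    pop <- config_population(cfg)
    net <- network_model(pop, generate_gap_junctions(pop,
                                                     config_scheme(cfg)),
                         g_lk = cfg$channels$g_lk_coupled)
    w(net$gap_junctions, "gap_junctions")
    st <- layout_statistics(net)
    jsonlite::write_json(st, file.path(out_dir, "layout_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    files$layout_stats <- file.path(out_dir, "layout_stats.json")
  } else {
    net <- final_din_network(cfg)
    set.seed(seeds[["noise"]])
    dens <- realise_densities(net$pop$compartments, net$density,
                              g_lk_base = net$g_lk)
    set.seed(seeds[["protocol"]])
    mid <- (net$pop$n - 1L) %/% 2L
    if (subcommand == "fire") {
      cl <- classify_firing(net, mid, densities = dens,
                            dt = cfg$solver$dt_active)
      w(data.frame(level_pA = cl$levels_pA, spikes = cl$spike_counts,
                   label = cl$label), "firing")
    } else if (subcommand == "rebound") {
      rb <- rebound_test(net, mid, densities = dens,
                         dt = cfg$solver$dt_active)
      w(data.frame(rebound = rb$rebound,
                   spike_after_pulse = rb$spike_after_pulse,
                   fires_from_rest = rb$fires_from_rest), "rebound")
    } else if (subcommand == "propagate") {
      pr <- propagation_test(net, mid, densities = dens,
                             dt = cfg$solver$dt_active)
      w(cbind(data.frame(success = pr$success), pr$probes), "propagation")
    } else if (subcommand == "population-step") {
      th <- find_population_threshold(net, densities = dens,
                                      dt = cfg$solver$dt_active)
      spikes <- if (is.null(th$result)) data.frame() else
        do.call(rbind, lapply(seq_along(th$result$spikes), function(i)
          if (length(th$result$spikes[[i]]))
            data.frame(neuron = i - 1L, t_spike = th$result$spikes[[i]])
          else NULL))
      w(spikes, "population_raster")
      jsonlite::write_json(list(threshold_pA = th$level_pA,
                                mean_frequency_Hz =
                                  th$result$mean_frequency,
                                synchrony = th$result$synchrony),
                           file.path(out_dir, "population_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      files$population_summary <- file.path(out_dir,
                                            "population_summary.json")
    } else if (subcommand == "recruit") {
      set.seed(seeds[["sensory"]])
      rec <- recruitment_experiment(net, config_tin(cfg),
                                    config_synapse(cfg), densities = dens,
                                    dt = cfg$solver$dt_active)
      w(rec, "recruitment")
    }
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(cfg, cfg_path)
  manifest <- list(subcommand = subcommand, master_seed = seed,
                   child_seeds = as.list(seeds),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package_version =
                     as.character(utils::packageVersion("axonet")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  files$manifest <- file.path(out_dir, "manifest.json")
  invisible(files)
}
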