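# Membrane current kinetics: leak, Hodgkin-Huxley type Na/Kf/Ks, and a
# Goldman-Hodgkin-Katz (constant-field) calcium current, plus channel-density
# configuration (multipliers, per-neuron noise, regional overrides).
#
# Unit bookkeeping used throughout the package:
#   voltage mV, time ms, rates ms^-1, conductance density mS/cm^2,
#   current density uA/cm^2, permeability cm/s, length um.

#' Rate-function parameters
#'
#' Parameters of the generic voltage-dependent rate function
#' \deqn{r(V) = \frac{A + B V}{C + \exp((D + V)/E)}}
#' with `A` in ms^-1, `B` in ms^-1 mV^-1, `C` dimensionless, `D` and `E` in
#' mV. All channel opening/closing rates in the model are of this form.
#'
#' @param A,B,C,D,E numeric scalars; `E` must be non-zero.
#' @return an object of class `rate_params`.
#' @export
rate_params <- function(A, B, C, D, E) {
  stopifnot(is.numeric(A), is.numeric(B), is.numeric(C), is.numeric(D),
            is.numeric(E), length(E) == 1L)
  if (E == 0) stop("rate_params: E must be non-zero")
  structure(list(A = A, B = B, C = C, D = D, E = E), class = "rate_params")
}

#' Evaluate a rate function
#'
#' Evaluates `(A + B*V) / (C + exp((D + V)/E))` at membrane potential `V`
#' (mV). Values that come out marginally negative (possible for some
#' parameter rows at strongly hyperpolarised potentials) are clamped to zero,
#' so rates are always valid transition rates.
#'
#' @param params a [rate_params] object.
#' @param V membrane potential, mV (vectorised).
#' @param clamp clamp negative evaluations to 0 (default `TRUE`).
#' @return rate in ms^-1.
#' @export
eval_rate <- function(params, V, clamp = TRUE) {
  stopifnot(inherits(params, "rate_params"), all(is.finite(V)))
  denom <- params$C + exp((params$D + V) / params$E)
  if (any(abs(denom) < 1e-12))
    stop("eval_rate: denominator within machine epsilon of zero")
  r <- (params$A + params$B * V) / denom
  if (clamp) r <- pmax(r, 0)
  r
}

#' Gating-variable specification
#'
#' A gate `X` follows first-order kinetics `dX/dt = (Xinf(V) - X)/tau(V)` with
#' `Xinf = alpha/(alpha+beta)` and `tau = 1/(alpha+beta)`. The calcium
#' activation gate uses a voltage-piecewise closing rate: one parameter set
#' below the split voltage and another above it (the split itself, -25 mV,
#' uses the upper branch).
#'
#' @param name gate name, one of `m_na`, `h_na`, `n_kf`, `n_ks`, `m_ca`.
#' @param exponent integer power the gate enters the conductance with (1-4).
#' @param alpha,beta [rate_params] for the opening/closing rates.
#' @param beta_high optional [rate_params]: closing rate above `split_mV`.
#' @param split_mV split voltage for the piecewise closing rate (mV).
#' @return an object of class `gate_spec`.
#' @export
gate_spec <- function(name, exponent, alpha, beta, beta_high = NULL,
                      split_mV = -25) {
  stopifnot(exponent %in% 1:4, inherits(alpha, "rate_params"),
            inherits(beta, "rate_params"))
  if (!is.null(beta_high)) stopifnot(inherits(beta_high, "rate_params"))
  structure(list(name = name, exponent = as.integer(exponent), alpha = alpha,
                 beta = beta, beta_high = beta_high, split_mV = split_mV),
            class = "gate_spec")
}

gate_rates <- function(gate, V) {
  a <- eval_rate(gate$alpha, V)
  if (is.null(gate$beta_high)) {
    b <- eval_rate(gate$beta, V)
  } else {
    b <- ifelse(V < gate$split_mV,
                eval_rate(gate$beta, V),
                eval_rate(gate$beta_high, V))
  }
  list(alpha = a, beta = b)
}

#' Steady-state activation of a gate
#'
#' @param gate a [gate_spec].
#' @param V membrane potential, mV (vectorised).
#' @return `Xinf(V) = alpha/(alpha+beta)`, a fraction in \[0, 1\].
#' @export
gate_steady_state <- function(gate, V) {
  r <- gate_rates(gate, V)
  s <- r$alpha + r$beta
  if (any(s <= 0)) stop("gate_steady_state: alpha + beta must be positive")
  r$alpha / s
}

#' Time constant of a gate
#'
#' @inheritParams gate_steady_state
#' @return `tau(V) = 1/(alpha+beta)` in ms.
#' @export
gate_time_constant <- function(gate, V) {
  r <- gate_rates(gate, V)
  s <- r$alpha + r$beta
  if (any(s <= 0)) stop("gate_time_constant: alpha + beta must be positive")
  1 / s
}

#' Physical constants and calcium concentrations for the GHK current
#'
#' Concentrations are in mol/L. Defaults are conventional for an amphibian
#' preparation: 100 nmol/L internal, 10 mmol/L external calcium.
#'
#' @param F Faraday constant, C/mol.
#' @param R gas constant, J/(K mol).
#' @param T absolute temperature, K.
#' @param Ca_internal,Ca_external calcium concentrations, mol/L.
#' @export
ghk_constants <- function(F = 96485, R = 8.314, T = 300,
                          Ca_internal = 1e-7, Ca_external = 1e-2) {
  stopifnot(T > 0, Ca_internal > 0, Ca_external > 0)
  structure(list(F = F, R = R, T = T, Ca_internal = Ca_internal,
                 Ca_external = Ca_external), class = "ghk_constants")
}

#' Goldman-Hodgkin-Katz calcium current density
#'
#' Constant-field calcium flux
#' \deqn{i_{ca} = -P \, 2\upsilon F \frac{[Ca]_i - [Ca]_o e^{-\upsilon}}
#'   {1 - e^{-\upsilon}} m^2, \qquad \upsilon = \frac{2 V F}{R T},}
#' with the leading sign fixed so that, with external calcium far exceeding
#' internal, the current is inward and therefore *depolarising* (positive
#' under the convention that all membrane currents enter `C dV/dt` with
#' depolarising sign). The removable singularity at `V = 0` is evaluated by
#' series expansion, so the current is continuous there.
#'
#' Numerical convention: concentrations enter in mol/L and the result is read
#' in uA/cm^2. This fixed scale is what makes the calibrated permeability
#' constant (0.016 cm/s) produce calcium currents of the same order as the
#' other membrane currents; see the methods vignette.
#'
#' @param P permeability, cm/s.
#' @param m activation gate value in \[0, 1\] (vectorised with `V`).
#' @param V membrane potential, mV.
#' @param k a [ghk_constants] object.
#' @return current density, uA/cm^2 (positive = depolarising).
#' @export
ghk_current <- function(P, m, V, k = ghk_constants()) {
  stopifnot(P >= 0, all(is.finite(V)), all(m >= 0), all(m <= 1))
  ci <- k$Ca_internal; co <- k$Ca_external
  u <- 2 * (V / 1000) * k$F / (k$R * k$T)   # dimensionless
  small <- abs(u) < 1e-5
  g <- numeric(length(u))
  if (any(!small)) {
    us <- u[!small]
    g[!small] <- us * (ci - co * exp(-us)) / (1 - exp(-us))
  }
  if (any(small)) {
    us <- u[small]
    g[small] <- (ci - co) * (1 + us / 2 + us^2 / 12) + co * us
  }
  -2 * k$F * P * g * m^2
}

#' Channel specification
#'
#' @param kind one of `lk`, `na`, `kf`, `ks`, `ca`.
#' @param reversal_mV reversal potential (mV); `NA` for the GHK calcium
#'   channel, which has no ohmic reversal.
#' @param base_value base conductance density (mS/cm^2) or, for calcium,
#'   permeability (cm/s).
#' @param gates list of [gate_spec]s (empty for leak).
#' @export
channel_spec <- function(kind, reversal_mV, base_value, gates = list()) {
  kind <- match.arg(kind, c("lk", "na", "kf", "ks", "ca"))
  stopifnot(base_value >= 0)
  structure(list(kind = kind, reversal_mV = reversal_mV,
                 base_value = base_value, gates = gates),
            class = "channel_spec")
}

#' Ohmic membrane current density
#'
#' `i = g * prod(gates^exponent) * (e_rev - V)`, positive = depolarising.
#'
#' @param spec a [channel_spec] (ohmic kinds only).
#' @param V membrane potential, mV.
#' @param gate_values named list of gate values in \[0,1\], one per gate of
#'   the spec, in spec order (e.g. `list(m = m, h = h)` for sodium).
#' @param g conductance density, mS/cm^2; defaults to the spec's base value.
#' @return current density, uA/cm^2 (mS/cm^2 * mV = uA/cm^2).
#' @export
ohmic_current <- function(spec, V, gate_values = list(), g = NULL) {
  stopifnot(inherits(spec, "channel_spec"), spec$kind != "ca")
  if (is.null(g)) g <- spec$base_value
  stopifnot(length(gate_values) == length(spec$gates))
  open <- 1
  for (i in seq_along(spec$gates)) {
    x <- gate_values[[i]]
    stopifnot(all(x >= 0), all(x <= 1))
    open <- open * x^spec$gates[[i]]$exponent
  }
  g * open * (spec$reversal_mV - V)
}

rate_table_path <- function()
  system.file("extdata", "rate_params.csv", package = "axonet")
base_table_path <- function()
  system.file("extdata", "channel_base.csv", package = "axonet")

#' Channel parameter registry
#'
#' Loads the packaged kinetic and density tables (five channels: leak, Na,
#' fast K, slow K, GHK Ca; rate-function rows for the five gating variables)
#' and assembles them into [channel_spec]s. Any entry can be overridden.
#'
#' @param overrides optional named list: `base` (named numeric, replaces base
#'   densities/permeability by kind) and/or `reversal` (named numeric, mV).
#' @return named list of [channel_spec]s with attributes `multipliers_tested`
#'   and `multiplier_chosen` (per-channel, from the packaged table).
#' @export
channel_registry <- function(overrides = NULL) {
  rp <- utils::read.csv(rate_table_path(), stringsAsFactors = FALSE)
  bs <- utils::read.csv(base_table_path(), stringsAsFactors = FALSE)
  getp <- function(gate, rate, branch = "all") {
    r <- rp[rp$gate == gate & rp$rate == rate & rp$branch == branch, ]
    stopifnot(nrow(r) == 1L)
    rate_params(r$A, r$B, r$C, r$D, r$E)
  }
  base <- stats::setNames(bs$base_value, bs$kind)
  rev  <- stats::setNames(bs$reversal_mV, bs$kind)
  if (!is.null(overrides$base))
    base[names(overrides$base)] <- overrides$base
  if (!is.null(overrides$reversal))
    rev[names(overrides$reversal)] <- overrides$reversal

  reg <- list(
    lk = channel_spec("lk", rev[["lk"]], base[["lk"]]),
    na = channel_spec("na", rev[["na"]], base[["na"]], list(
      gate_spec("m_na", 3, getp("m_na", "alpha"), getp("m_na", "beta")),
      gate_spec("h_na", 1, getp("h_na", "alpha"), getp("h_na", "beta")))),
    kf = channel_spec("kf", rev[["kf"]], base[["kf"]],
                      list(gate_spec("n_kf", 4, getp("n_kf", "alpha"),
                                     getp("n_kf", "beta")))),
    ks = channel_spec("ks", rev[["ks"]], base[["ks"]],
                      list(gate_spec("n_ks", 2, getp("n_ks", "alpha"),
                                     getp("n_ks", "beta")))),
    ca = channel_spec("ca", NA_real_, base[["ca"]],
                      list(gate_spec("m_ca", 2, getp("m_ca", "alpha"),
                                     getp("m_ca", "beta", "low"),
                                     beta_high = getp("m_ca", "beta",
                                                      "high")))))
  attr(reg, "multipliers_tested") <- stats::setNames(
    lapply(strsplit(bs$multipliers_tested, ";"), as.numeric), bs$kind)
  attr(reg, "multiplier_chosen") <- stats::setNames(bs$multiplier_chosen,
                                                    bs$kind)
  class(reg) <- "channel_registry"
  reg
}

#' Channel-density configuration
#'
#' Realised densities are `g_x = base_x * M_x * N(1, noise_sd)`, with one
#' normal draw per neuron, channel and realisation; negative draws clamp to
#' zero. Regional overrides multiply on top within an arc-distance interval
#' of the axon (half-open, \[a, b), measured along the axon from the soma).
#'
#' @param multipliers named numeric `M_x` per channel kind (missing kinds
#'   default to 1).
#' @param noise_sd standard deviation of the per-neuron noise (default 0.05).
#' @param overrides list of `list(interval = c(a, b), channel = kind,
#'   factor = f)` entries.
#' @export
density_config <- function(multipliers = c(ca = 1, na = 1, kf = 1, ks = 1,
                                           lk = 1),
                           noise_sd = 0.05, overrides = list()) {
  m <- c(ca = 1, na = 1, kf = 1, ks = 1, lk = 1)
  m[names(multipliers)] <- multipliers
  stopifnot(all(m >= 0), noise_sd >= 0)
  for (ov in overrides)
    stopifnot(length(ov$interval) == 2L, ov$interval[1] < ov$interval[2],
              ov$channel %in% names(m), ov$factor >= 0)
  structure(list(multipliers = m, noise_sd = noise_sd, overrides = overrides),
            class = "density_config")
}

#' Initial-segment density overrides
#'
#' Convenience constructor for the non-uniform axon used in the final model:
#' sodium density scaled up and both potassium densities scaled down over a
#' proximal interval of the axon (default 20-70 um from the soma).
#'
#' @param interval arc-distance interval on the axon, um.
#' @param na_factor sodium scale factor (default 5).
#' @param k_factor potassium scale factor applied to both Kf and Ks
#'   (default 0.5).
#' @export
initial_segment_overrides <- function(interval = c(20, 70), na_factor = 5,
                                      k_factor = 0.5) {
  list(list(interval = interval, channel = "na", factor = na_factor),
       list(interval = interval, channel = "kf", factor = k_factor),
       list(interval = interval, channel = "ks", factor = k_factor))
}

#' Realise per-compartment channel densities
#'
#' Draws the per-neuron noise and applies multipliers and regional overrides,
#' yielding a compartment-by-channel density matrix. With `noise_sd = 0` the
#' result is deterministic and seed-independent.
#'
#' @param compartments compartment table of a population (see
#'   [build_population]); needs columns `neuron`, `axon_arc`, `section`.
#' @param config a [density_config].
#' @param registry a [channel_registry].
#' @param g_lk_base optional leak density (mS/cm^2) replacing the registry
#'   base value — used for the coupled-mode leak of 0.125 mS/cm^2.
#' @return numeric matrix (n_compartments x 5), columns
#'   `lk, na, kf, ks` (mS/cm^2) and `ca` (permeability, cm/s).
#' @export
realise_densities <- function(compartments, config = density_config(),
                              registry = channel_registry(),
                              g_lk_base = NULL) {
  kinds <- c("lk", "na", "kf", "ks", "ca")
  base <- vapply(registry[kinds], function(s) s$base_value, numeric(1))
  if (!is.null(g_lk_base)) base[["lk"]] <- g_lk_base
  neurons <- sort(unique(compartments$neuron))
  n_comp <- nrow(compartments)
  dens <- matrix(0, n_comp, length(kinds), dimnames = list(NULL, kinds))
  axon_max <- max(compartments$axon_arc, na.rm = TRUE)
  for (ov in config$overrides)
    if (ov$interval[1] < 0 || ov$interval[2] > axon_max + 1e-9)
      stop("realise_densities: override interval [", ov$interval[1], ", ",
           ov$interval[2], ") outside the axon span")
  for (k in kinds) {
    g0 <- base[[k]] * config$multipliers[[k]]
    for (nid in neurons) {
      noise <- if (config$noise_sd > 0)
        max(0, stats::rnorm(1, 1, config$noise_sd)) else 1
      dens[compartments$neuron == nid, k] <- g0 * noise
    }
  }
  for (ov in config$overrides) {
    sel <- compartments$section == "axon" &
      !is.na(compartments$axon_arc) &
      compartments$axon_arc >= ov$interval[1] &
      compartments$axon_arc < ov$interval[2]
    dens[sel, ov$channel] <- dens[sel, ov$channel] * ov$factor
  }
  dens
}
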