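# Four-section dIN geometry (soma, two hillock tapers, axon), its spatial
# discretisation into compartments, and the 30-neuron rostrocaudal column.

#' Build the four-section dIN morphology
#'
#' The soma (with its short dendrites) is treated as a single isopotential
#' cylinder whose lateral surface equals `soma_area`; with length equal to
#' diameter this gives `d = sqrt(soma_area/pi)` (17.84 um for the default
#' 1000 um^2). Two short tapered hillock sections interpolate linearly from
#' `hillock_proximal_diameter` down to the axon diameter, and a uniform
#' cylindrical axon completes the cell.
#'
#' @param soma_area soma + dendrite membrane area, um^2 (default 1000).
#' @param axon_diameter axon diameter, um (default 0.4).
#' @param axon_length axon length, um (default 1500).
#' @param hillock_lengths lengths of the two hillock sections, um.
#' @param hillock_proximal_diameter diameter where the hillock leaves the
#'   soma, um.
#' @return an object of class `din_morphology`: a list with a `sections`
#'   data frame (label, proximal/distal diameter, length, um) plus the
#'   summary fields `soma_surface_area`, `axon_diameter`, `axon_length`.
#' @export
din_morphology <- function(soma_area = 1000, axon_diameter = 0.4,
                           axon_length = 1500, hillock_lengths = c(5, 5),
                           hillock_proximal_diameter = 2.0) {
  if (soma_area <= 0 || axon_diameter <= 0 || axon_length <= 0 ||
      any(hillock_lengths <= 0) || hillock_proximal_diameter <= 0)
    stop("din_morphology: all dimensions must be positive (invalid geometry)")
  if (hillock_proximal_diameter < axon_diameter)
    stop("din_morphology: hillock must taper from soma scale down to the ",
         "axon diameter")
  d_soma <- sqrt(soma_area / pi)          # lateral area pi*d*L with L = d
  d_mid <- hillock_proximal_diameter +
    (axon_diameter - hillock_proximal_diameter) *
    hillock_lengths[1] / sum(hillock_lengths)
  sections <- data.frame(
    label = c("soma", "hillock1", "hillock2", "axon"),
    proximal_diameter = c(d_soma, hillock_proximal_diameter, d_mid,
                          axon_diameter),
    distal_diameter = c(d_soma, d_mid, axon_diameter, axon_diameter),
    length = c(d_soma, hillock_lengths, axon_length),
    stringsAsFactors = FALSE)
  structure(list(sections = sections,
                 soma_surface_area = soma_area,
                 axon_diameter = axon_diameter,
                 axon_length = axon_length),
            class = "din_morphology")
}

#' Equivalent-sphere diameter of a membrane area
#'
#' Diameter of the sphere with surface area `area` (`area = pi d^2`).
#' @param area membrane area, um^2.
#' @export
equivalent_sphere_diameter <- function(area) sqrt(area / pi)

# lateral (frustum) area of a tapered cylinder piece, um^2; the taper slope
# is shallow everywhere so the slant correction is negligible and omitted,
# matching the cylinder-based bookkeeping of compartmental simulators
frustum_area <- function(d1, d2, len) pi * (d1 + d2) / 2 * len

#' Analytic surface area of a morphology
#' @param morph a [din_morphology].
#' @return total membrane area, um^2.
#' @export
morphology_area <- function(morph) {
  s <- morph$sections
  sum(frustum_area(s$proximal_diameter, s$distal_diameter, s$length))
}

#' Discretisation rules
#'
#' Segment lengths per region: the hillock and the proximal axon use short
#' compartments, the distal axon (beyond `axon_switch` um) long ones.
#'
#' @param hillock compartment length in the hillock, um (default 5).
#' @param axon_proximal compartment length over the first `axon_switch` um of
#'   axon, um (default 5).
#' @param axon_switch arc distance at which the axon bin width switches, um
#'   (default 400).
#' @param axon_distal compartment length beyond the switch, um (default 100).
#' @export
discretisation_rules <- function(hillock = 5, axon_proximal = 5,
                                 axon_switch = 400, axon_distal = 100) {
  r <- list(hillock = hillock, axon_proximal = axon_proximal,
            axon_switch = axon_switch, axon_distal = axon_distal)
  if (any(vapply(r, length, integer(1)) != 1L) ||
      any(!is.finite(unlist(r))) || any(unlist(r) <= 0))
    stop("discretisation_rules: all segment lengths must be positive")
  structure(r, class = "discretisation_rules")
}

# split a length into pieces of width `w` (last piece may be shorter)
split_length <- function(len, w) {
  n <- floor(len / w + 1e-9)
  out <- rep(w, n)
  rem <- len - n * w
  if (rem > 1e-9) out <- c(out, rem)
  out
}

#' Discretise a morphology into compartments
#'
#' Produces a chain of compartments rooted at the soma: one soma compartment,
#' short hillock compartments, then axon compartments (fine bins out to the
#' switch distance, coarse bins beyond). Diameters taper linearly within the
#' hillock sections. Two arc coordinates are recorded per compartment
#' midpoint: `arc` (distance along the neurite from the soma boundary, um)
#' and `axon_arc` (distance along the axon proper from its hillock end; `NA`
#' for soma/hillock). Gap-junction placement and regional density overrides
#' are expressed in `axon_arc`.
#'
#' @param morph a [din_morphology].
#' @param rules a [discretisation_rules].
#' @return data frame with one row per compartment: `index`, `parent`
#'   (`NA` for the soma root), `section`, `length`, `mean_diameter`,
#'   `area_um2`, `arc`, `axon_arc`.
#' @export
compartmentalise <- function(morph, rules = discretisation_rules()) {
  stopifnot(inherits(morph, "din_morphology"))
  if (!inherits(rules, "discretisation_rules"))
    stop("compartmentalise: `rules` must be discretisation_rules()")
  s <- morph$sections
  rows <- list()
  # soma: single compartment, arc 0
  rows[[1]] <- data.frame(section = "soma", length = s$length[1],
                          d1 = s$proximal_diameter[1],
                          d2 = s$distal_diameter[1],
                          arc = 0, axon_arc = NA_real_)
  arc0 <- 0
  for (i in 2:3) {                         # hillock sections, linear taper
    lens <- split_length(s$length[i], rules$hillock)
    ends <- cumsum(lens); starts <- ends - lens
    f1 <- starts / s$length[i]; f2 <- ends / s$length[i]
    d1 <- s$proximal_diameter[i] +
      (s$distal_diameter[i] - s$proximal_diameter[i]) * f1
    d2 <- s$proximal_diameter[i] +
      (s$distal_diameter[i] - s$proximal_diameter[i]) * f2
    rows[[i]] <- data.frame(section = s$label[i], length = lens,
                            d1 = d1, d2 = d2,
                            arc = arc0 + (starts + ends) / 2,
                            axon_arc = NA_real_)
    arc0 <- arc0 + s$length[i]
  }
  la <- morph$axon_length
  prox <- split_length(min(la, rules$axon_switch), rules$axon_proximal)
  dist <- if (la > rules$axon_switch)
    split_length(la - rules$axon_switch, rules$axon_distal) else numeric(0)
  lens <- c(prox, dist)
  ends <- cumsum(lens); starts <- ends - lens
  rows[[4]] <- data.frame(section = "axon", length = lens,
                          d1 = morph$axon_diameter, d2 = morph$axon_diameter,
                          arc = arc0 + (starts + ends) / 2,
                          axon_arc = (starts + ends) / 2)
  cmp <- do.call(rbind, rows)
  n <- nrow(cmp)
  data.frame(index = seq_len(n),
             parent = c(NA_integer_, seq_len(n - 1L)),
             section = cmp$section,
             length = cmp$length,
             mean_diameter = (cmp$d1 + cmp$d2) / 2,
             d1 = cmp$d1, d2 = cmp$d2,
             area_um2 = frustum_area(cmp$d1, cmp$d2, cmp$length),
             arc = cmp$arc,
             axon_arc = cmp$axon_arc,
             stringsAsFactors = FALSE)
}

#' Lay out the rostrocaudal column of neurons
#'
#' Soma `i` (0-based) sits at coordinate `i * spacing`; each descending axon
#' spans `[soma, soma + axon_length]` caudally. Every compartment of every
#' neuron receives a rostrocaudal `coordinate` (um): soma and hillock
#' compartments carry the soma coordinate, axon compartments the soma
#' coordinate plus their `axon_arc`.
#'
#' @param n number of neurons (default 30).
#' @param spacing soma spacing, um (default 10).
#' @param morphology a [din_morphology] used for every neuron.
#' @param rules a [discretisation_rules].
#' @return an object of class `din_population`: list with `n`, `spacing`,
#'   `soma_positions`, `morphology`, and the pooled `compartments` data frame
#'   (extra columns `neuron` (0-based id), `gindex` (global row index),
#'   `coordinate`).
#' @export
build_population <- function(n = 30, spacing = 10,
                             morphology = din_morphology(),
                             rules = discretisation_rules()) {
  if (n < 1) stop("build_population: n must be >= 1")
  stopifnot(spacing > 0)
  base <- compartmentalise(morphology, rules)
  soma_positions <- (seq_len(n) - 1L) * spacing
  per <- nrow(base)
  comp <- base[rep(seq_len(per), n), ]
  comp$neuron <- rep(seq_len(n) - 1L, each = per)
  comp$coordinate <- soma_positions[comp$neuron + 1L] +
    ifelse(is.na(comp$axon_arc), 0, comp$axon_arc)
  comp$gindex <- seq_len(n * per)
  rownames(comp) <- NULL
  structure(list(n = n, spacing = spacing,
                 soma_positions = soma_positions,
                 morphology = morphology, rules = rules,
                 comps_per_neuron = per,
                 compartments = comp),
            class = "din_population")
}

#' @export
print.din_population <- function(x, ...) {
  cat("din_population:", x$n, "neurons,", x$spacing, "um soma spacing,",
      x$comps_per_neuron, "compartments each\n")
  invisible(x)
}

#' Export a morphology to SWC
#'
#' Writes the soma as a single sample and the hillock/axon chain as a line of
#' samples (SWC type 2, axon). Radii in um.
#'
#' @param morph a [din_morphology].
#' @param path output file path.
#' @param rules a [discretisation_rules].
#' @return the path, invisibly.
#' @export
write_swc <- function(morph, path, rules = discretisation_rules()) {
  cmp <- compartmentalise(morph, rules)
  # sample at compartment distal ends along x; soma at origin
  xs <- c(0, cmp$arc[-1] + cmp$length[-1] / 2)
  type <- ifelse(cmp$section == "soma", 1L, 2L)
  swc <- data.frame(id = cmp$index, type = type,
                    x = round(xs, 3), y = 0, z = 0,
                    r = round(ifelse(cmp$section == "soma",
                                     equivalent_sphere_diameter(
                                       morph$soma_surface_area) / 2,
                                     cmp$mean_diameter / 2), 4),
                    parent = ifelse(is.na(cmp$parent), -1L, cmp$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export: soma (single sample) + hillock/axon chain", con)
  utils::write.table(swc, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export a morphology to JSON
#' @param morph a [din_morphology].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_morphology_json <- function(morph, path) {
  jsonlite::write_json(list(sections = morph$sections,
                            soma_surface_area = morph$soma_surface_area,
                            axon_diameter = morph$axon_diameter,
                            axon_length = morph$axon_length),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
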