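# Stochastic gap-junction layout generation between overlapping descending
# axons, and the assembled network model (population + junctions + channel
# density configuration).

#' Gap-junction layout scheme
#'
#' Two stochastic rules for placing axo-axonic gap junctions between
#' overlapping axons, both expressed along the axon of the more caudal
#' neuron of each pair:
#' * `density`: a fixed probability density (per um) over the interval
#'   \[`min_dist`, `max_dist`) of each axon, discretised into `bin_width` um
#'   bins; in every bin up to `max_neighbours` overlapping partner axons are
#'   sampled and each receives a junction with probability
#'   `probability_density * bin_width`.
#' * `fixed_point`: a single candidate position `fixed_dist` um from the
#'   caudal soma; each ordered pair of overlapping axons receives a junction
#'   there with probability `probability` (capped at `max_neighbours`
#'   partners per position).
#'
#' @param variant `"density"` or `"fixed_point"`.
#' @param probability_density junction probability density, um^-1 (default
#'   0.015; density variant).
#' @param probability per-pair probability (fixed-point variant).
#' @param min_dist,max_dist junction region on the caudal axon, um (default
#'   \[0, 50)).
#' @param bin_width bin width, um (default 1).
#' @param max_neighbours partner cap per axon position (default 6: the
#'   maximum number of equal-diameter cylinders touching one axon).
#' @param fixed_dist candidate position for the fixed-point variant, um.
#' @param resistance junction resistance, MOhm (default 600).
#' @export
layout_scheme <- function(variant = c("density", "fixed_point"),
                          probability_density = 0.015, probability = 0.5,
                          min_dist = 0, max_dist = 50, bin_width = 1,
                          max_neighbours = 6, fixed_dist = 25,
                          resistance = 600) {
  variant <- match.arg(variant)
  stopifnot(min_dist < max_dist, probability_density >= 0,
            probability >= 0, probability <= 1, bin_width > 0,
            max_neighbours >= 1, resistance > 0)
  structure(list(variant = variant,
                 probability_density = probability_density,
                 probability = probability, min_dist = min_dist,
                 max_dist = max_dist, bin_width = bin_width,
                 max_neighbours = max_neighbours, fixed_dist = fixed_dist,
                 resistance = resistance),
            class = "layout_scheme")
}

# neurons (0-based ids) whose axon covers rostrocaudal coordinate x
axons_covering <- function(pop, x) {
  s <- pop$soma_positions
  which(s <= x + 1e-9 & x <= s + pop$morphology$axon_length + 1e-9) - 1L
}

# rostral neurons whose axons pass coordinate x (junction partners for the
# caudal neuron `nid`: the junction lies on nid's proximal axon, so the
# partner must be more rostral for d_gj to be measured from the caudal soma)
rostral_partners <- function(pop, x, nid) {
  cand <- axons_covering(pop, x)
  cand[cand < nid]
}

gj_frame <- function(owner, partner, d_owner, coord, soma_pos, resistance) {
  caudal <- pmax(owner, partner)
  rostral <- pmin(owner, partner)
  data.frame(caudal = caudal, rostral = rostral,
             d_gj = coord - soma_pos[caudal + 1L],
             coordinate = coord, resistance = resistance)
}

#' Generate a density-scheme gap-junction layout
#'
#' For each neuron, the junction region of its axon (\[`min_dist`,
#' `max_dist`) from its soma) is divided into `bin_width` um bins. For each
#' bin, up to `max_neighbours` more rostral neurons whose axons pass the
#' bin's rostrocaudal coordinate are picked uniformly at random (without
#' replacement), and each sampled partner receives a gap
#' junction at the bin centre with probability
#' `probability_density * bin_width`. Duplicate junctions between the same
#' pair in different bins are allowed (bins are independent). `d_gj` is
#' recorded from the soma of the more caudal member of each pair.
#'
#' @param pop a [build_population] result.
#' @param scheme a [layout_scheme] with `variant = "density"`.
#' @return data frame of junctions: `caudal`, `rostral` (0-based neuron
#'   ids), `d_gj` (um from the caudal soma), `coordinate` (um), `resistance`
#'   (MOhm). Uses the session RNG; seed it for reproducibility.
#' @export
generate_density_layout <- function(pop, scheme = layout_scheme()) {
  stopifnot(inherits(pop, "din_population"),
            scheme$variant == "density")
  p <- scheme$probability_density * scheme$bin_width
  stopifnot(p <= 1)
  centres <- seq(scheme$min_dist + scheme$bin_width / 2, scheme$max_dist,
                 by = scheme$bin_width)
  centres <- centres[centres < scheme$max_dist]
  out <- list()
  if (p == 0) return(gj_frame(integer(0), integer(0), numeric(0), numeric(0),
                              pop$soma_positions, numeric(0)))
  for (nid in seq_len(pop$n) - 1L) {
    soma <- pop$soma_positions[nid + 1L]
    for (dc in centres) {
      coord <- soma + dc
      cand <- rostral_partners(pop, coord, nid)
      if (!length(cand)) next
      k <- min(scheme$max_neighbours, length(cand))
      partners <- if (length(cand) == 1L) cand else sample(cand, k)
      hit <- partners[stats::runif(length(partners)) < p]
      if (length(hit))
        out[[length(out) + 1L]] <-
          gj_frame(rep(nid, length(hit)), hit, dc, coord,
                   pop$soma_positions, scheme$resistance)
    }
  }
  if (!length(out))
    return(data.frame(caudal = integer(0), rostral = integer(0),
                      d_gj = numeric(0), coordinate = numeric(0),
                      resistance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a fixed-point gap-junction layout
#'
#' A single candidate junction position `fixed_dist` um from each neuron's
#' soma; every other overlapping axon forms a junction there independently
#' with probability `probability`, with at most `max_neighbours` partners at
#' the position. Neurons whose axons do not reach a candidate coordinate are
#' skipped.
#'
#' @inheritParams generate_density_layout
#' @export
generate_fixed_point_layout <- function(pop, scheme) {
  stopifnot(inherits(pop, "din_population"),
            scheme$variant == "fixed_point")
  out <- list()
  for (nid in seq_len(pop$n) - 1L) {
    if (scheme$fixed_dist > pop$morphology$axon_length) next
    coord <- pop$soma_positions[nid + 1L] + scheme$fixed_dist
    cand <- rostral_partners(pop, coord, nid)
    if (!length(cand)) next
    hit <- cand[stats::runif(length(cand)) < scheme$probability]
    if (length(hit) > scheme$max_neighbours)
      hit <- sample(hit, scheme$max_neighbours)
    if (length(hit))
      out[[length(out) + 1L]] <-
        gj_frame(rep(nid, length(hit)), hit, scheme$fixed_dist, coord,
                 pop$soma_positions, scheme$resistance)
  }
  if (!length(out))
    return(data.frame(caudal = integer(0), rostral = integer(0),
                      d_gj = numeric(0), coordinate = numeric(0),
                      resistance = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a gap-junction layout
#'
#' Dispatches on the scheme variant.
#' @inheritParams generate_density_layout
#' @export
generate_gap_junctions <- function(pop, scheme = layout_scheme()) {
  switch(scheme$variant,
         density = generate_density_layout(pop, scheme),
         fixed_point = generate_fixed_point_layout(pop, scheme))
}

#' Assembled network model
#'
#' Bundles a population, a junction table, the channel-density
#' configuration, and the leak density in force. The coupled-mode final
#' model uses `g_lk = 0.125` mS/cm^2 (half the uniform passive value of
#' 0.25, restoring the physiological input resistance once junction shunting
#' is present).
#'
#' @param pop a [build_population] result.
#' @param gap_junctions junction data frame (see
#'   [generate_density_layout]); may have zero rows.
#' @param density a [density_config].
#' @param g_lk leak conductance density, mS/cm^2 (default 0.25).
#' @param passive logical: if `TRUE` the model is solved as a passive
#'   (leak-only) network.
#' @return an object of class `din_network`.
#' @export
network_model <- function(pop, gap_junctions, density = density_config(),
                          g_lk = 0.25, passive = FALSE) {
  stopifnot(inherits(pop, "din_population"), g_lk > 0)
  gj <- gap_junctions
  if (nrow(gj)) {
    stopifnot(all(gj$caudal != gj$rostral), all(gj$resistance > 0))
    # junction coordinate must lie within both axon spans
    al <- pop$morphology$axon_length
    s <- pop$soma_positions
    ok <- gj$coordinate >= s[gj$rostral + 1L] - 1e-9 &
      gj$coordinate <= s[gj$rostral + 1L] + al + 1e-9 &
      gj$coordinate >= s[gj$caudal + 1L] - 1e-9 &
      gj$coordinate <= s[gj$caudal + 1L] + al + 1e-9
    if (!all(ok)) stop("network_model: junction coordinate outside an axon")
  }
  structure(list(pop = pop, gap_junctions = gj, density = density,
                 g_lk = g_lk, passive = passive),
            class = "din_network")
}

#' @export
print.din_network <- function(x, ...) {
  cat("din_network:", x$pop$n, "neurons,", nrow(x$gap_junctions),
      "gap junctions, g_lk =", x$g_lk, "mS/cm2",
      if (x$passive) "(passive)" else "", "\n")
  invisible(x)
}

#' Classify pairwise electrical coupling paths
#'
#' Builds the neuron-level graph whose edges are pairs sharing at least one
#' direct gap junction and classifies every unordered pair by shortest path
#' length: `direct` (length 1), `indirect_1` (via the axon of one other
#' neuron, length 2), `indirect_k` generally, or `uncoupled`.
#'
#' @param net a [network_model].
#' @return data frame with one row per unordered pair: `a`, `b` (0-based
#'   ids), `path_length` (`Inf` if uncoupled), `class`.
#' @export
coupling_graph <- function(net) {
  n <- net$pop$n
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(net$gap_junctions)) {
    ed <- unique(net$gap_junctions[, c("caudal", "rostral")])
    g <- igraph::add_edges(g, rbind(ed$caudal + 1L, ed$rostral + 1L))
  }
  d <- igraph::distances(g)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pl <- d[pairs]
  cls <- ifelse(is.infinite(pl), "uncoupled",
                ifelse(pl == 1, "direct", paste0("indirect_", pl - 1)))
  data.frame(a = pairs[, "row"] - 1L, b = pairs[, "col"] - 1L,
             path_length = pl, class = cls, stringsAsFactors = FALSE)
}

#' Subsample the gap junctions of a network
#'
#' Retains a uniformly random subset of `floor(fraction * N)` junctions,
#' modelling partial removal of coupling.
#'
#' @param net a [network_model].
#' @param fraction fraction of junctions to keep, in \[0, 1\].
#' @return a new `din_network` with the reduced junction table.
#' @export
gj_subsample <- function(net, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  gj <- net$gap_junctions
  keep <- floor(fraction * nrow(gj))
  gj2 <- if (keep == nrow(gj)) gj else
    gj[sort(sample(seq_len(nrow(gj)), keep)), , drop = FALSE]
  rownames(gj2) <- NULL
  net$gap_junctions <- gj2
  net
}

#' Remove every gap junction
#' @param net a [network_model].
#' @export
remove_gap_junctions <- function(net) {
  net$gap_junctions <- net$gap_junctions[integer(0), , drop = FALSE]
  net
}

#' Junction-count summaries
#'
#' @param net a [network_model].
#' @return list with `total` junction count, `per_axon` (mean hemichannel
#'   count per neuron: each junction contributes to two neurons), and
#'   `fraction_direct` (share of the `n(n-1)/2` unordered pairs sharing a
#'   direct junction).
#' @export
layout_statistics <- function(net) {
  gj <- net$gap_junctions
  n <- net$pop$n
  cg <- coupling_graph(net)
  list(total = nrow(gj),
       per_axon = 2 * nrow(gj) / n,
       fraction_direct = mean(cg$class == "direct"))
}

#' Serialise a network to JSON
#' @param net a [network_model].
#' @param path output path.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(
    list(n_neurons = net$pop$n, spacing = net$pop$spacing,
         axon_length = net$pop$morphology$axon_length,
         g_lk = net$g_lk, passive = net$passive,
         gap_junctions = net$gap_junctions),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the junction table to CSV
#' @param net a [network_model].
#' @param path output path.
#' @export
write_junction_csv <- function(net, path) {
  utils::write.csv(net$gap_junctions, path, row.names = FALSE)
  invisible(path)
}
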