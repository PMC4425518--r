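test_that("default morphology matches the estimated cell geometry", {
  m <- din_morphology()
  expect_equal(nrow(m$sections), 4L)
  expect_equal(m$soma_surface_area, 1000)
  # soma cylinder with length = diameter reproduces the target area
  d <- m$sections$proximal_diameter[1]
  expect_equal(pi * d * m$sections$length[1], 1000, tolerance = 1e-9)
  expect_equal(equivalent_sphere_diameter(1000), 17.84, tolerance = 1e-2)
  # ~17.5 um equivalent sphere as estimated for the real cells
  expect_lt(abs(equivalent_sphere_diameter(1000) - 17.5), 0.4)
  # hillock tapers monotonically down to the axon diameter
  s <- m$sections
  expect_true(all(s$distal_diameter[2:3] <= s$proximal_diameter[2:3]))
  expect_equal(s$distal_diameter[3], m$axon_diameter)
})

test_that("degenerate geometry is rejected", {
  expect_error(din_morphology(axon_length = 0), "positive")
  expect_error(din_morphology(soma_area = -1), "positive")
  expect_error(din_morphology(axon_diameter = 3), "taper")
})

test_that("compartmentalisation bins the axon as specified", {
  cmp400 <- compartmentalise(din_morphology(axon_length = 400))
  expect_equal(sum(cmp400$section == "axon"), 80L)      # 400/5
  cmp1500 <- compartmentalise(din_morphology(axon_length = 1500))
  expect_equal(sum(cmp1500$section == "axon"), 91L)     # 80 x 5um + 11 x 100um
  expect_equal(sum(cmp1500$length[cmp1500$section == "axon"]), 1500)
  # contiguity: compartments form a rooted chain
  expect_true(is.na(cmp1500$parent[1]))
  expect_equal(cmp1500$parent[-1], cmp1500$index[-nrow(cmp1500)])
  expect_true(all(cmp1500$area_um2 > 0))
  expect_error(compartmentalise(din_morphology(), rules = list()))
})

test_that("discretised membrane area matches the analytic area", {
  for (la in c(400, 977, 1500)) {
    m <- din_morphology(axon_length = la)
    cmp <- compartmentalise(m)
    rel <- abs(sum(cmp$area_um2) - morphology_area(m)) / morphology_area(m)
    expect_lt(rel, 0.001)
  }
})

test_that("refining the discretisation barely moves input resistance", {
  coarse <- build_population(1)
  fine <- build_population(1, morphology = din_morphology(),
                           rules = discretisation_rules(2.5, 2.5, 400, 50))
  r1 <- input_resistance(network_model(coarse, axonet:::empty_junctions(),
                                       g_lk = 0.25, passive = TRUE))
  r2 <- input_resistance(network_model(fine, axonet:::empty_junctions(),
                                       g_lk = 0.25, passive = TRUE))
  expect_lt(abs(r1 - r2) / r2, 0.01)
})

test_that("population layout places somata and axons on the column", {
  pop <- build_population(30, 10)
  expect_equal(pop$soma_positions[30], 290)
  expect_true(all(diff(pop$soma_positions) == 10))
  # rostrocaudal coordinate is monotone non-decreasing along every neuron
  for (nid in c(0L, 14L, 29L)) {
    co <- pop$compartments$coordinate[pop$compartments$neuron == nid]
    expect_true(all(diff(co) >= 0))
  }
  # axons of the first and last neuron overlap where coordinates coincide
  a0 <- c(0, 1500); a29 <- c(290, 290 + 1500)
  expect_true(max(a0[1], a29[1]) < min(a0[2], a29[2]))
  expect_error(build_population(0), ">= 1")
  p1 <- build_population(1)
  expect_equal(p1$n, 1L)
})

test_that("morphology exports round-trip the key fields", {
  m <- din_morphology(axon_length = 400)
  swc <- tempfile(fileext = ".swc")
  write_swc(m, swc)
  tab <- utils::read.table(swc)
  expect_equal(nrow(tab), nrow(compartmentalise(m)))
  expect_equal(tab[1, 2], 1)                 # soma sample first
  expect_equal(tab[1, 7], -1)                # root
  js <- tempfile(fileext = ".json")
  write_morphology_json(m, js)
  got <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(got$axon_length, 400)
  expect_equal(got$soma_surface_area, 1000)
})
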