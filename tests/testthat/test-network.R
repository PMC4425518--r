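test_that("density layout matches its binomial expectation (2 neurons)", {
  # only the caudal neuron has a rostral partner: 50 bins x p = 0.75 expected
  pop <- build_population(2)
  set.seed(101)
  counts <- replicate(400, nrow(generate_density_layout(pop)))
  expect_lt(abs(mean(counts) - 0.75), 0.15)  # ~3.5 se
})

test_that("density layout respects region, cap and caudal-soma distances", {
  pop <- build_population(30)
  set.seed(5)
  gj <- generate_density_layout(pop)
  expect_true(all(gj$d_gj >= 0 & gj$d_gj < 50))
  expect_true(all(gj$rostral < gj$caudal))
  expect_true(all(gj$coordinate - pop$soma_positions[gj$caudal + 1] ==
                    gj$d_gj))
  # per caudal-axon bin, at most 6 partners
  percell <- table(paste(gj$caudal, gj$d_gj))
  expect_true(all(percell <= 6))
  # zero density -> empty layout
  none <- generate_density_layout(pop, layout_scheme(probability_density = 0))
  expect_equal(nrow(none), 0L)
})

test_that("layout statistics reproduce the published network scale", {
  pop <- build_population(30)
  set.seed(11)
  tot <- per <- dir <- numeric(20)
  for (i in 1:20) {
    net <- network_model(pop, generate_density_layout(pop))
    st <- layout_statistics(net)
    tot[i] <- st$total; per[i] <- st$per_axon; dir[i] <- st$fraction_direct
  }
  expect_gt(mean(tot), 80)
  expect_lt(mean(tot), 123)        # expectation 119.25 under the scheme
  expect_gt(mean(per), 5)
  expect_lt(mean(per), 8.5)
  expect_gt(mean(dir), 0.18)       # about a quarter of the 435 pairs
  expect_lt(mean(dir), 0.30)
})

test_that("layout generation is reproducible under a fixed seed", {
  pop <- build_population(10)
  set.seed(99); a <- generate_density_layout(pop)
  set.seed(99); b <- generate_density_layout(pop)
  expect_identical(a, b)
})

test_that("fixed-point layout places all junctions at one distance", {
  pop <- build_population(5)
  sch <- layout_scheme("fixed_point", probability = 1, fixed_dist = 25)
  set.seed(3)
  gj <- generate_fixed_point_layout(pop, sch)
  expect_true(all(gj$d_gj == 25))
  # probability 1: every caudal neuron junctions with every rostral partner
  expect_equal(nrow(gj), choose(5, 2))
  sch0 <- layout_scheme("fixed_point", probability = 0)
  expect_equal(nrow(generate_fixed_point_layout(pop, sch0)), 0L)
})

test_that("coupling graph classifies direct and indirect paths", {
  net3 <- fixture_chain3()
  cg <- coupling_graph(net3)
  expect_equal(cg$class[cg$a == 0 & cg$b == 1], "direct")
  expect_equal(cg$class[cg$a == 1 & cg$b == 2], "direct")
  expect_equal(cg$class[cg$a == 0 & cg$b == 2], "indirect_1")
  # no junctions: everything uncoupled
  empty <- network_model(build_population(3), axonet:::empty_junctions())
  expect_true(all(coupling_graph(empty)$class == "uncoupled"))
})

test_that("junction subsampling keeps the requested count", {
  pop <- build_population(30)
  set.seed(2)
  net <- network_model(pop, generate_density_layout(pop))
  n0 <- nrow(net$gap_junctions)
  expect_identical(gj_subsample(net, 1)$gap_junctions, net$gap_junctions)
  expect_equal(nrow(gj_subsample(net, 0)$gap_junctions), 0L)
  expect_equal(nrow(gj_subsample(net, 0.5)$gap_junctions), floor(0.5 * n0))
})

test_that("network serialisation round-trips the junction table", {
  net <- fixture_chain3()
  p <- tempfile(fileext = ".json")
  write_network_json(net, p)
  got <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(got$n_neurons, 3)
  expect_equal(nrow(got$gap_junctions), 2)
  csv <- tempfile(fileext = ".csv")
  write_junction_csv(net, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$d_gj, net$gap_junctions$d_gj)
})

test_that("junctions outside an axon span are rejected", {
  pop <- build_population(2)
  bad <- data.frame(caudal = 1L, rostral = 0L, d_gj = 25,
                    coordinate = 5000, resistance = 600)
  expect_error(network_model(pop, bad), "outside an axon")
})
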