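test_that("generation is bit-reproducible for an identical config", {
  cfg <- generator_config(seed = 1, n_terminals = 8)
  n1 <- generate_arteriolar_tree(cfg)
  n2 <- generate_arteriolar_tree(cfg)
  expect_identical(n1, n2)
  # and leaves the global RNG stream untouched
  set.seed(42); before <- runif(3)
  set.seed(42); invisible(generate_arteriolar_tree(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("the requested number of terminals is produced exactly", {
  for (n in c(1, 8, 37)) {
    net <- generate_arteriolar_tree(generator_config(seed = 2, n_terminals = n))
    expect_equal(sum(net$segments$terminal), n)
    expect_length(validate_network(net), 0)
    expect_equal(nrow(net$segments), nrow(net$nodes) - 1)
  }
})

test_that("per-order diameters follow the configured order map", {
  net <- generate_arteriolar_tree(generator_config(seed = 4, n_terminals = 20))
  sg <- net$segments
  expect_true(all(sg$diameter[sg$order == 5] == 22))
  expect_true(all(sg$diameter[sg$order == 1] == 117))
  for (o in sort(unique(sg$order))) {
    expect_true(all(sg$diameter[sg$order == o] ==
                      net$order_diameters[[as.character(o)]]))
  }
})

test_that("diameters never increase from root to leaf along any path", {
  net <- generate_arteriolar_tree(generator_config(seed = 6, n_terminals = 25))
  sg <- net$segments
  for (path in retinox:::terminal_paths(net)) {
    expect_true(all(diff(sg$diameter[path]) <= 0))
  }
})

test_that("a single-terminal config yields one root-to-leaf path", {
  net <- generate_arteriolar_tree(generator_config(seed = 3, n_terminals = 1))
  expect_equal(sum(net$segments$terminal), 1)
  expect_equal(nrow(net$segments), nrow(net$nodes) - 1)
  # every non-terminal node has exactly one child segment
  expect_true(all(table(net$segments$from) == 1))
})

test_that("capillary counts follow the nearest-integer rule with floor one", {
  net <- bifurcation_net()
  qc <- capillary_reference_flow()
  net$segments$flow <- c(10.3 * qc, 10 * qc, 0.3 * qc)
  net$segments$hd <- 0.4
  net$segments$visc <- 2
  net$nodes$pressure <- c(40, 30, 24, 24)
  ch <- attach_compartments(net, q_c = qc, seed = 1)
  expect_equal(ch$n_C, c(10L, 1L))

  # proportionality: flows 2:1 give counts in ratio ~2:1
  net$segments$flow <- c(300 * qc, 200 * qc, 100 * qc)
  ch <- attach_compartments(net, q_c = qc, seed = 1)
  expect_equal(ch$n_C[1] / ch$n_C[2], 2, tolerance = 0.01)
})

test_that("capillary totals conserve terminal flow within the rounding bound", {
  net <- solved_small_net(seed = 7, n_terminals = 15)
  qc <- capillary_reference_flow()
  ch <- attach_compartments(net, q_c = qc, seed = 2)
  term_total <- sum(net$segments$flow[net$segments$terminal])
  expect_lt(abs(sum(ch$n_C) * qc - term_total), 0.5 * qc * nrow(ch) + 1e-9)
})

test_that("asymmetric configs give right-skewed capillary distributions", {
  net <- iterate_flow(suppressWarnings(generate_arteriolar_tree(
    generator_config(seed = 11, n_terminals = 40, asymmetry = 0.6))))
  ch <- attach_compartments(net, seed = 3)
  s <- summarize_capillary_distribution(ch)
  expect_gt(s$mean, s$median)
  expect_equal(s$total, sum(ch$n_C))
  expect_equal(sum(s$histogram$counts), nrow(ch))
})

test_that("distribution summary handles edge cases", {
  ch <- data.frame(n_C = c(243, 243, 2500))
  s <- summarize_capillary_distribution(ch)
  expect_equal(s$median, 243)
  expect_equal(s$total, 2986)
  s1 <- summarize_capillary_distribution(data.frame(n_C = 57))
  expect_equal(s1$total, 57)
  expect_equal(s1$median, 57)
})

test_that("the single-capillary reference flow follows the shear relation", {
  # Q = tau * pi * D^3 / (32 mu), then tau recovered from Q
  q <- capillary_reference_flow(diameter = 6, shear = 15, viscosity = 9.05)
  expect_equal(q, 0.2109, tolerance = 1e-3)
  q_cgs <- q * retinox_units$nl_min_to_cm3_s
  tau_back <- 32 * 9.05e-2 * q_cgs / (pi * (6e-4)^3)
  expect_equal(tau_back, 15, tolerance = 1e-12)
})
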