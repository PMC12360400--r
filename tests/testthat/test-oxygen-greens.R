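test_that("with zero demand the tissue equilibrates to the blood PO2", {
  net <- single_vessel_net(diameter = 40, box = 200)
  dom <- tissue_domain(net, spacing = 20, sleeve = Inf,
                       bbox = rbind(c(0, 0, 0), c(200, 200, 200)))
  f <- solve_greens_field(net, dom, oxygen_params(m0 = 1e-12),
                          fixed_blood_po2 = 50)
  expect_lt(max(abs(f$tissue$po2 - 50)), 0.01)
  expect_lt(sum(abs(f$elements$qs)), 1e-15)
})

test_that("source strengths balance tissue consumption at convergence", {
  net <- solved_small_net(seed = 5, n_terminals = 8)
  dom <- tissue_domain(net, spacing = 40, sleeve = 90)
  f <- solve_greens_field(net, dom, oxygen_params(m0 = 2))
  expect_true(f$converged)
  expect_lt(f$balance$residual, 0.01)
  expect_true(all(f$elements$qs >= 0))
  expect_true(all(f$tissue$po2 >= 0))
})

test_that("blood saturation never increases along the flow direction", {
  net <- solved_small_net(seed = 7, n_terminals = 8)
  dom <- tissue_domain(net, spacing = 40, sleeve = 90)
  f <- solve_greens_field(net, dom, oxygen_params(m0 = 3))
  el <- f$elements
  for (k in unique(el$seg)) {
    s <- el$saturation[el$seg == k][order(el$s_mid[el$seg == k])]
    expect_true(all(diff(s) <= 1e-12))
  }
  # and from parent to child across every junction
  sg <- net$segments
  sat_out <- hill_saturation(pmax(f$terminal_po2, 0))
  expect_true(all(sat_out <= oxygen_params()$inlet_saturation + 1e-12))
})

test_that("with linear consumption the field responds linearly to demand", {
  # replace Michaelis-Menten by its linear regime: PO2 >> P0 makes the
  # consumption effectively constant; doubling demand then doubles the
  # field depression below the vessel PO2
  net <- single_vessel_net(diameter = 40, box = 200)
  dom <- tissue_domain(net, spacing = 10, sleeve = Inf,
                       bbox = rbind(c(0, 0, 0), c(200, 200, 200)))
  par1 <- oxygen_params(m0 = 0.5, p0 = 1e-6)
  par2 <- oxygen_params(m0 = 1.0, p0 = 1e-6)
  f1 <- solve_greens_field(net, dom, par1, fixed_blood_po2 = 80)
  f2 <- solve_greens_field(net, dom, par2, fixed_blood_po2 = 80)
  dep1 <- 80 - f1$tissue$po2
  dep2 <- 80 - f2$tissue$po2
  expect_equal(dep2, 2 * dep1, tolerance = 0.01)
})

test_that("far tissue saturates at the sink-limited consumption", {
  net <- single_vessel_net(diameter = 30, box = 300)
  dom <- tissue_domain(net, spacing = 15, sleeve = Inf,
                       bbox = rbind(c(0, 0, 0), c(300, 300, 300)))
  par <- oxygen_params(m0 = 4)
  f <- solve_greens_field(net, dom, par, fixed_blood_po2 = 40)
  r <- sqrt((f$tissue$x - 150)^2 + (f$tissue$y - 150)^2)
  far <- r > 130
  expect_true(any(f$tissue$po2[far] < 1))   # PO2 clamps near zero far out
  # consumption stays below demand everywhere (Michaelis-Menten limit)
  m_frac <- f$tissue$po2 / (par$p0 + f$tissue$po2)
  expect_true(all(m_frac < 1))
  # the far tissue consumes at a small fraction of demand
  expect_lt(min(m_frac[far]), 0.2)
})

test_that("the FD oracle reproduces the 2-D log profile of a line source", {
  # quasi-2-D slab: vessel along z, zero-flux z faces, fixed lateral faces;
  # the radial profile between geometrically spaced radii is logarithmic
  net <- vascular_network(
    data.frame(id = 1:2, x = 200, y = 200, z = c(0, 20)),
    data.frame(id = 1, from = 1, to = 2, order = 3, diameter = 10,
               length = 20, terminal = TRUE),
    inlet_node = 1)
  par <- oxygen_params(m0 = 0)    # pure diffusion between two boundaries
  fd <- finite_difference_oracle(net, rbind(c(0, 0, 0), c(400, 400, 20)),
                                 n = c(81, 81, 5), params = par,
                                 blood_po2 = 60, outer_dirichlet = 20,
                                 dirichlet_axes = 1:2)
  g <- fd$grid
  mid <- g[g$y == 200 & g$z == 10 & g$x > 200, ]
  p_at <- function(r) mid$po2[mid$x == 200 + r]
  r <- c(20, 40, 80)  # geometric spacing: equal log-profile decrements
  ratio <- (p_at(r[1]) - p_at(r[2])) / (p_at(r[2]) - p_at(r[3]))
  expect_equal(ratio, log(r[2] / r[1]) / log(r[3] / r[2]), tolerance = 0.02)
})

test_that("grid refinement brings the FD oracle toward the Green's field", {
  net <- single_vessel_net(diameter = 40, box = 200, n_seg = 5)
  bbox <- rbind(c(0, 0, 0), c(200, 200, 200))
  par <- oxygen_params(m0 = 1)
  dom <- tissue_domain(net, spacing = 10, sleeve = Inf, bbox = bbox)
  gf <- solve_greens_field(net, dom, par, fixed_blood_po2 = 50,
                           max_factor = 0.5, boundary = "mirror")
  disc <- function(n_fd) {
    fd <- finite_difference_oracle(net, bbox, n = n_fd, params = par,
                                   blood_po2 = 50)
    key <- function(df) paste(round(df$x, 2), round(df$y, 2), round(df$z, 2))
    common <- match(key(fd$grid), key(gf$tissue))
    g <- fd$grid
    interior <- g$x >= 50 & g$x <= 150 & g$y >= 50 & g$y <= 150 &
      g$z >= 50 & g$z <= 150
    ok <- !is.na(common) & !fd$vessel_mask & interior
    mean(abs(g$po2[ok] - gf$tissue$po2[common[ok]]))
  }
  d11 <- disc(11)
  d21 <- disc(21)
  d41 <- disc(41)
  expect_lt(d21, d11)
  expect_lt(d41, d21)
})

test_that("the hypoxia threshold curve is a proper distribution function", {
  net <- solved_small_net(seed = 5, n_terminals = 8)
  dom <- tissue_domain(net, spacing = 40, sleeve = 90)
  f <- solve_greens_field(net, dom, oxygen_params(m0 = 3))
  curve <- fraction_below_threshold(f)
  expect_true(all(diff(curve$fraction) >= 0))
  expect_equal(curve$fraction[1], 0)   # threshold 0: nothing strictly below
  expect_true(all(curve$fraction >= 0 & curve$fraction <= 1))
  hi <- fraction_below_threshold(f, thresholds = 1000)
  expect_equal(hi$fraction, 1)
})

test_that("warm-started re-solves reproduce the cold solution", {
  net <- solved_small_net(seed = 5, n_terminals = 8)
  dom <- tissue_domain(net, spacing = 40, sleeve = 90)
  par <- oxygen_params(m0 = 2)
  cold <- solve_greens_field(net, dom, par)
  warm <- solve_greens_field(net, dom, par, warm = cold)
  expect_equal(warm$tissue$po2, cold$tissue$po2, tolerance = 0.05)
  expect_lte(warm$iterations, cold$iterations)
})
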