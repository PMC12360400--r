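test_that("two equal segments in series put the midpoint at 32 mmHg", {
  net <- series_net()
  net <- solve_pressures(net, flow_solver_config(viscosity_law = "constant"))
  expect_equal(net$nodes$pressure, c(40, 32, 24), tolerance = 1e-10)
})

test_that("unequal series conductances weight the midpoint pressure", {
  # g1, g2 from different diameters/lengths: P_mid = (g1*40 + g2*24)/(g1+g2)
  net <- series_net(d1 = 60, d2 = 35, l1 = 400, l2 = 700)
  cfg <- flow_solver_config(viscosity_law = "constant", constant_viscosity = 2)
  net$segments$visc <- 2
  g <- retinox:::segment_conductance(net$segments)
  expected_mid <- (g[1] * 40 + g[2] * 24) / (g[1] + g[2])
  net <- solve_pressures(net, cfg)
  expect_equal(net$nodes$pressure[2], expected_mid, tolerance = 1e-10)
  # cross-check the whole solve against a dense direct solve
  expect_equal(net$nodes$pressure, dense_pressure_oracle(net, cfg),
               tolerance = 1e-10)
})

test_that("a symmetric bifurcation splits flow equally", {
  net <- bifurcation_net()
  net <- iterate_flow(net, flow_solver_config())
  sg <- net$segments
  expect_equal(sg$flow[2], sg$flow[3], tolerance = 1e-12)
  expect_equal(sg$flow[1], sg$flow[2] + sg$flow[3], tolerance = 1e-10)
})

test_that("Poiseuille flow and wall shear have the right scalings and units", {
  net <- series_net(d1 = 50, d2 = 50)
  cfg <- flow_solver_config(viscosity_law = "constant", constant_viscosity = 2)
  net <- compute_flows(solve_pressures(net, cfg))
  sg <- net$segments
  # hand evaluation of Q = dP pi D^4 / (128 mu L) in CGS, reported in nl/min
  dp <- 8 * 1333.22
  q_hand <- dp * pi * (50e-4)^4 / (128 * 0.02 * 0.05) / (1e-6 / 60)
  expect_equal(sg$flow[1], q_hand, tolerance = 1e-10)
  # tau = 32 mu Q / (pi D^3) equals dP D / (4 L) for a single segment
  expect_equal(sg$wall_shear[1], dp * 50e-4 / (4 * 0.05), tolerance = 1e-10)

  # zero pressure drop means zero flow and shear
  net0 <- net
  net0$nodes$pressure <- c(30, 30, 30)
  net0 <- compute_flows(net0)
  expect_equal(net0$segments$flow, c(0, 0))
  expect_equal(net0$segments$wall_shear, c(0, 0))

  # doubling D at fixed dP, mu, L gives 16x the flow
  net16 <- series_net(d1 = 100, d2 = 100)
  net16$nodes$pressure <- net$nodes$pressure
  net16$segments$visc <- 2
  net16 <- compute_flows(net16)
  expect_equal(net16$segments$flow[1] / sg$flow[1], 16, tolerance = 1e-10)
})

test_that("the in-vitro viscosity law has its documented shape", {
  # dimensionless relative viscosity: high in large tubes, minimum near
  # capillary diameters, steep rise below
  v <- viscosity_in_vitro(c(3, 6, 10, 40, 117, 500), 0.45)
  expect_lt(v[2], v[5])           # 6 um below 117 um
  expect_gt(v[1], v[2])           # rises again under the minimum
  expect_gt(v[6], v[5])           # grows toward large-tube limit
  expect_equal(viscosity_in_vitro(2000, 0.45), 3.2, tolerance = 0.01)
  # hematocrit 0 gives the suspending medium
  expect_equal(viscosity_in_vitro(50, 0), 1, tolerance = 1e-10)
})

test_that("proportional hematocrit split conserves RBC flux exactly", {
  net <- solved_small_net(seed = 9, n_terminals = 10)
  sg <- net$segments
  expect_true(all(abs(sg$hd - 0.4) < 1e-14))
  for (nd in unique(sg$from)) {
    parent <- which(sg$to == nd)
    kids <- which(sg$from == nd)
    if (!length(parent)) next
    flux_in <- sg$flow[parent] * sg$hd[parent]
    flux_out <- sum(sg$flow[kids] * sg$hd[kids])
    expect_lt(abs(flux_in - flux_out) / flux_in, 1e-10)
  }
})

test_that("phase-separation split conserves RBC flux and skews hematocrit", {
  net <- bifurcation_net()
  net$segments$diameter <- c(40, 30, 18)   # unequal daughters
  cfg <- flow_solver_config(hematocrit_rule = "phase_separation")
  net <- iterate_flow(net, cfg)
  sg <- net$segments
  flux_in <- sg$flow[1] * sg$hd[1]
  flux_out <- sum(sg$flow[2:3] * sg$hd[2:3])
  expect_lt(abs(flux_in - flux_out) / flux_in, 1e-10)
  expect_false(isTRUE(all.equal(sg$hd[2], sg$hd[3])))
  # higher-flow daughter receives the higher hematocrit
  expect_gt(sg$hd[which.max(sg$flow[2:3]) + 1], sg$hd[which.min(sg$flow[2:3]) + 1])
})

test_that("constant-viscosity mode converges in one outer iteration", {
  net <- solved_small_net(seed = 2, n_terminals = 6)  # warm structure
  net$segments$visc <- NA_real_
  net <- iterate_flow(net, flow_solver_config(viscosity_law = "constant"))
  expect_equal(attr(net, "outer_iterations"), 1)
})

test_that("iterate_flow is idempotent and start-independent", {
  cfg <- flow_solver_config()
  net <- generate_arteriolar_tree(generator_config(seed = 8, n_terminals = 8))
  a <- iterate_flow(net, cfg)
  b <- iterate_flow(a, cfg)
  expect_equal(a$segments$flow, b$segments$flow, tolerance = 1e-9)
  # different initial viscosity guesses reach the same fixed point
  net2 <- net
  net2$segments$visc <- 9
  net2$segments$hd <- 0.4
  c2 <- iterate_flow(net2, cfg)
  expect_equal(a$segments$flow, c2$segments$flow, tolerance = 1e-8)
})

test_that("compartment flows divide evenly and conserve mass", {
  net <- solved_small_net(seed = 5, n_terminals = 8)
  ch <- attach_compartments(net, seed = 4)
  ch <- propagate_compartment_flows(net, ch)
  expect_equal(ch$q_per_cap, ch$q / ch$n_C)
  inflow <- sum(net$segments$flow[net$segments$from == net$inlet_node])
  expect_equal(sum(ch$q), inflow, tolerance = 1e-9)
  expect_true(all(ch$p_after_LV < ch$p_after_SV))
  expect_true(all(ch$p_after_SV < ch$p_after_C))
})

test_that("compartment pressure drops match a hand series-resistor solve", {
  net <- bifurcation_net()
  net <- iterate_flow(net, flow_solver_config())
  ch <- attach_compartments(net, seed = 1)
  ch <- propagate_compartment_flows(net, ch, cap_viscosity = 9.05)
  i <- 1
  r_hand <- function(n, d_um, l_um, mu_cP) {
    128 * mu_cP * 1e-2 * l_um * 1e-4 / (pi * (d_um * 1e-4)^4) / n
  }
  q_cgs <- ch$q[i] * retinox_units$nl_min_to_cm3_s
  dp_c <- q_cgs * r_hand(ch$n_C[i], 2 * ch$r_C[i], ch$L_C[i], 9.05) / 1333.22
  expect_equal(ch$p_in[i] - ch$p_after_C[i], dp_c, tolerance = 1e-10)
})

test_that("a missing chain for a terminal is detected", {
  net <- solved_small_net(seed = 5, n_terminals = 8)
  ch <- attach_compartments(net, seed = 4)
  expect_error(propagate_compartment_flows(net, ch[-1, ]), "missing chain")
})
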