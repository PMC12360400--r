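test_that("Laplace tension is linear and converts units correctly", {
  expect_equal(laplace_tension(15, 15, 80), 0)
  expect_equal(laplace_tension(40, 15, 100), 25 * 1333.22 * 0.01 / 2)
  d <- c(20, 40, 80)
  t <- laplace_tension(35, 15, d)
  expect_equal(t / d, rep(t[1] / d[1], 3))
})

test_that("total wall tension has the documented passive and active anatomy", {
  d0 <- 120
  # passive-only tension at the reference diameter equals 1.67 * D0
  expect_equal(total_tension(d0, 0, d0), 1.67 * d0, tolerance = 1e-12)
  # passive tension is strictly increasing in diameter
  d <- seq(0.6 * d0, 1.4 * d0, length.out = 30)
  expect_true(all(diff(total_tension(d, 0, d0)) > 0))
  # at the Gaussian peak with full activation the active part is C_act
  co <- retinox:::wall_coefficients(d0)
  d_peak <- d0 * co$c_act_p
  active <- total_tension(d_peak, 1, d0) - total_tension(d_peak, 0, d0)
  expect_equal(active, co$c_act, tolerance = 1e-12)
})

test_that("the tone stimulus responds with the documented signs", {
  p <- regulation_params()
  base <- stimulus_tone(0, 0, 0, c_myo = 0.01, c_tone = 3, params = p)
  expect_equal(base, 3)
  expect_lt(stimulus_tone(0, 50, 0, 0.01, 3, p), base)   # shear dilates
  expect_lt(stimulus_tone(0, 0, 0.05, 0.01, 3, p), base) # metabolic dilates
  expect_gt(stimulus_tone(200, 0, 0, 0.01, 3, p), base)  # tension constricts
})

test_that("target activation is a proper sigmoid", {
  expect_equal(target_activation(0), 0.5)
  expect_equal(target_activation(-50), 0, tolerance = 1e-12)
  s <- c(-3, -0.7, 0.2, 4)
  expect_equal(target_activation(s) + target_activation(-s), rep(1, 4))
})

test_that("the calibrated control state is an exact equilibrium", {
  net <- solved_small_net(seed = 5, n_terminals = 8)
  st <- init_regulation(net, regulation_params())
  st2 <- run_to_steady_state(st, dt = 0.1, tol = 1e-8, t_max = 30)
  expect_equal(st2$vessels$D, st$vessels$Dc, tolerance = 1e-9)
  expect_lt(max(abs(st2$vessels$A - st$vessels$A)), 1e-9)
  # tension balance per vessel at the fixed point
  p_mid <- retinox:::segment_mid_pressure(st2$net)
  t_lap <- laplace_tension(p_mid, st2$params$iop, st2$vessels$D)
  t_tot <- total_tension(st2$vessels$D, st2$vessels$A, st2$vessels$D0)
  expect_lt(max(abs(t_lap - t_tot) / st2$vessels$Tc), 1e-6)
})

test_that("activation relaxes exponentially with time constant tau_a", {
  # decouple the feedbacks: freeze D (huge Tc) and remove the dependence of
  # the stimulus on activation (c_myo = 0) so the target is a constant
  net <- iterate_flow(single_segment_net(), flow_solver_config())
  st <- init_regulation(net, regulation_params())
  st$vessels$Tc <- st$vessels$Tc * 1e12
  st$vessels$c_myo <- 0
  p <- st$params
  a_target <- plogis(-p$c_shear * st$net$segments$wall_shear -
                       p$c_meta * st$vessels$s_meta + st$vessels$c_tone)
  a0 <- st$vessels$A
  for (i in 1:40) st <- step_regulation(st, dt = 0.5)
  # 20 s elapsed = one time constant
  expect_equal((st$vessels$A - a_target) / (a0 - a_target), exp(-1),
               tolerance = 0.01)
})

test_that("single-vessel steady state matches the algebraic fixed point", {
  net <- iterate_flow(single_segment_net(diameter = 50, length = 600),
                      flow_solver_config())
  st <- init_regulation(net, regulation_params())
  # perturb the driving pressure away from the calibration point
  st$net$inlet_pressure <- 45
  st2 <- run_to_steady_state(st, dt = 0.1, tol = 1e-7, t_max = 900)

  # independent 1-D root solve of {T_laplace = T_total, A = A_total}
  v <- st$vessels
  p <- st$params
  co <- retinox:::wall_coefficients(v$D0)
  l_cm <- net$segments$length * 1e-4
  dp_cgs <- (45 - 24) * 1333.22
  resid <- function(d) {
    p_mid <- (45 + 24) / 2
    t_lap <- (p_mid - p$iop) * 1333.22 * d * 1e-4 / 2
    tau <- dp_cgs * d * 1e-4 / (4 * l_cm)
    a_bal <- (t_lap - co$c_pass * exp(co$c_pass_p * (d / v$D0 - 1))) /
      (co$c_act * exp(-((d / v$D0 - co$c_act_p) / co$c_act_pp)^2))
    s_tone <- co$c_myo * t_lap - p$c_shear * tau - p$c_meta * v$s_meta +
      v$c_tone
    plogis(s_tone) - a_bal
  }
  d_star <- uniroot(resid, c(0.7 * v$Dc, 1.35 * v$Dc), tol = 1e-10)$root
  expect_equal(st2$vessels$D, d_star, tolerance = 1e-4)

  # steady state is invariant to halving dt
  st3 <- run_to_steady_state(st, dt = 0.05, tol = 1e-7, t_max = 900)
  expect_equal(st2$vessels$D, st3$vessels$D, tolerance = 1e-6)

  # and locally stable: a 1% perturbation returns to the same point
  st4 <- st2
  st4$vessels$D <- st2$vessels$D * 1.01
  st4 <- run_to_steady_state(st4, dt = 0.1, tol = 1e-7, t_max = 900)
  expect_equal(st4$vessels$D, st2$vessels$D, tolerance = 1e-5)
})

test_that("activation stays inside (0,1) along a strongly driven trajectory", {
  net <- iterate_flow(single_segment_net(), flow_solver_config())
  st <- init_regulation(net, regulation_params())
  st$vessels$c_tone <- st$vessels$c_tone + 5   # strong constrictive push
  for (i in 1:100) {
    st <- step_regulation(st, dt = 0.2)
    expect_true(all(st$vessels$A >= 0 & st$vessels$A <= 1))
    expect_true(all(st$vessels$D > 0))
  }
})

test_that("with only the myogenic response, pressure raises steady tone", {
  p <- regulation_params(c_shear = 0, c_meta = 0)
  run_at <- function(p_in) {
    net <- single_segment_net(diameter = 50, length = 600)
    net$inlet_pressure <- p_in
    net <- iterate_flow(net, flow_solver_config())
    st <- init_regulation(net, p)
    ct <- st$vessels$c_tone
    st$vessels$c_tone <- ct  # calibrated at its own pressure
    st
  }
  st40 <- run_at(40)
  # raise pressure on the calibrated vessel and find the new steady state
  stp <- st40
  stp$net$inlet_pressure <- 48
  stp <- run_to_steady_state(stp, dt = 0.1, tol = 1e-6, t_max = 900)
  expect_gt(stp$vessels$A, st40$vessels$A)  # more pressure, more tone
})

test_that("passive mode relaxes to the passive equilibrium", {
  net <- iterate_flow(single_segment_net(), flow_solver_config())
  st <- init_regulation(net, regulation_params())
  stp <- run_to_steady_state(st, dt = 0.1, tol = 1e-9, t_max = 300,
                             mode = "passive")
  d <- stp$vessels$D
  p_mid <- retinox:::segment_mid_pressure(stp$net)
  t_lap <- laplace_tension(p_mid, stp$params$iop, d)
  expect_equal(total_tension(d, 0, stp$vessels$D0), t_lap, tolerance = 1e-5)
  # passive diameter exceeds the (toned) control diameter
  expect_gt(d, stp$vessels$Dc)
})

test_that("the conducted metabolic signal accumulates desaturation upstream", {
  net <- solved_small_net(seed = 5, n_terminals = 8)
  p <- regulation_params()
  sat_hi <- rep(0.92, nrow(net$segments))
  sat_lo <- rep(0.80, nrow(net$segments))
  s_hi <- metabolic_signal(net, sat_hi, p)
  s_lo <- metabolic_signal(net, sat_lo, p)
  expect_true(all(s_lo > s_hi))  # more desaturation, more dilatory signal
  # the root integrates its whole subtree: largest signal at the inlet
  root <- which(net$segments$from == net$inlet_node)
  expect_equal(which.max(s_hi), root)
  # capillary-bed desaturation adds to the terminals
  ch <- attach_compartments(net, seed = 2)
  ch$s_out <- 0.5
  s_ch <- metabolic_signal(net, sat_hi, p, chains = ch)
  term <- net$segments$terminal
  expect_true(all(s_ch[term] > s_hi[term]))
})
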