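test_that("zero consumption gives a flat radial profile", {
  prof <- krogh_radial_profile(30, r_c = 3, d = 22, m0 = 0)
  expect_true(all(prof$po2 == 30))
  expect_false(attr(prof, "hypoxic"))
})

test_that("the outer boundary is zero-flux and the wall is pinned", {
  prof <- krogh_radial_profile(25, r_c = 3, d = 22, m0 = 3, n_r = 2001)
  expect_equal(prof$po2[1], 25)
  # numerical outer gradient vanishes relative to the profile scale
  n <- nrow(prof)
  grad <- (prof$po2[n] - prof$po2[n - 1]) / (prof$r[n] - prof$r[n - 1])
  scale <- (max(prof$po2) - min(prof$po2)) / (max(prof$r) - min(prof$r))
  expect_lt(abs(grad / scale), 1e-3)
  # monotone decreasing into the tissue
  expect_true(all(diff(prof$po2) < 0))
})

test_that("the closed form matches a shooting-method BVP oracle on a grid", {
  skip_if_not_installed("deSolve")
  k <- 6e-10
  bvp_edge <- function(p_wall, r_c, d, m0) {
    # integrate K (1/r) d/dr (r dP/dr) = M0 with P(r_c) = P_wall; by
    # linearity two trial slopes bracket the zero-outer-flux solution
    rhs <- function(r, y, parms) {
      list(c(y[2], parms$m / parms$k - y[2] / r))
    }
    shoot <- function(s) {
      deSolve::ode(c(p_wall, s), seq(r_c * 1e-4, (r_c + d) * 1e-4,
                                     length.out = 201),
                   rhs, list(m = m0 / 6000, k = k),
                   method = "lsoda", rtol = 1e-12, atol = 1e-12)
    }
    o1 <- shoot(0); o2 <- shoot(-1e4)
    n <- nrow(o1)
    w <- o1[n, 3] / (o1[n, 3] - o2[n, 3])
    (1 - w) * o1[, 2] + w * o2[, 2]
  }
  grid <- expand.grid(p_wall = c(15, 23, 32, 40),
                      d = c(10, 18, 27, 36),
                      m0 = c(1, 2, 3, 4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    oracle <- bvp_edge(g$p_wall, 3, g$d, g$m0)
    r <- seq(3, 3 + g$d, length.out = 201)
    closed <- retinox:::krogh_po2_at(r, g$p_wall, 3, 3 + g$d, g$m0, k)
    expect_lt(max(abs(closed - oracle)), 1e-6)
  }
})

test_that("the hypoxic annulus radius marks where the profile reaches zero", {
  k <- 6e-10
  # a case whose closed form goes negative before the outer edge
  r_star <- retinox:::hypoxic_annulus_radius(8, 3, 36, 4, k)
  expect_lt(r_star, 3 + 36)
  expect_gt(r_star, 3)
  p_at_star <- retinox:::krogh_po2_at(r_star, 8, 3, r_star, 4, k)
  expect_lt(abs(p_at_star), 1e-5)
  prof <- krogh_radial_profile(8, 3, 36, 4, k)
  expect_true(attr(prof, "hypoxic"))
  expect_equal(min(prof$po2), 0)
})

test_that("capillary density is strictly decreasing in the sleeve width", {
  net <- solved_small_net(seed = 5, n_terminals = 8)
  ch <- attach_compartments(net, seed = 4)
  d <- seq(0, 60, by = 5)
  cd <- vapply(d, function(x) capillary_density(ch, x), numeric(1))
  expect_true(all(diff(cd) < 0))
})

test_that("tissue width inverts the density relation (substitution oracle)", {
  # toy instance: one chain, no venule volume worth mentioning
  ch <- data.frame(terminal_id = 1, n_C = 1000L, L_C = 400, r_C = 3,
                   n_SV = 1L, L_SV = 1e-6, r_SV = 1e-3,
                   n_LV = 1L, L_LV = 1e-6, r_LV = 1e-3)
  class(ch) <- c("compartment_chains", "data.frame")
  for (cd_t in c(200, 300, 340)) {
    d <- tissue_width_from_density(ch, cd_t)
    expect_equal(capillary_density(ch, d), cd_t, tolerance = 1e-6 * cd_t)
  }
  # doubling the density target shrinks the width
  expect_gt(tissue_width_from_density(ch, 150),
            tissue_width_from_density(ch, 300))
  # infeasible targets are refused with the supremum in the message
  expect_error(tissue_width_from_density(ch, 1e5), "infeasible")
})

test_that("chain oxygen is deterministic and monotone in capillary length", {
  par <- oxygen_params(m0 = 3)
  mk <- function(l_c) {
    ch <- data.frame(terminal_id = 1:2, n_C = c(50L, 50L), L_C = l_c,
                     r_C = 3, n_SV = 5L, L_SV = 500, r_SV = 9,
                     n_LV = 1L, L_LV = 2000, r_LV = 31,
                     q = c(12, 12), p_in = c(24, 24),
                     q_per_cap = c(0.24, 0.24))
    class(ch) <- c("compartment_chains", "data.frame")
    ch
  }
  same <- chain_oxygen(mk(c(400, 400)), p_b_in = 60, d = 22, params = par)
  expect_identical(same$p_out[1], same$p_out[2])
  diff_l <- chain_oxygen(mk(c(300, 500)), p_b_in = 60, d = 22, params = par)
  expect_gt(diff_l$p_out[1], diff_l$p_out[2])
  expect_gt(diff_l$p_edge[1], diff_l$p_edge[2])
})

test_that("the downstream radial profile reports the capillary-end station", {
  par <- oxygen_params(m0 = 2)
  ch <- data.frame(terminal_id = 1, n_C = 50L, L_C = 400, r_C = 3,
                   n_SV = 5L, L_SV = 500, r_SV = 9, n_LV = 1L, L_LV = 2000,
                   r_LV = 31, q = 12, p_in = 24, q_per_cap = 0.24)
  class(ch) <- c("compartment_chains", "data.frame")
  ch <- chain_oxygen(ch, p_b_in = 55, d = 22, params = par)
  prof <- chain_downstream_profile(ch[1, ], d = 22, params = par)
  expect_equal(prof$po2[1], ch$p_out[1])
  expect_equal(prof$po2[nrow(prof)], ch$p_edge[1], tolerance = 1e-9)
})
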