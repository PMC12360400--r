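# shared fixtures: small hand-built networks used across test files

# two segments in series: inlet -> mid -> terminal
series_net <- function(d1 = 50, d2 = 50, l1 = 500, l2 = 500) {
  nodes <- data.frame(id = 1:3, x = c(0, l1, l1 + l2), y = 0, z = 0)
  segs <- data.frame(id = 1:2, from = c(1, 2), to = c(2, 3), order = c(4, 5),
                     diameter = c(d1, d2), length = c(l1, l2),
                     terminal = c(FALSE, TRUE))
  vascular_network(nodes, segs, inlet_node = 1)
}

# symmetric bifurcation: inlet segment feeding two identical terminals
bifurcation_net <- function() {
  nodes <- data.frame(id = 1:4,
                      x = c(0, 500, 900, 900),
                      y = c(0, 0, 300, -300), z = 0)
  segs <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                     order = c(4, 5, 5), diameter = c(40, 25, 25),
                     length = c(500, 500, 500),
                     terminal = c(FALSE, TRUE, TRUE))
  vascular_network(nodes, segs, inlet_node = 1)
}

# one straight vessel spanning a cubic box, for oxygen-field validation;
# n_seg > 1 splits the same cylinder into a collinear chain, giving the
# Green's solver that many independent source strengths along the axis
single_vessel_net <- function(diameter = 40, box = 200, n_seg = 1L) {
  z <- seq(0, box, length.out = n_seg + 1L)
  nodes <- data.frame(id = seq_len(n_seg + 1L), x = box / 2, y = box / 2,
                      z = z)
  segs <- data.frame(id = seq_len(n_seg), from = seq_len(n_seg),
                     to = seq_len(n_seg) + 1L, order = 3,
                     diameter = diameter, length = diff(z),
                     terminal = c(rep(FALSE, n_seg - 1L), TRUE))
  vascular_network(nodes, segs, inlet_node = 1)
}

# single-segment vessel between the boundary pressures (regulation tests)
single_segment_net <- function(diameter = 50, length = 600) {
  nodes <- data.frame(id = 1:2, x = c(0, length), y = 0, z = 0)
  segs <- data.frame(id = 1, from = 1, to = 2, order = 3,
                     diameter = diameter, length = length, terminal = TRUE)
  vascular_network(nodes, segs, inlet_node = 1)
}

solved_small_net <- function(seed = 5, n_terminals = 12) {
  iterate_flow(generate_arteriolar_tree(
    generator_config(seed = seed, n_terminals = n_terminals)))
}

# dense direct pressure solve: independent oracle for the SOR solver
dense_pressure_oracle <- function(net, cfg = flow_solver_config()) {
  sg <- net$segments
  if (anyNA(sg$visc)) {
    sg$visc <- retinox:::segment_viscosity(sg$diameter, cfg$inflow_hematocrit,
                                           cfg)
  }
  ids <- net$nodes$id
  n <- length(ids)
  g <- retinox:::segment_conductance(sg)
  a <- matrix(0, n, n)
  for (k in seq_len(nrow(sg))) {
    i <- match(sg$from[k], ids); j <- match(sg$to[k], ids)
    a[i, i] <- a[i, i] + g[k]; a[j, j] <- a[j, j] + g[k]
    a[i, j] <- a[i, j] - g[k]; a[j, i] <- a[j, i] - g[k]
  }
  b <- rep(0, n)
  fixed <- rep(NA_real_, n)
  fixed[match(net$inlet_node, ids)] <- net$inlet_pressure
  fixed[match(sg$to[sg$terminal], ids)] <- net$outlet_pressure
  for (i in which(!is.na(fixed))) {
    a[i, ] <- 0; a[i, i] <- 1; b[i] <- fixed[i]
  }
  as.numeric(solve(a, b))
}
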