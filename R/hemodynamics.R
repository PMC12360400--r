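# Network hemodynamics: nodal pressures by successive over-relaxation,
# Poiseuille flows, and the hematocrit / apparent-viscosity iteration.

#' Flow solver configuration
#'
#' @param sor_relaxation SOR relaxation factor in (0, 2); default 1.5.
#' @param pressure_tol convergence tolerance on the per-sweep pressure
#'   update, mmHg.
#' @param outer_tol relative flow-change tolerance for the outer
#'   pressure/viscosity iteration.
#' @param max_iterations maximum SOR sweeps.
#' @param inflow_hematocrit discharge hematocrit of the inflowing blood
#'   (default 0.4).
#' @param viscosity_law `"in_vitro"` (empirical diameter- and
#'   hematocrit-dependent apparent viscosity) or `"constant"`.
#' @param constant_viscosity viscosity used in `"constant"` mode, cP.
#' @param plasma_viscosity plasma viscosity multiplying the relative
#'   in-vitro law, cP.
#' @param hematocrit_rule how discharge hematocrit divides at diverging
#'   bifurcations: `"proportional"` (children inherit the parent hematocrit,
#'   which satisfies red-cell and plasma conservation exactly) or
#'   `"phase_separation"` (empirical red-cell phase separation at
#'   two-child bifurcations).
#' @return A `flow_solver_config` list.
#' @export
flow_solver_config <- function(sor_relaxation = 1.5,
                               pressure_tol = 1e-12,
                               outer_tol = 1e-10,
                               max_iterations = 200000L,
                               inflow_hematocrit = 0.4,
                               viscosity_law = c("in_vitro", "constant"),
                               constant_viscosity = 2,
                               plasma_viscosity = 1.2,
                               hematocrit_rule = c("proportional",
                                                   "phase_separation")) {
  viscosity_law <- match.arg(viscosity_law)
  hematocrit_rule <- match.arg(hematocrit_rule)
  stopifnot(sor_relaxation > 0, sor_relaxation < 2,
            pressure_tol > 0, outer_tol > 0)
  structure(list(sor_relaxation = sor_relaxation, pressure_tol = pressure_tol,
                 outer_tol = outer_tol, max_iterations = max_iterations,
                 inflow_hematocrit = inflow_hematocrit,
                 viscosity_law = viscosity_law,
                 constant_viscosity = constant_viscosity,
                 plasma_viscosity = plasma_viscosity,
                 hematocrit_rule = hematocrit_rule),
            class = "flow_solver_config")
}

#' Empirical in-vitro apparent blood viscosity
#'
#' Relative apparent viscosity of blood flowing in a glass tube of given
#' diameter at a given discharge hematocrit, from the classic empirical fit
#' to in-vitro measurements. Multiply by the plasma viscosity to obtain the
#' apparent viscosity in cP.
#'
#' @param diameter vessel diameter, um.
#' @param hd discharge hematocrit in \[0, 1\].
#' @return Viscosity relative to the suspending medium (dimensionless).
#' @export
#' @examples
#' viscosity_in_vitro(6, 0.45)    # near the minimum of the curve
#' viscosity_in_vitro(117, 0.45)
viscosity_in_vitro <- function(diameter, hd) {
  d <- diameter
  eta45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + 1 / (1 + 1e-11 * d^12)) +
    1 / (1 + 1e-11 * d^12)
  1 + (eta45 - 1) * ((1 - hd)^cc - 1) / ((1 - 0.45)^cc - 1)
}

segment_viscosity <- function(diameter, hd, cfg) {
  if (cfg$viscosity_law == "constant") {
    rep(cfg$constant_viscosity, length(diameter))
  } else {
    viscosity_in_vitro(diameter, hd) * cfg$plasma_viscosity
  }
}

# conductance so that Q [cm^3/s] = g * dP [mmHg]
segment_conductance <- function(sg) {
  d <- um_to_cm(sg$diameter); l <- um_to_cm(sg$length)
  mu <- cP_to_poise(sg$visc)
  pi * d^4 / (128 * mu * l) * retinox_units$mmHg_to_dyn_cm2
}

node_depths <- function(net) {
  sg <- net$segments
  ids <- net$nodes$id
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[as.character(net$inlet_node)] <- 0L
  frontier <- net$inlet_node
  while (length(frontier)) {
    kids <- sg$to[sg$from %in% frontier]
    depth[as.character(kids)] <- depth[as.character(sg$from[match(kids, sg$to)])] + 1L
    frontier <- kids
  }
  depth
}

#' Solve nodal pressures by successive over-relaxation
#'
#' Conservation of flow at every interior node defines a linear system in
#' the nodal pressures, with the inlet held at `net$inlet_pressure` and all
#' terminal outlets at `net$outlet_pressure`. The system is solved by
#' red-black successive over-relaxation (a rooted tree is bipartite by depth
#' parity, so each half-sweep is an exact Gauss-Seidel update).
#'
#' @param net a `vascular_network` with segment viscosities set (or they are
#'   initialised from `cfg` at the inflow hematocrit).
#' @param cfg a [flow_solver_config()].
#' @param warm_start reuse pressures already stored in the network as the
#'   initial iterate.
#' @return The network with `nodes$pressure` filled in (mmHg). The number of
#'   sweeps is attached as attribute `"sor_sweeps"`.
#' @export
solve_pressures <- function(net, cfg = flow_solver_config(), warm_start = TRUE) {
  sg <- net$segments
  if (anyNA(sg$visc)) {
    hd0 <- ifelse(is.na(sg$hd), cfg$inflow_hematocrit, sg$hd)
    net$segments$visc <- segment_viscosity(sg$diameter, hd0, cfg)
    sg <- net$segments
  }
  ids <- net$nodes$id
  n <- length(ids)
  g <- segment_conductance(sg)
  i_from <- match(sg$from, ids); i_to <- match(sg$to, ids)

  # fixed-pressure nodes: inlet and terminal outlets
  fixed <- rep(NA_real_, n)
  fixed[match(net$inlet_node, ids)] <- net$inlet_pressure
  fixed[i_to[sg$terminal]] <- net$outlet_pressure
  is_fixed <- !is.na(fixed)

  A <- Matrix::sparseMatrix(i = c(i_from, i_to), j = c(i_to, i_from),
                            x = c(g, g), dims = c(n, n))
  deg <- Matrix::rowSums(A)

  depth <- node_depths(net)[as.character(ids)]
  red <- depth %% 2L == 0L

  p <- net$nodes$pressure
  if (!warm_start || anyNA(p)) {
    p <- rep((net$inlet_pressure + net$outlet_pressure) / 2, n)
  }
  p[is_fixed] <- fixed[is_fixed]

  w <- cfg$sor_relaxation
  sweeps <- 0L
  repeat {
    delta <- 0
    for (col in list(red, !red)) {
      upd <- col & !is_fixed
      if (!any(upd)) next
      gs <- as.numeric(A %*% p) / deg
      dp <- w * (gs[upd] - p[upd])
      p[upd] <- p[upd] + dp
      delta <- max(delta, max(abs(dp)))
    }
    sweeps <- sweeps + 1L
    if (delta < cfg$pressure_tol) break
    if (sweeps >= cfg$max_iterations) {
      stop(sprintf(
        "SOR did not converge in %d sweeps (last max pressure update %.3g mmHg)",
        sweeps, delta))
    }
  }
  net$nodes$pressure <- p
  attr(net, "sor_sweeps") <- sweeps
  net
}

#' Compute segment flows and wall shear from solved pressures
#'
#' Poiseuille's law per segment, `Q = dP * pi D^4 / (128 mu L)`, signed
#' positive from `from` to `to`, plus the wall shear stress
#' `tau = 32 mu |Q| / (pi D^3)`.
#'
#' @param net a `vascular_network` with solved pressures.
#' @return The network with `segments$flow` (nl/min) and
#'   `segments$wall_shear` (dyn/cm^2) filled in.
#' @export
compute_flows <- function(net) {
  if (anyNA(net$nodes$pressure)) stop("pressures not solved")
  sg <- net$segments
  g <- segment_conductance(sg)
  dp <- net$nodes$pressure[match(sg$from, net$nodes$id)] -
    net$nodes$pressure[match(sg$to, net$nodes$id)]
  q_cgs <- g * dp
  d <- um_to_cm(sg$diameter)
  net$segments$flow <- cgs_to_nlmin(q_cgs)
  net$segments$wall_shear <- 32 * cP_to_poise(sg$visc) * abs(q_cgs) / (pi * d^3)
  net
}

#' Update segment hematocrit and apparent viscosity
#'
#' Discharge hematocrit is propagated from the inlet down the tree assuming
#' conservation of red-cell and plasma flow at every node. Under the default
#' proportional rule each child inherits the parent discharge hematocrit
#' (which satisfies the conservation statement exactly); the optional
#' empirical phase-separation rule redistributes red cells between the two
#' children of a diverging bifurcation according to their flow fractions and
#' the feed diameter. Apparent viscosity is then re-evaluated per segment
#' from the configured viscosity law at (diameter, hematocrit).
#'
#' @param net a `vascular_network` with solved flows.
#' @param cfg a [flow_solver_config()].
#' @return The network with `segments$hd` and `segments$visc` updated.
#' @export
update_hematocrit_viscosity <- function(net, cfg = flow_solver_config()) {
  sg <- net$segments
  if (anyNA(sg$flow)) stop("flows not solved")
  hd <- rep(NA_real_, nrow(sg))
  topo <- segment_topo_order(net)
  for (i in topo) {
    parent <- which(sg$to == sg$from[i])
    if (!length(parent)) { hd[i] <- cfg$inflow_hematocrit; next }
    if (!is.na(hd[i])) next
    sibs <- which(sg$from == sg$from[i])
    hp <- hd[parent]; qp <- sg$flow[parent]
    if (length(sibs) == 2 && cfg$hematocrit_rule == "phase_separation") {
      hd[sibs] <- phase_separation_split(
        q_parent = qp, h_parent = hp, d_parent = sg$diameter[parent],
        q_children = sg$flow[sibs], d_children = sg$diameter[sibs])
    } else {
      hd[sibs] <- hp
    }
  }
  net$segments$hd <- hd
  net$segments$visc <- segment_viscosity(sg$diameter, hd, cfg)
  net
}

# Empirical red-cell phase separation at a diverging bifurcation.
# Returns the two child discharge hematocrits; conserves RBC flux exactly.
phase_separation_split <- function(q_parent, h_parent, d_parent,
                                   q_children, d_children) {
  fqb <- q_children[1] / q_parent  # fractional blood flow into child 1
  x0 <- 0.964 * (1 - h_parent) / d_parent
  a <- -13.29 * ((d_children[1] / d_children[2])^2 - 1) /
    ((d_children[1] / d_children[2])^2 + 1) * (1 - h_parent) / d_parent
  b <- 1 + 6.98 * (1 - h_parent) / d_parent
  fqe <- if (fqb <= x0) 0 else if (fqb >= 1 - x0) 1 else {
    xl <- log((fqb - x0) / (1 - fqb - x0))
    1 / (1 + exp(-(a + b * xl)))
  }
  rbc <- q_parent * h_parent
  h1 <- fqe * rbc / q_children[1]
  h2 <- (1 - fqe) * rbc / q_children[2]
  # a child cannot carry more red cells than whole blood; clamp and rebalance
  if (h1 > 1) { h1 <- 1; h2 <- (rbc - q_children[1]) / q_children[2] }
  if (h2 > 1) { h2 <- 1; h1 <- (rbc - q_children[2]) / q_children[1] }
  c(h1, h2)
}

#' Iterate pressures, flows, hematocrit and viscosity to a fixed point
#'
#' Alternates the SOR pressure solve / Poiseuille flow update with the
#' hematocrit and apparent-viscosity update until the flows change by less
#' than `cfg$outer_tol` (relative) between successive solves. In constant-
#' viscosity mode there is no coupling and a single outer iteration
#' suffices.
#'
#' @param net a `vascular_network`.
#' @param cfg a [flow_solver_config()].
#' @return Converged network; the outer iteration count is attached as
#'   attribute `"outer_iterations"`.
#' @export
iterate_flow <- function(net, cfg = flow_solver_config()) {
  sg <- net$segments
  hd0 <- ifelse(is.na(sg$hd), cfg$inflow_hematocrit, sg$hd)
  net$segments$visc <- segment_viscosity(sg$diameter, hd0, cfg)
  prev_flow <- NULL
  for (iter in 1:100) {
    net <- solve_pressures(net, cfg)
    net <- compute_flows(net)
    old_visc <- net$segments$visc
    net <- update_hematocrit_viscosity(net, cfg)
    visc_change <- max(abs(net$segments$visc - old_visc) / old_visc)
    flow_change <- if (is.null(prev_flow)) Inf else
      max(abs(net$segments$flow - prev_flow) /
            pmax(abs(prev_flow), 1e-12))
    prev_flow <- net$segments$flow
    if (visc_change == 0 || flow_change < cfg$outer_tol) {
      attr(net, "outer_iterations") <- iter
      return(net)
    }
  }
  stop("flow iteration did not converge in 100 outer iterations ",
       sprintf("(last relative flow change %.3g)", flow_change))
}

#' Propagate terminal flows and pressures through the compartment chains
#'
#' Each chain inherits the flow and outlet pressure of its terminal
#' arteriole; flow divides equally among the identical parallel vessels of
#' each compartment, and pressure drops along the capillary, small-venule
#' and large-venule compartments follow Poiseuille's law with the
#' compartment dimensions. The capillary compartment uses the single-
#' capillary apparent viscosity (9.05 cP by default); venule viscosities
#' come from the in-vitro law at the venule diameters.
#'
#' @param net a converged `vascular_network`.
#' @param chains a `compartment_chains` data.frame (see
#'   [attach_compartments()]).
#' @param cap_viscosity capillary apparent viscosity, cP.
#' @param cfg a [flow_solver_config()] (for the venule viscosity law).
#' @return `chains` with per-capillary flow `q_per_cap` (nl/min) and
#'   compartment outlet pressures `p_after_C`, `p_after_SV`, `p_after_LV`
#'   (mmHg).
#' @export
propagate_compartment_flows <- function(net, chains, cap_viscosity = 9.05,
                                        cfg = flow_solver_config()) {
  sg <- net$segments
  term <- sg[sg$terminal, ]
  if (!all(chains$terminal_id %in% term$id))
    stop("chain references a non-terminal segment")
  if (!all(term$id %in% chains$terminal_id))
    stop("missing chain for terminal segment(s) ",
         paste(setdiff(term$id, chains$terminal_id), collapse = ", "))
  idx <- match(chains$terminal_id, term$id)
  chains$q <- term$flow[idx]
  chains$p_in <- net$nodes$pressure[match(term$to[idx], net$nodes$id)]
  chains$q_per_cap <- chains$q / chains$n_C

  poiseuille_dp <- function(q_nlmin, d_um, l_um, mu_cP) {
    q <- nlmin_to_cgs(q_nlmin)
    cgs_to_mmHg(q * 128 * cP_to_poise(mu_cP) * um_to_cm(l_um) /
                  (pi * um_to_cm(d_um)^4))
  }
  hd <- cfg$inflow_hematocrit
  mu_sv <- segment_viscosity(2 * chains$r_SV, hd, cfg)
  mu_lv <- segment_viscosity(2 * chains$r_LV, hd, cfg)
  dp_c <- poiseuille_dp(chains$q_per_cap, 2 * chains$r_C, chains$L_C, cap_viscosity)
  dp_sv <- poiseuille_dp(chains$q / chains$n_SV, 2 * chains$r_SV, chains$L_SV, mu_sv)
  dp_lv <- poiseuille_dp(chains$q / chains$n_LV, 2 * chains$r_LV, chains$L_LV, mu_lv)
  chains$p_after_C <- chains$p_in - dp_c
  chains$p_after_SV <- chains$p_after_C - dp_sv
  chains$p_after_LV <- chains$p_after_SV - dp_lv
  chains
}
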