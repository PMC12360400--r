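# Vascular smooth muscle flow regulation: Laplace wall tension balanced
# against passive + active wall tension, with activation driven by a
# sigmoidal stimulus combining myogenic, shear-dependent and conducted
# metabolic responses. Diameters and activations relax to steady state
# through a pair of first-order ODEs per arteriole, re-solving network
# flows as diameters change.

#' Regulation model parameters
#'
#' Wall-mechanics and smooth-muscle parameters. Scalar sensitivities are
#' fixed; the diameter-dependent coefficients (passive/active tension
#' strengths and shapes, myogenic sensitivity) are functions of the
#' per-vessel passive reference diameter `D0` and are derived during
#' calibration (see [init_regulation()]).
#'
#' @param iop intraocular pressure, mmHg (external pressure in the Laplace
#'   balance).
#' @param c_shear shear-stress sensitivity, cm^2/dyn.
#' @param c_meta metabolic sensitivity, 1/(uM cm).
#' @param tau_d,tau_a time constants for diameter and activation, s.
#' @param d0_ratio ratio of the passive reference diameter `D0` to the
#'   control diameter `Dc`. The default 1.3 places `D0` in 29-151 um for
#'   control diameters 22-117 um.
#' @param meta_c_ref concentration scale of the conducted metabolic signal,
#'   uM. The signal itself is a model reconstruction: the flow-weighted
#'   integral of hemoglobin desaturation over the downstream pathway with
#'   exponential decay upstream (see [metabolic_signal()]). The default is
#'   scaled so that a full swing of capillary-bed desaturation shifts the
#'   tone stimulus by order one (the width of the activation sigmoid),
#'   giving graded rather than all-or-none vasomotor responses.
#' @param meta_decay_cm decay length of the conducted signal, cm.
#' @return A `regulation_params` list.
#' @export
regulation_params <- function(iop = 15, c_shear = 0.0258, c_meta = 1000,
                              tau_d = 1, tau_a = 20, d0_ratio = 1.3,
                              meta_c_ref = 0.1, meta_decay_cm = 1) {
  stopifnot(tau_d > 0, tau_a > 0, d0_ratio > 1)
  structure(as.list(environment()), class = "regulation_params")
}

# Diameter-dependent wall-mechanics coefficients, D0 in um.
wall_coefficients <- function(d0) {
  list(c_myo = 1.37 / d0,
       c_pass = 1.67 * d0,
       c_pass_p = -0.027 * d0 + 12.52,
       c_act = 1.30 * d0^1.48,
       c_act_p = -0.00146 * d0 + 1.13,
       c_act_pp = -0.00146 * d0 + 0.308)
}

#' Circumferential wall tension from the Laplace law
#'
#' `T = (P - IOP) * D / 2`, with the transmural pressure converted from
#' mmHg to dyn/cm^2 and the diameter from um to cm.
#'
#' @param p intravascular pressure, mmHg.
#' @param iop external (intraocular) pressure, mmHg.
#' @param d diameter, um.
#' @return Tension in dyn/cm.
#' @export
#' @examples
#' laplace_tension(40, 15, 100)  # 166.65 dyn/cm
laplace_tension <- function(p, iop, d) {
  mmHg_to_cgs(p - iop) * um_to_cm(d) / 2
}

#' Total wall tension: passive plus active
#'
#' Passive tension is exponential in diameter; maximal active tension is a
#' Gaussian of diameter scaled by the activation `A` of the vascular smooth
#' muscle.
#'
#' @param d diameter, um.
#' @param a activation in \[0, 1\].
#' @param d0 passive reference diameter, um.
#' @return Tension in dyn/cm.
#' @export
total_tension <- function(d, a, d0) {
  co <- wall_coefficients(d0)
  dr <- d / d0
  co$c_pass * exp(co$c_pass_p * (dr - 1)) +
    a * co$c_act * exp(-((dr - co$c_act_p) / co$c_act_pp)^2)
}

#' Smooth muscle tone stimulus
#'
#' `S_tone = C_myo T_total - C_shear tau_wall - C_meta S_meta + C_tone''`:
#' pressure (via wall tension) raises tone, shear stress and the conducted
#' metabolic signal lower it.
#'
#' @param t_total total wall tension, dyn/cm.
#' @param tau_wall wall shear stress, dyn/cm^2.
#' @param s_meta conducted metabolic signal, uM cm.
#' @param c_myo,c_tone per-vessel myogenic sensitivity and calibrated tone
#'   constant.
#' @param params a [regulation_params()].
#' @return Dimensionless stimulus.
#' @export
stimulus_tone <- function(t_total, tau_wall, s_meta, c_myo, c_tone, params) {
  c_myo * t_total - params$c_shear * tau_wall - params$c_meta * s_meta + c_tone
}

#' Target smooth muscle activation
#'
#' Sigmoid of the tone stimulus: `A_total = 1 / (1 + exp(-S_tone))`.
#'
#' @param s_tone stimulus.
#' @return Activation in (0, 1).
#' @export
target_activation <- function(s_tone) stats::plogis(s_tone)

#' Conducted metabolic signal along the network
#'
#' A reconstruction of the conducted metabolic (PO2) response: for each
#' arteriole the flow-weighted sum, over all downstream segments, of
#' hemoglobin desaturation `(1 - S)` times segment length, attenuated
#' exponentially with the path distance from the vessel, and scaled by the
#' concentration `meta_c_ref`. Hypoxic (desaturated) downstream blood thus
#' produces a dilatory signal that is conducted upstream. When compartment
#' chains with solved capillary saturations are supplied, each terminal
#' also receives the desaturation signal of its capillary compartment.
#'
#' @param net a `vascular_network` with solved flows.
#' @param saturation per-segment mean blood oxyhemoglobin saturation
#'   (vector aligned with `net$segments`).
#' @param params a [regulation_params()].
#' @param chains optional `compartment_chains` with columns `s_out`
#'   (capillary outlet saturation) and `L_C`.
#' @return Vector of signals, uM cm, aligned with `net$segments`.
#' @export
metabolic_signal <- function(net, saturation, params = regulation_params(),
                             chains = NULL) {
  sg <- net$segments
  stopifnot(length(saturation) == nrow(sg))
  q <- abs(sg$flow)
  l_cm <- um_to_cm(sg$length)
  lam <- params$meta_decay_cm
  own <- q * (1 - saturation) * l_cm * exp(-(l_cm / 2) / lam)
  extra <- numeric(nrow(sg))
  if (!is.null(chains) && !is.null(chains$s_out)) {
    idx <- match(chains$terminal_id, sg$id)
    extra[idx] <- chains$q * (1 - chains$s_out) * um_to_cm(chains$L_C)
  }
  # reverse-topological accumulation: g_i = own_i + exp(-L_i/lam) * sum(g_children)
  g <- own + extra * exp(-l_cm / lam)
  topo <- rev(segment_topo_order(net))
  kids <- split(seq_len(nrow(sg)), match(sg$from, sg$to))  # by parent index
  for (i in topo) {
    ki <- kids[[as.character(i)]]
    if (!is.null(ki)) g[i] <- g[i] + exp(-l_cm[i] / lam) * sum(g[ki])
  }
  params$meta_c_ref * g / pmax(q, 1e-12)
}

segment_mid_pressure <- function(net) {
  nd <- net$nodes
  (nd$pressure[match(net$segments$from, nd$id)] +
     nd$pressure[match(net$segments$to, nd$id)]) / 2
}

#' Initialise and calibrate the regulation state
#'
#' Treats the supplied (reference) network as the control state: each
#' arteriole's control diameter `Dc` is its current diameter, the control
#' tension `Tc` is the Laplace tension at the solved control pressures, the
#' passive reference diameter is `D0 = d0_ratio * Dc`, the control
#' activation follows from the tension balance
#' `Tc = T_pass(Dc) + A_c T_act_max(Dc)`, and the per-vessel tone constant
#' `C_tone''` is chosen so the control state is an exact equilibrium of the
#' diameter and activation dynamics under the control flows, shear and
#' metabolic signal.
#'
#' @param net a converged `vascular_network` (see [iterate_flow()]).
#' @param params a [regulation_params()].
#' @param saturation per-segment blood saturation at control (defaults to
#'   the inlet saturation everywhere, i.e. a purely hemodynamic control
#'   state; supply the solved saturations to couple to oxygen transport).
#' @param chains optional chains for the capillary desaturation signal.
#' @return A `regulation_state` list: data frame `vessels` (one row per
#'   segment: `D`, `A`, `D0`, `Dc`, `Tc`, `c_myo`, `c_tone`, `s_meta`,
#'   `saturation`), the network, and bookkeeping fields.
#' @export
init_regulation <- function(net, params = regulation_params(),
                            saturation = NULL, chains = NULL) {
  sg <- net$segments
  if (anyNA(sg$flow)) stop("control flows not solved; run iterate_flow() first")
  if (is.null(saturation)) saturation <- rep(0.92, nrow(sg))
  dc <- sg$diameter
  d0 <- params$d0_ratio * dc
  co <- wall_coefficients(d0)
  p_mid <- segment_mid_pressure(net)
  tc <- laplace_tension(p_mid, params$iop, dc)
  t_pass <- co$c_pass * exp(co$c_pass_p * (dc / d0 - 1))
  t_act_max <- co$c_act * exp(-((dc / d0 - co$c_act_p) / co$c_act_pp)^2)
  a_c <- (tc - t_pass) / t_act_max
  clamped <- a_c < 0.01 | a_c > 0.99
  if (any(clamped))
    warning(sum(clamped), " vessel(s) required control activation outside ",
            "(0.01, 0.99); clamped")
  a_c <- pmin(pmax(a_c, 0.01), 0.99)
  s_meta <- metabolic_signal(net, saturation, params, chains)
  s_tone_c <- stats::qlogis(a_c)
  c_tone <- s_tone_c - co$c_myo * tc + params$c_shear * sg$wall_shear +
    params$c_meta * s_meta
  structure(list(
    vessels = data.frame(id = sg$id, D = dc, A = a_c, D0 = d0, Dc = dc,
                         Tc = tc, c_myo = co$c_myo, c_tone = c_tone,
                         s_meta = s_meta, saturation = saturation),
    net = net, params = params, time = 0), class = "regulation_state")
}

# Re-solve network hemodynamics for the current regulated diameters.
resolve_flows_for_state <- function(state, cfg) {
  net <- state$net
  net$segments$diameter <- state$vessels$D
  net$segments$visc <- segment_viscosity(net$segments$diameter,
                                         net$segments$hd, cfg)
  net <- solve_pressures(net, cfg, warm_start = TRUE)
  compute_flows(net)
}

#' Advance the regulation dynamics by one time step
#'
#' Advances the diameter and activation ODEs,
#' `dD/dt = (1/tau_d)(Dc/Tc)(T - T_total)` and
#' `dA/dt = (1/tau_a)(A_total - A)`, followed by a re-solve of the network
#' flows at the updated diameters. The diameter equation is integrated with
#' a per-vessel exponential (locally linearized) update: near the control
#' state its effective relaxation rate `(Dc/(tau_d Tc)) dT_total/dD` can be
#' an order of magnitude faster than `1/tau_d`, which would force very
#' small explicit-Euler steps; the exponential update is stable at any `dt`
#' and has the same fixed points. The activation equation is advanced by
#' its exact exponential relaxation towards the (frozen) target. If any
#' diameter would still become non-positive the step is retried with a
#' halved `dt`.
#'
#' @param state a `regulation_state`.
#' @param dt time step, s.
#' @param cfg a [flow_solver_config()].
#' @param mode `"active"` evolves both D and A; `"passive"` freezes A at 0
#'   and lets D relax to the passive equilibrium.
#' @return Updated state; the last rate magnitudes are attached in
#'   `state$residual` (dimensionless: `|dD/dt| tau_d / Dc` and
#'   `|dA/dt| tau_a`).
#' @export
step_regulation <- function(state, dt = 0.1, cfg = flow_solver_config(),
                            mode = c("active", "passive")) {
  mode <- match.arg(mode)
  v <- state$vessels
  net <- state$net
  p_mid <- segment_mid_pressure(net)
  a_eff <- if (mode == "passive") rep(0, nrow(v)) else v$A
  rate_fn <- function(d) {
    (1 / state$params$tau_d) * (v$Dc / v$Tc) *
      (laplace_tension(p_mid, state$params$iop, d) -
         total_tension(d, a_eff, v$D0))
  }
  dD_dt <- rate_fn(v$D)
  # local relaxation rate for the exponential update (finite difference)
  eps <- 1e-3 * v$D
  kloc <- -(rate_fn(v$D + eps) - dD_dt) / eps
  if (mode == "active") {
    t_tot <- total_tension(v$D, a_eff, v$D0)
    s_tone <- stimulus_tone(t_tot, net$segments$wall_shear, v$s_meta,
                            v$c_myo, v$c_tone, state$params)
    dA_dt <- (1 / state$params$tau_a) * (target_activation(s_tone) - v$A)
  } else dA_dt <- rep(0, nrow(v))

  h <- dt
  for (halving in 1:12) {
    fac <- ifelse(kloc > 1e-10, (1 - exp(-kloc * h)) / kloc, h)
    d_new <- v$D + fac * dD_dt
    if (all(d_new > 0)) break
    h <- h / 2
  }
  if (any(d_new <= 0)) stop("diameter collapsed to zero during integration")
  state$vessels$D <- d_new
  if (mode == "active") {
    a_target <- v$A + state$params$tau_a * dA_dt  # = A_total
    state$vessels$A <- pmin(pmax(
      a_target + (v$A - a_target) * exp(-h / state$params$tau_a), 0), 1)
  }
  state$time <- state$time + h
  state$net <- resolve_flows_for_state(state, cfg)
  state$residual <- c(diameter = max(abs(dD_dt) * state$params$tau_d / v$Dc),
                      activation = max(abs(dA_dt) * state$params$tau_a))
  state
}

#' Integrate the regulation dynamics to steady state
#'
#' Repeats [step_regulation()] until the scaled rates fall below `tol`
#' (`max |dD/dt| tau_d / Dc < tol` and `max |dA/dt| tau_a < tol`),
#' optionally refreshing the blood-oxygen saturations (and hence the
#' conducted metabolic signal) every `oxygen_every` steps through a
#' user-supplied callback.
#'
#' @param state a `regulation_state` from [init_regulation()].
#' @param dt Euler time step, s.
#' @param tol relative-rate convergence tolerance.
#' @param t_max maximum simulated time, s.
#' @param cfg a [flow_solver_config()].
#' @param mode `"active"` or `"passive"` (see [step_regulation()]).
#' @param oxygen_update optional callback called every `oxygen_every`
#'   steps to refresh the metabolic signal: `function(net)` returning
#'   either a per-segment saturation vector or a list with elements
#'   `saturation` and (optionally) `chains` (a solved chain table whose
#'   capillary desaturation feeds the conducted signal at the terminals).
#' @param oxygen_every steps between saturation refreshes.
#' @return The converged `regulation_state` with a `trajectory` data frame
#'   (time, max scaled rates, mean diameter by order).
#' @export
run_to_steady_state <- function(state, dt = 0.1, tol = 1e-6, t_max = 600,
                                cfg = flow_solver_config(),
                                mode = c("active", "passive"),
                                oxygen_update = NULL, oxygen_every = 10L) {
  mode <- match.arg(mode)
  # refresh the hemodynamic state first so that changed boundary conditions
  # or perturbed diameters are reflected in the very first step's rates
  state$net <- resolve_flows_for_state(state, cfg)
  traj <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (!is.null(oxygen_update) && step %% oxygen_every == 1L) {
      state <- apply_oxygen_update(state, oxygen_update)
    }
    state <- step_regulation(state, dt, cfg, mode)
    if (step %% 10L == 0L || state$residual[["diameter"]] < tol) {
      traj[[length(traj) + 1L]] <-
        c(time = state$time, state$residual,
          mean_d = mean(state$vessels$D))
    }
    done <- state$residual[["diameter"]] < tol &&
      (mode == "passive" || state$residual[["activation"]] < tol)
    if (done) break
    if (state$time >= t_max)
      stop(sprintf(
        "regulation did not reach steady state by t = %g s (rates: D %.3g, A %.3g)",
        t_max, state$residual[["diameter"]], state$residual[["activation"]]))
  }
  if (!is.null(oxygen_update)) {
    # verify self-consistency of the final state with a fresh oxygen solve
    state <- apply_oxygen_update(state, oxygen_update)
  }
  state$trajectory <- as.data.frame(do.call(rbind, traj))
  state
}

apply_oxygen_update <- function(state, oxygen_update) {
  res <- oxygen_update(state$net)
  if (!is.list(res)) res <- list(saturation = res, chains = NULL)
  state$vessels$saturation <- res$saturation
  state$vessels$s_meta <- metabolic_signal(state$net, res$saturation,
                                           state$params, chains = res$chains)
  state
}
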