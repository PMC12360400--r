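# End-to-end simulation pipeline: generate (or take) a network, solve
# hemodynamics, optionally run flow regulation to steady state, solve the
# arteriolar oxygen field, attach and solve the downstream compartment
# chains, and report network oxygenation metrics.

#' Run the full simulation pipeline
#'
#' @param gen_cfg a [generator_config()] describing the network, or an
#'   already-generated `vascular_network`.
#' @param dims a [compartment_dims()].
#' @param params an [oxygen_params()]; `params$m0` is the oxygen demand.
#' @param cd target capillary density, 1/mm^2.
#' @param regulation `"off"` (diameters fixed at the reference state) or
#'   `"on"` (smooth-muscle regulation run to steady state, with the
#'   metabolic signal refreshed from the oxygen field).
#' @param control_m0 oxygen demand defining the control (calibration) state
#'   of the regulation model; the tone constants are chosen so the
#'   reference network is an exact equilibrium at this demand, and demands
#'   different from it drive metabolic dilation or constriction.
#' @param reg_params a [regulation_params()].
#' @param flow_cfg a [flow_solver_config()].
#' @param vol_a arteriolar vessel+tissue volume for the capillary-density
#'   relation, cm^3.
#' @param spacing,sleeve tissue-domain grid spacing and sleeve radius, um.
#' @param oxygen_every regulation steps between oxygen-field refreshes.
#' @param reg_dt,reg_tol,reg_t_max regulation integration controls.
#' @param chain_seed seed for the per-chain capillary-length draws
#'   (defaults to the generator seed plus one).
#' @return A `metrics_report`: scalar metrics (`oef`, `mean_tissue_po2`,
#'   `fraction_below_25`, `mean_downstream_po2`, `tissue_width`), the
#'   threshold curve, capillary summary, radial profile, per-pathway table
#'   `po2_vs_length`, and the underlying `net`, `field`, `chains` objects.
#' @export
run_pipeline <- function(gen_cfg, dims = compartment_dims(),
                         params = oxygen_params(), cd = 500,
                         regulation = c("off", "on"), control_m0 = 2,
                         reg_params = regulation_params(),
                         flow_cfg = flow_solver_config(),
                         vol_a = 0.00115, spacing = 25, sleeve = 100,
                         oxygen_every = 20L, reg_dt = 0.5, reg_tol = 1e-5,
                         reg_t_max = 900, chain_seed = NULL) {
  regulation <- match.arg(regulation)
  if (inherits(gen_cfg, "vascular_network")) {
    net <- gen_cfg
    seed <- 1L
  } else {
    net <- generate_arteriolar_tree(gen_cfg)
    seed <- gen_cfg$seed
  }
  if (is.null(chain_seed)) chain_seed <- seed + 1L
  net <- iterate_flow(net, flow_cfg)
  domain <- tissue_domain(net, spacing = spacing, sleeve = sleeve)

  # compartment structure (capillary counts and lengths) is anatomical:
  # derived once from the reference flows and held fixed across conditions
  # and regulation states; only the flows through it are re-propagated
  ref_chains <- attach_compartments(net, dims = dims, seed = chain_seed)

  chain_stage <- function(n, field, prm) {
    ch <- propagate_compartment_flows(n, ref_chains, cap_viscosity = 9.05,
                                      cfg = flow_cfg)
    dw <- tissue_width_from_density(ch, cd_target = cd, vol_a = vol_a)
    p_in <- field$terminal_po2[as.character(ch$terminal_id)]
    list(chains = chain_oxygen(ch, p_b_in = p_in, d = dw, params = prm),
         d = dw)
  }

  last_field <- NULL
  if (regulation == "on") {
    # calibrate the control state at the baseline demand (including the
    # capillary desaturation feeding the conducted signal), then let the
    # metabolic response to the actual demand drive the diameters
    params_ctrl <- params
    params_ctrl$m0 <- control_m0
    field_ctrl <- solve_greens_field(net, domain, params_ctrl)
    cs_ctrl <- chain_stage(net, field_ctrl, params_ctrl)
    state <- init_regulation(net, reg_params,
                             saturation = field_ctrl$segment_sat,
                             chains = cs_ctrl$chains)
    refresh <- function(n) {
      last_field <<- solve_greens_field(n, domain, params, warm = last_field)
      cs <- chain_stage(n, last_field, params)
      list(saturation = last_field$segment_sat, chains = cs$chains)
    }
    state <- run_to_steady_state(state, dt = reg_dt, tol = reg_tol,
                                 t_max = reg_t_max, cfg = flow_cfg,
                                 mode = "active", oxygen_update = refresh,
                                 oxygen_every = oxygen_every)
    net <- state$net
  }

  field <- solve_greens_field(net, domain, params, warm = last_field)
  cs <- chain_stage(net, field, params)
  chains <- cs$chains
  d <- cs$d

  curve <- fraction_below_threshold(field)
  cap <- summarize_capillary_distribution(chains)
  structure(list(
    oef = oxygen_extraction_fraction(chains$s_out, chains$q,
                                     params$inlet_saturation),
    mean_tissue_po2 = stats::weighted.mean(field$tissue$po2,
                                           field$tissue$volume),
    fraction_below_25 = curve$fraction[curve$threshold == 25],
    mean_downstream_po2 = mean(chains$p_edge),
    tissue_width = d,
    threshold_curve = curve,
    capillary_summary = cap,
    radial_profile = mean_radial_profile(chains, d, params),
    po2_vs_length = data.frame(terminal_id = chains$terminal_id,
                               L_C = chains$L_C, p_out = chains$p_out,
                               p_edge = chains$p_edge, q = chains$q),
    conditions = list(m0 = params$m0, cd = cd,
                      inlet_saturation = params$inlet_saturation,
                      inlet_pressure = net$inlet_pressure,
                      outlet_pressure = net$outlet_pressure,
                      regulation = regulation),
    net = net, field = field, chains = chains),
    class = "metrics_report")
}

#' Sweep oxygen demand or capillary density
#'
#' Runs the pipeline across a range of oxygen demand (`m0`) or capillary
#' density (`cd`) values, with regulation on or off, and tabulates OEF and
#' tissue oxygenation per sweep point. For a density sweep the arteriolar
#' stage is computed once (the arteriolar field does not depend on the
#' capillary density) and only the downstream chain stage is re-solved.
#'
#' @param gen_cfg network generator config (or a `vascular_network`).
#' @param vary `"m0"` or `"cd"`.
#' @param values sweep values: demand in cm^3 O2/100 cm^3/min, or density
#'   in 1/mm^2.
#' @param regulation `"off"` or `"on"`.
#' @param params base [oxygen_params()] (fixed `m0` used for a `cd` sweep).
#' @param ... further arguments to [run_pipeline()].
#' @return data.frame: sweep value, `oef`, `mean_tissue_po2`,
#'   `fraction_below_25`, `mean_downstream_po2`, `tissue_width`.
#' @export
sweep_conditions <- function(gen_cfg, vary = c("m0", "cd"), values,
                             regulation = c("off", "on"),
                             params = oxygen_params(), ...) {
  vary <- match.arg(vary)
  regulation <- match.arg(regulation)
  rows <- vector("list", length(values))
  if (vary == "cd") {
    base <- run_pipeline(gen_cfg, params = params, cd = values[1],
                         regulation = regulation, ...)
    for (i in seq_along(values)) {
      rep_i <- if (i == 1) base else
        rechain_report(base, cd = values[i], params = params)
      rows[[i]] <- report_row(values[i], rep_i)
    }
  } else {
    for (i in seq_along(values)) {
      p_i <- params
      p_i$m0 <- values[i]
      rep_i <- run_pipeline(gen_cfg, params = p_i, regulation = regulation, ...)
      rows[[i]] <- report_row(values[i], rep_i)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- vary
  out
}

# redo the downstream chain stage of an existing report at a new capillary
# density (the arteriolar solution is unchanged)
rechain_report <- function(report, cd, params) {
  chains <- report$chains
  d <- tissue_width_from_density(chains, cd_target = cd)
  p_in <- report$field$terminal_po2[as.character(chains$terminal_id)]
  chains <- chain_oxygen(chains, p_b_in = p_in, d = d, params = params)
  report$oef <- oxygen_extraction_fraction(chains$s_out, chains$q,
                                           params$inlet_saturation)
  report$mean_downstream_po2 <- mean(chains$p_edge)
  report$tissue_width <- d
  report$chains <- chains
  report$conditions$cd <- cd
  report
}

report_row <- function(value, r) {
  data.frame(value = value, oef = r$oef, mean_tissue_po2 = r$mean_tissue_po2,
             fraction_below_25 = r$fraction_below_25,
             mean_downstream_po2 = r$mean_downstream_po2,
             tissue_width = r$tissue_width)
}
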