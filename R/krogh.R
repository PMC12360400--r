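# Krogh cylinder oxygen transport in the capillary compartments: closed-form
# radial profiles with constant consumption, the hypoxic-annulus guard, and
# the tissue-sleeve width implied by a target capillary density.

#' Radial Krogh tissue PO2 profile
#'
#' Closed-form solution of the steady-state radial diffusion equation with
#' constant consumption `M0` in a tissue annulus `r_c <= r <= r_t = r_c + d`
#' around a capillary, with the wall held at the blood PO2 and zero flux at
#' the outer edge:
#' `P(r) = P_wall + (M0/(4K))(r^2 - r_c^2) - (M0 r_t^2/(2K)) ln(r / r_c)`.
#' If the form goes negative the profile is clamped at zero and flagged
#' (hypoxic annulus).
#'
#' @param p_wall wall (blood) PO2, mmHg.
#' @param r_c capillary radius, um.
#' @param d tissue sleeve width, um.
#' @param m0 consumption rate, cm^3 O2/100 cm^3/min.
#' @param krogh_coeff diffusivity times solubility, cm^3 O2/cm/s/mmHg.
#' @param n_r number of radial sample points.
#' @return A `krogh_profile` data.frame with columns `r` (um) and `po2`
#'   (mmHg); attributes `hypoxic` (logical) and `p_edge` (unclamped PO2 at
#'   the outer edge).
#' @export
#' @examples
#' prof <- krogh_radial_profile(25, r_c = 3, d = 22, m0 = 3)
#' attr(prof, "p_edge")
krogh_radial_profile <- function(p_wall, r_c = 3, d = 22, m0 = 2,
                                 krogh_coeff = 6e-10, n_r = 61L) {
  stopifnot(p_wall >= 0, r_c > 0, d >= 0)
  r <- seq(r_c, r_c + d, length.out = n_r)
  po2 <- krogh_po2_at(r, p_wall, r_c, r_c + d, m0, krogh_coeff)
  hypoxic <- any(po2 < 0)
  out <- data.frame(r = r, po2 = pmax(po2, 0))
  class(out) <- c("krogh_profile", "data.frame")
  attr(out, "hypoxic") <- hypoxic
  attr(out, "p_edge") <- po2[n_r]
  out
}

# closed form at radii r (um) for tissue cylinder [r_c, r_t] (um)
krogh_po2_at <- function(r, p_wall, r_c, r_t, m0, krogh_coeff) {
  k <- krogh_coeff
  m <- m0_to_cgs(m0)
  rc <- um_to_cm(r_c); rt <- um_to_cm(r_t); rr <- um_to_cm(r)
  p_wall + (m / (4 * k)) * (rr^2 - rc^2) - (m * rt^2 / (2 * k)) * log(rr / rc)
}

krogh_edge_po2 <- function(p_wall, r_c, d, m0, krogh_coeff) {
  krogh_po2_at(r_c + d, p_wall, r_c, r_c + d, m0, krogh_coeff)
}

# Radius r* <= r_t of the oxygenated annulus: the largest tissue radius a
# capillary at wall PO2 p_wall can supply (P(r*) = 0 and dP/dr(r*) = 0 with
# consumption confined to r <= r*). Returns r_t when the whole sleeve is
# supplied. Units: um.
hypoxic_annulus_radius <- function(p_wall, r_c, d, m0, krogh_coeff) {
  r_t <- r_c + d
  if (p_wall <= 0) return(r_c)
  if (krogh_edge_po2(p_wall, r_c, d, m0, krogh_coeff) >= 0) return(r_t)
  f <- function(r_star) krogh_po2_at(r_star, p_wall, r_c, r_star, m0, krogh_coeff)
  stats::uniroot(f, c(r_c * (1 + 1e-9), r_t), tol = 1e-8)$root
}

#' Capillary density implied by a tissue-sleeve width
#'
#' Total capillary length divided by the total tissue volume: the arteriolar
#' network volume plus the downstream capillary (with sleeve of width `d`),
#' small-venule and large-venule compartment volumes, summed over all
#' pathways.
#'
#' @param chains a `compartment_chains` data.frame.
#' @param d tissue sleeve width, um.
#' @param vol_a arteriolar vessel+tissue volume, cm^3 (default 0.00115).
#' @return Capillary density in 1/mm^2 (capillary length per tissue volume,
#'   mm/mm^3).
#' @export
capillary_density <- function(chains, d, vol_a = 0.00115) {
  mm <- function(um) um / 1000
  num <- sum(chains$n_C * mm(chains$L_C))
  den <- vol_a * 1000 +
    sum(chains$n_C * mm(chains$L_C) * pi * (mm(chains$r_C) + mm(d))^2) +
    sum(chains$n_SV * mm(chains$L_SV) * pi * mm(chains$r_SV)^2) +
    sum(chains$n_LV * mm(chains$L_LV) * pi * mm(chains$r_LV)^2)
  num / den
}

#' Tissue-sleeve width for a target capillary density
#'
#' Inverts [capillary_density()] for the sleeve width `d`: the density is
#' strictly decreasing in `d` (the denominator volume grows), so the root is
#' unique when it exists. Errors if the target exceeds the density at
#' `d = 0`.
#'
#' @param chains a `compartment_chains` data.frame.
#' @param cd_target target capillary density, 1/mm^2 (reference value 500).
#' @param vol_a arteriolar vessel+tissue volume, cm^3.
#' @return Sleeve width `d` in um (solved to 1e-4 um).
#' @export
#' @examples \donttest{
#' # at the reference density of 500/mm^2 the width is around 22 um
#' }
tissue_width_from_density <- function(chains, cd_target, vol_a = 0.00115) {
  stopifnot(cd_target > 0)
  cd0 <- capillary_density(chains, 0, vol_a)
  if (cd0 < cd_target)
    stop(sprintf(
      "infeasible density: target %.3g/mm^2 exceeds the d = 0 supremum %.3g/mm^2",
      cd_target, cd0))
  upper <- 10
  while (capillary_density(chains, upper, vol_a) > cd_target) upper <- upper * 2
  stats::uniroot(function(d) capillary_density(chains, d, vol_a) - cd_target,
                 c(0, upper), tol = 1e-4)$root
}

#' Oxygen transport through a compartment chain
#'
#' Applies the convective Krogh-capillary update to every chain (all
#' capillaries within a compartment are identical, so one representative
#' capillary determines the compartment outcome), then passes the
#' saturation through the venule stages unchanged (no venular oxygen
#' exchange, sleeve width 0).
#'
#' @param chains a `compartment_chains` data.frame with propagated flows
#'   (column `q_per_cap`; see [propagate_compartment_flows()]).
#' @param p_b_in per-chain inlet blood PO2, mmHg (recycled if length 1).
#' @param d tissue sleeve width, um (global across chains for a given
#'   capillary density; see [tissue_width_from_density()]).
#' @param params an [oxygen_params()]; consumption uses `params$m0`.
#' @return `chains` with columns `p_out` (capillary outlet blood PO2),
#'   `s_out` (outlet saturation), `p_edge` (tissue PO2 at the outer edge of
#'   the Krogh cylinder at the downstream end, clamped at 0), and flags
#'   `hypoxic`, `depleted`.
#' @export
chain_oxygen <- function(chains, p_b_in, d, params = oxygen_params()) {
  if (is.null(chains$q_per_cap))
    stop("chains lack propagated flows; run propagate_compartment_flows()")
  n <- nrow(chains)
  p_b_in <- rep_len(p_b_in, n)
  res <- lapply(seq_len(n), function(i) {
    convective_update(p_b_in[i], chains$q_per_cap[i], chains$r_C[i], d,
                      chains$L_C[i], params$m0, params)
  })
  chains$p_in_o2 <- p_b_in
  chains$p_out <- vapply(res, `[[`, numeric(1), "p_out")
  chains$s_out <- vapply(res, `[[`, numeric(1), "s_out")
  chains$depleted <- vapply(res, `[[`, logical(1), "depleted")
  chains$hypoxic <- vapply(res, `[[`, logical(1), "hypoxic")
  edge <- krogh_po2_at(chains$r_C + d, chains$p_out, chains$r_C,
                       chains$r_C + d, params$m0, params$krogh_coeff)
  chains$p_edge <- pmax(edge, 0)
  chains
}

#' Downstream Krogh radial profile for one chain
#'
#' Radial tissue PO2 at the downstream end of the capillaries of a chain
#' (the station used for pathway comparisons).
#'
#' @param chain one row of a solved `chain_oxygen()` result.
#' @param d sleeve width, um.
#' @param params an [oxygen_params()].
#' @param n_r radial samples.
#' @return A `krogh_profile` (see [krogh_radial_profile()]).
#' @export
chain_downstream_profile <- function(chain, d, params = oxygen_params(),
                                     n_r = 61L) {
  krogh_radial_profile(chain$p_out, chain$r_C, d, params$m0,
                       params$krogh_coeff, n_r)
}
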