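# Blood oxygen chemistry (Hill saturation) and convective oxygen transport
# along vessels with diffusive efflux to the surrounding tissue.

#' Oxygen transport parameters
#'
#' @param krogh_coeff Krogh diffusion coefficient (diffusivity times
#'   solubility), cm^3 O2/cm/s/mmHg.
#' @param m0 tissue oxygen demand (maximum consumption rate),
#'   cm^3 O2/100 cm^3/min. Study range 1-4; default 2 (moderate demand).
#' @param p0 Michaelis-Menten half-maximal PO2 for consumption, mmHg.
#' @param c0 oxygen-binding capacity of red blood cells, cm^3 O2/cm^3.
#' @param hd discharge hematocrit of inflowing blood.
#' @param alpha_b solubility of oxygen in blood, cm^3 O2/cm^3/mmHg.
#' @param p50 half-saturation PO2 of the Hill curve, mmHg.
#' @param hill_n Hill exponent.
#' @param inlet_saturation arterial oxyhemoglobin saturation at the network
#'   inlet.
#' @return An `oxygen_params` list.
#' @export
oxygen_params <- function(krogh_coeff = 6e-10, m0 = 2, p0 = 10, c0 = 0.5,
                          hd = 0.4, alpha_b = 3.1e-5, p50 = 26, hill_n = 2.7,
                          inlet_saturation = 0.92) {
  stopifnot(krogh_coeff > 0, m0 >= 0, p0 > 0, c0 > 0, alpha_b > 0, p50 > 0,
            hill_n > 0, inlet_saturation > 0, inlet_saturation < 1)
  structure(as.list(environment()), class = "oxygen_params")
}

#' Oxyhemoglobin saturation (Hill equation) and its inverse
#'
#' `S = P^n / (P^n + P50^n)`; the inverse is the closed form
#' `P = P50 (S / (1 - S))^(1/n)`.
#'
#' @param p_b blood PO2, mmHg (>= 0).
#' @param s saturation in (0, 1).
#' @param params an [oxygen_params()].
#' @return Saturation in \[0, 1\] / PO2 in mmHg.
#' @export
#' @examples
#' hill_saturation(26)          # 0.5 at P50
#' inverse_hill(0.92)           # arterial PO2 at 92% saturation
hill_saturation <- function(p_b, params = oxygen_params()) {
  stopifnot(all(p_b >= 0))
  p_b^params$hill_n / (p_b^params$hill_n + params$p50^params$hill_n)
}

#' @rdname hill_saturation
#' @export
inverse_hill <- function(s, params = oxygen_params()) {
  stopifnot(all(s >= 0), all(s < 1))
  params$p50 * (s / (1 - s))^(1 / params$hill_n)
}

#' Convective oxygen transport rate in blood
#'
#' `f(P_b) = Q (H_D C0 S(P_b) + alpha_b P_b)`: hemoglobin-bound plus
#' dissolved oxygen carried by the blood, in cm^3 O2/s.
#'
#' @param p_b blood PO2, mmHg.
#' @param q_nlmin blood flow, nl/min.
#' @param params an [oxygen_params()].
#' @param hd discharge hematocrit (defaults to `params$hd`).
#' @return Transport rate, cm^3 O2/s.
#' @export
blood_o2_flux <- function(p_b, q_nlmin, params = oxygen_params(),
                          hd = params$hd) {
  nlmin_to_cgs(q_nlmin) *
    (hd * params$c0 * hill_saturation(p_b, params) + params$alpha_b * p_b)
}

# invert f(P_b) for P_b >= 0 given flow and hematocrit; f is strictly
# increasing in P_b. Closed bracket [0, upper] grown as needed.
invert_blood_o2_flux <- function(f_target, q_nlmin, params, hd = params$hd) {
  if (f_target <= 0) return(0)
  upper <- 200
  while (blood_o2_flux(upper, q_nlmin, params, hd) < f_target) upper <- upper * 2
  stats::uniroot(function(p) blood_o2_flux(p, q_nlmin, params, hd) - f_target,
                 c(0, upper), tol = 1e-12)$root
}

#' Convective update of blood PO2 along a Krogh capillary
#'
#' Integrates `df(P_b)/ds = -q_v(s)` along a capillary of length `L_C`
#' surrounded by a tissue sleeve of width `d`. While the wall PO2 is high
#' enough to keep the whole sleeve oxygenated, the efflux is the constant
#' demand `q_v = M0 pi (r_t^2 - r_c^2)` and the update is exact
#' (`f_out = f_in - q_v L_C`). When the radial profile would turn negative,
#' consumption is limited to the oxygenated annulus (Michaelis-Menten-
#' consistent supply) and the equation is integrated in sub-steps.
#' A venule stage (`d = 0`) has zero efflux and leaves PO2 unchanged
#' exactly.
#'
#' @param p_b_in inlet blood PO2, mmHg.
#' @param q_nlmin flow through the single vessel, nl/min (> 0).
#' @param r_c vessel radius, um.
#' @param d tissue sleeve width, um.
#' @param length vessel length, um.
#' @param m0 oxygen demand, cm^3 O2/100 cm^3/min.
#' @param params an [oxygen_params()].
#' @param hd discharge hematocrit.
#' @param n_sub sub-steps used only when the hypoxic-annulus limiter engages.
#' @return List with `p_out`, `s_out`, `f_in`, `f_out` (cm^3 O2/s), and
#'   `depleted` / `hypoxic` flags.
#' @export
convective_update <- function(p_b_in, q_nlmin, r_c, d, length, m0,
                              params = oxygen_params(), hd = params$hd,
                              n_sub = 200L) {
  stopifnot(q_nlmin > 0, p_b_in >= 0)
  r_c_cm <- um_to_cm(r_c); r_t_cm <- um_to_cm(r_c + d); l_cm <- um_to_cm(length)
  m0_cgs <- m0_to_cgs(m0)
  q_v_full <- m0_cgs * pi * (r_t_cm^2 - r_c_cm^2)  # cm^3 O2 / s / cm
  f_in <- blood_o2_flux(p_b_in, q_nlmin, params, hd)

  if (q_v_full == 0) {
    return(list(p_out = p_b_in, s_out = hill_saturation(p_b_in, params),
                f_in = f_in, f_out = f_in, depleted = FALSE, hypoxic = FALSE))
  }

  # exact constant-demand update if the sleeve stays oxygenated throughout
  f_out_const <- f_in - q_v_full * l_cm
  if (f_out_const > 0) {
    p_out <- invert_blood_o2_flux(f_out_const, q_nlmin, params, hd)
    if (krogh_edge_po2(p_out, r_c, d, m0, params$krogh_coeff) >= 0) {
      return(list(p_out = p_out, s_out = hill_saturation(p_out, params),
                  f_in = f_in, f_out = f_out_const,
                  depleted = FALSE, hypoxic = FALSE))
    }
  }

  # hypoxic-annulus / depletion regime: sub-step integration with the
  # efflux limited to the oxygenated annulus radius
  ds <- l_cm / n_sub
  f <- f_in
  p <- p_b_in
  hypoxic <- FALSE
  for (k in seq_len(n_sub)) {
    r_star <- hypoxic_annulus_radius(p, r_c, d, m0, params$krogh_coeff)
    if (r_star < r_c + d) hypoxic <- TRUE
    q_v <- m0_cgs * pi * (um_to_cm(r_star)^2 - r_c_cm^2)
    f <- f - q_v * ds
    if (f <= 0) {
      return(list(p_out = 0, s_out = 0, f_in = f_in, f_out = 0,
                  depleted = TRUE, hypoxic = TRUE))
    }
    p <- invert_blood_o2_flux(f, q_nlmin, params, hd)
  }
  list(p_out = p, s_out = hill_saturation(p, params),
       f_in = f_in, f_out = f, depleted = FALSE, hypoxic = hypoxic)
}
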