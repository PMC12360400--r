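# Network-level oxygenation metrics and cross-network comparison.

#' Oxygen extraction fraction
#'
#' Ratio of oxygen consumption to oxygen delivery across the network:
#' `OEF = sum(Q_i (SaO2 - SvO2_i)) / (Q_total SaO2)`, with `SvO2_i` the
#' saturation at the downstream end of the capillaries of pathway `i` and
#' `Q_i` the pathway flow.
#'
#' @param sv_o2 per-pathway venous-end saturation.
#' @param q per-pathway flow (any consistent unit).
#' @param sa_o2 arterial inlet saturation.
#' @return OEF, dimensionless in \[0, 1\] when `sv_o2 <= sa_o2`.
#' @export
#' @examples
#' oxygen_extraction_fraction(c(0.46, 0.92), q = c(2, 1), sa_o2 = 0.92)  # 1/3
oxygen_extraction_fraction <- function(sv_o2, q, sa_o2 = 0.92) {
  stopifnot(length(sv_o2) == length(q), sa_o2 > 0)
  q_total <- sum(q)
  if (q_total == 0) stop("total pathway flow is zero")
  sum(q * (sa_o2 - sv_o2)) / (q_total * sa_o2)
}

#' Pathway-averaged downstream Krogh radial profile
#'
#' Mean tissue PO2 as a function of radial position at the downstream end
#' of the capillaries, averaged over pathways. The plain average weights
#' every pathway equally; a flow-weighted average is also returned.
#'
#' @param chains a solved [chain_oxygen()] result.
#' @param d sleeve width, um.
#' @param params an [oxygen_params()].
#' @param n_r radial samples.
#' @return data.frame: `r` (um), `po2_mean`, `po2_flow_weighted`,
#'   `po2_min`, `po2_max`.
#' @export
mean_radial_profile <- function(chains, d, params = oxygen_params(), n_r = 41L) {
  profs <- vapply(seq_len(nrow(chains)), function(i) {
    krogh_radial_profile(chains$p_out[i], chains$r_C[i], d, params$m0,
                         params$krogh_coeff, n_r)$po2
  }, numeric(n_r))
  w <- chains$q / sum(chains$q)
  data.frame(r = seq(chains$r_C[1], chains$r_C[1] + d, length.out = n_r),
             po2_mean = rowMeans(profs),
             po2_flow_weighted = as.numeric(profs %*% w),
             po2_min = apply(profs, 1, min),
             po2_max = apply(profs, 1, max))
}

#' Compare the metric reports of two networks
#'
#' Paired differences of the scalar metrics, the pointwise difference of
#' the tissue hypoxia threshold curves, and ordering flags between two
#' pipeline runs that used identical conditions apart from the network
#' itself.
#'
#' @param report_a,report_b `metrics_report` objects from [run_pipeline()].
#' @return List of paired differences and ordering flags.
#' @export
compare_networks <- function(report_a, report_b) {
  ca <- report_a$conditions; cb <- report_b$conditions
  same <- c("m0", "cd", "inlet_saturation", "inlet_pressure", "outlet_pressure",
            "regulation")
  for (f in same) {
    if (!isTRUE(all.equal(ca[[f]], cb[[f]])))
      stop("reports differ in condition '", f, "'; comparison refused")
  }
  stopifnot(all(report_a$threshold_curve$threshold ==
                  report_b$threshold_curve$threshold))
  curve_diff <- data.frame(
    threshold = report_a$threshold_curve$threshold,
    diff = report_a$threshold_curve$fraction - report_b$threshold_curve$fraction)
  list(
    oef_diff = report_a$oef - report_b$oef,
    mean_tissue_po2_diff = report_a$mean_tissue_po2 - report_b$mean_tissue_po2,
    mean_downstream_po2_diff =
      report_a$mean_downstream_po2 - report_b$mean_downstream_po2,
    threshold_curve_diff = curve_diff,
    max_curve_separation = max(abs(curve_diff$diff)),
    lower_downstream_po2 =
      if (report_a$mean_downstream_po2 < report_b$mean_downstream_po2) "A" else "B",
    higher_oef = if (report_a$oef > report_b$oef) "A" else "B")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  OEF: %.3f   (M0 = %g, CD = %g/mm^2, regulation %s)\n",
              x$oef, x$conditions$m0, x$conditions$cd, x$conditions$regulation))
  cat(sprintf("  arteriolar tissue PO2: mean %.1f mmHg; %.1f%% below 25 mmHg\n",
              x$mean_tissue_po2, 100 * x$fraction_below_25))
  cat(sprintf("  downstream capillary-end tissue PO2: mean %.1f mmHg\n",
              x$mean_downstream_po2))
  cat(sprintf("  capillaries: %d total, median %g per compartment; d = %.1f um\n",
              x$capillary_summary$total, x$capillary_summary$median,
              x$tissue_width))
  invisible(x)
}
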