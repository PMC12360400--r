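# Centralized unit conversions. Internal computations are CGS
# (cm, s, dyn, poise); user-facing quantities are um, mmHg, nl/min, cP.

#' Unit conversion constants
#'
#' Named constants used throughout the package to convert between the
#' interface units (micrometres, mmHg, nl/min, centipoise) and the internal
#' CGS system (cm, s, dyn, poise) in which all physical formulas are
#' evaluated.
#'
#' @format A named list:
#' \describe{
#'   \item{mmHg_to_dyn_cm2}{1 mmHg in dyn/cm^2 (1333.22).}
#'   \item{um_to_cm}{1 um in cm.}
#'   \item{nl_min_to_cm3_s}{1 nl/min in cm^3/s.}
#'   \item{cP_to_poise}{1 cP in poise.}
#'   \item{m0_to_cgs}{1 cm^3 O2/100 cm^3/min in cm^3 O2/cm^3/s.}
#' }
#' @export
#' @examples
#' 40 * retinox_units$mmHg_to_dyn_cm2  # arterial inflow pressure in dyn/cm^2
retinox_units <- list(
  mmHg_to_dyn_cm2 = 1333.22,
  um_to_cm        = 1e-4,
  nl_min_to_cm3_s = 1e-6 / 60,
  cP_to_poise     = 1e-2,
  m0_to_cgs       = 1 / (100 * 60)
)

mmHg_to_cgs <- function(p) p * retinox_units$mmHg_to_dyn_cm2
cgs_to_mmHg <- function(p) p / retinox_units$mmHg_to_dyn_cm2
um_to_cm    <- function(x) x * retinox_units$um_to_cm
cm_to_um    <- function(x) x / retinox_units$um_to_cm
nlmin_to_cgs <- function(q) q * retinox_units$nl_min_to_cm3_s
cgs_to_nlmin <- function(q) q / retinox_units$nl_min_to_cm3_s
cP_to_poise <- function(mu) mu * retinox_units$cP_to_poise
m0_to_cgs   <- function(m0) m0 * retinox_units$m0_to_cgs
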