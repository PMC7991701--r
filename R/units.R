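#' Unit conversion constants
#'
#' The solver works internally in CGS units (cm, g, s, dyn).  All
#' user-facing pressures are reported in mmHg and flows in mL/min.
#'
#' @name units
#' @keywords internal
NULL

#' dyn/cm^2 per mmHg
#' @rdname units
#' @export
MMHG <- 1333.22

#' Convert pressure from CGS (dyn/cm^2) to mmHg
#' @param p pressure in dyn/cm^2
#' @return pressure in mmHg
#' @export
to_mmhg <- function(p) p / MMHG

#' Convert pressure from mmHg to CGS (dyn/cm^2)
#' @param p pressure in mmHg
#' @return pressure in dyn/cm^2
#' @export
from_mmhg <- function(p) p * MMHG

#' Convert flow from cm^3/s to mL/min
#' @param q flow in cm^3/s
#' @return flow in mL/min
#' @export
to_ml_min <- function(q) q * 60

#' Convert flow from mL/min to cm^3/s
#' @param q flow in mL/min
#' @return flow in cm^3/s
#' @export
from_ml_min <- function(q) q / 60
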