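#' Reference cross-sectional area of a segment
#'
#' Reference (diastolic) lumen area computed from the segment's
#' proximal and distal radii.  The pulse-wave solver treats each
#' segment as uniform, using the mean of the two radii; strongly
#' tapered vessels are represented in the shipped network as chains of
#' shorter segments joined by junctions.
#'
#' @param segment a segment record (one row of `net$segments`, or any
#'   list with `r_prox_cm` and `r_dist_cm`)
#' @return reference area A0 in cm^2
#' @export
segment_area0 <- function(segment) {
  r <- (segment$r_prox_cm + segment$r_dist_cm) / 2
  pi * r^2
}

#' Tube-law stiffness coefficient
#'
#' beta = sqrt(pi) E h / ((1 - nu^2) A0) with Poisson ratio nu = 0.5
#' (incompressible wall).  Units: dyn/cm^3.
#'
#' @inheritParams segment_area0
#' @return beta in dyn/cm^3
#' @export
segment_beta <- function(segment) {
  A0 <- segment_area0(segment)
  sqrt(pi) * segment$E_dyn_cm2 * segment$h_cm / ((1 - 0.5^2) * A0)
}

#' Elastic tube law: pressure as a function of lumen area
#'
#' P(A) = P_ext + beta (sqrt(A) - sqrt(A0)).  The external pressure
#' `P_ext` is the diastolic reference, taken as 0 (gauge) so that
#' P(A0) = 0 and reported pressures are conventional gauge pressures.
#' Strictly increasing in A.
#'
#' @param A lumen area, cm^2 (vectorised); must be positive
#' @param segment segment record with radii, wall thickness `h_cm` and
#'   Young's modulus `E_dyn_cm2`
#' @param p_ext external/reference pressure, dyn/cm^2
#' @return transmural pressure in dyn/cm^2
#' @export
tube_law <- function(A, segment, p_ext = 0) {
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("tube_law: lumen area must be positive and finite")
  }
  A0 <- segment_area0(segment)
  p_ext + segment_beta(segment) * (sqrt(A) - sqrt(A0))
}

#' Pulse-wave speed
#'
#' c(A) = sqrt((A / rho) dP/dA).  For the square-root tube law this is
#' c = sqrt(beta sqrt(A) / (2 rho)), so c(A0) = sqrt(beta sqrt(A0) /
#' (2 rho)).
#'
#' @inheritParams tube_law
#' @param rho blood density, g/cm^3
#' @return wave speed in cm/s
#' @export
wave_speed <- function(A, segment, rho = 1.06) {
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("wave_speed: lumen area must be positive and finite")
  }
  sqrt(segment_beta(segment) * sqrt(A) / (2 * rho))
}
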