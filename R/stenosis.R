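#' Geometry of a stenosis element on its host segment
#'
#' Evaluates the unstenosed lumen area A0s and diameter D0 at the
#' stenosis start offset from the host segment's reference geometry
#' (linear radius taper between the proximal and distal radii), the
#' stenosed area As under the diameter-based lumen-reduction
#' convention As = A0s (1 - r)^2, and the lesion length Ls.
#'
#' @param spec stenosis specification: list with `segment`,
#'   `start_offset_mm`, `length_mm`, `ratio` (diameter basis)
#' @param segment host segment record
#' @return list with `A0s`, `As` (cm^2), `D0` (cm), `Ls` (cm)
#' @export
stenosis_geometry <- function(spec, segment) {
  x <- spec$start_offset_mm / 10            # cm from proximal end
  L <- segment$length_cm
  stopifnot(x >= 0, spec$length_mm > 0, x + spec$length_mm / 10 <= L + 1e-9,
            spec$ratio >= 0, spec$ratio <= 1)
  r_site <- segment$r_prox_cm + (segment$r_dist_cm - segment$r_prox_cm) * x / L
  A0s <- pi * r_site^2
  list(A0s = A0s,
       As = A0s * (1 - spec$ratio)^2,
       D0 = 2 * r_site,
       Ls = spec$length_mm / 10)
}

#' Trans-stenotic pressure loss (lumped three-term model)
#'
#' Young--Tsai-type pressure drop across a short stenosis:
#' \deqn{\Delta P = \frac{K_v \mu}{A_{0s} D_0} Q
#'   + \frac{K_t \rho}{2 A_{0s}^2}\left(\frac{A_{0s}}{A_s}-1\right)^2 Q|Q|
#'   + \frac{K_u \rho L_s}{A_{0s}} \frac{dQ}{dt}}
#' with viscous coefficient Kv = 32 (Ls/D0) (A0s/As)^2, turbulent
#' (expansion-loss) coefficient Kt = 1.52 and inertance coefficient
#' Ku = 1.2.  For steady flow the drop has the sign of the flow.
#' Full occlusion (As = 0) is not handled here: it is represented as a
#' zero-flow interface by the network machinery.
#'
#' @param Q flow through the stenosis, cm^3/s (vectorised)
#' @param dQdt flow time derivative, cm^3/s^2
#' @param spec stenosis specification (see [stenosis_geometry()])
#' @param segment host segment record
#' @param rho blood density, g/cm^3
#' @param mu blood viscosity, poise
#' @param Kt,Ku turbulent and inertance coefficients
#' @return pressure drop in dyn/cm^2
#' @export
stenosis_pressure_drop <- function(Q, dQdt = 0, spec, segment,
                                   rho = 1.06, mu = 0.04,
                                   Kt = 1.52, Ku = 1.2) {
  k <- stenosis_coefficients(spec, segment, rho, mu, Kt, Ku)
  k$a * Q + k$b * Q * abs(Q) + k$e * dQdt
}

#' Lumped coefficients of the stenosis pressure-loss element
#'
#' The three-term drop is linear in (Q, Q|Q|, dQ/dt):
#' dP = a Q + b Q|Q| + e dQ/dt.  Returns the three coefficients; used
#' both by [stenosis_pressure_drop()] and by the solver's implicit
#' interface coupling.
#'
#' @inheritParams stenosis_pressure_drop
#' @return list with `a` (dyn s/cm^5), `b` (dyn s^2/cm^8), `e`
#'   (dyn s^2/cm^5)
#' @export
stenosis_coefficients <- function(spec, segment, rho = 1.06, mu = 0.04,
                                  Kt = 1.52, Ku = 1.2) {
  g <- stenosis_geometry(spec, segment)
  if (g$As <= 0) {
    stop("stenosis coefficients undefined at full occlusion (As = 0); ",
         "the occlusion is handled as a zero-flow interface")
  }
  Kv <- 32 * (g$Ls / g$D0) * (g$A0s / g$As)^2
  list(a = Kv * mu / (g$A0s * g$D0),
       b = (Kt * rho / (2 * g$A0s^2)) * ((g$A0s / g$As) - 1)^2,
       e = Ku * rho * g$Ls / g$A0s)
}
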