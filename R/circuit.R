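# Vessel mechanics and the lumped flow circuit.
#
# The circuit has three segments in series: popliteal artery (R_p, C_p, node
# P_p), arterioles (R_a(r_a), C_a(r_a), mid node P_a) and veins (R_v, C_v, mid
# node P_v).  Each segment's resistance is split in half around its
# mid-pressure node, so that
#   Q_a = 2 (P_p - P_a) / R_a          (into the arteriolar node)
#   Q_v = 2 (P_a - P_v) / (R_a + R_v)  (arteriolar node -> venous node)
#   Q_vo = 2 (P_v - P_vo) / R_v        (venous node -> outlet)
# ASL perfusion is f = Q_v / V_m.  Cuffing opens the inflow and outflow
# switches (Q_ai = Q_vo = 0) while the internal nodes keep exchanging volume.

#' Poiseuille resistance of a cylindrical vessel
#'
#' `R = 8 eta l / (pi r^4)`.
#'
#' @param radius Inner radius, cm.
#' @param length Vessel length, cm.
#' @param viscosity Dynamic viscosity, mmHg*s.
#' @param units Output units: `"mmHg.min/mL"` (default, the conventional
#'   reporting unit) or `"mmHg.s/mL"` (canonical).
#' @return Resistance in the requested units.
#' @examples
#' poiseuille_resistance(0.25, 40, 3e-5)   # ~0.013 mmHg*min/mL
#' @export
poiseuille_resistance <- function(radius, length, viscosity,
                                  units = c("mmHg.min/mL", "mmHg.s/mL")) {
  units <- match.arg(units)
  if (any(radius <= 0) || any(length <= 0) || any(viscosity <= 0))
    stop("radius, length and viscosity must be strictly positive")
  r <- 8 * viscosity * length / (pi * radius^4)   # mmHg*s/mL
  if (units == "mmHg.min/mL") r / 60 else r
}

#' Arteriolar wall thickness at a given inner radius
#'
#' Wall-volume conservation: the annulus cross-section
#' `(r_a + h_a)^2 - r_a^2` is independent of `r_a`, which gives
#' `h_a = sqrt(r_a^2 + 2 r_a0 h_a0 + h_a0^2) - r_a`.
#'
#' @param r_a Inner radius, um.
#' @param constants An [rh_constants()] list.
#' @return Wall thickness, um.
#' @export
wall_thickness <- function(r_a, constants = rh_constants()) {
  if (any(r_a <= 0)) stop("r_a must be strictly positive")
  r <- r_a * 1e-4
  1e4 * (sqrt(r^2 + 2 * constants$r_a0 * constants$h_a0 + constants$h_a0^2) - r)
}

#' Passive elastic wall tension
#'
#' `T_e = (sigma_1 exp(k_e (r_a - r_a0)/r_a0) - sigma_2) h_a(r_a)`; negative
#' below the radius at which the exponential term balances `sigma_2`
#' (a compressed wall pushes outward).
#'
#' @inheritParams wall_thickness
#' @return Tension, mmHg*cm.
#' @export
elastic_tension <- function(r_a, constants = rh_constants()) {
  if (any(r_a <= 0)) stop("r_a must be strictly positive")
  r <- r_a * 1e-4
  h <- wall_thickness(r_a, constants) * 1e-4
  (constants$sigma_1 * exp(constants$k_e * (r - constants$r_a0) / constants$r_a0) -
     constants$sigma_2) * h
}

#' Maximal (fully activated) muscular wall tension
#'
#' A bell curve in radius, peaking at `r_am`:
#' `T_m = T_m0 exp(-|(r_a - r_am)/(r_at - r_am)|^n_m)`.
#'
#' @inheritParams wall_thickness
#' @return Tension, mmHg*cm, in `(0, T_m0]`.
#' @export
muscular_tension <- function(r_a, constants = rh_constants()) {
  if (any(r_a <= 0)) stop("r_a must be strictly positive")
  r <- r_a * 1e-4
  constants$T_m0 *
    exp(-abs((r - constants$r_am) / (constants$r_at - constants$r_am))^constants$n_m)
}

#' Total wall tension at a radius and activation level
#'
#' `T = T_e(r_a) + A T_m(r_a)` — the tension the wall exerts when the smooth
#' muscle is active at fraction `A`.
#'
#' @inheritParams wall_thickness
#' @param A Smooth-muscle activation in `[0, 1]`.
#' @return Tension, mmHg*cm.
#' @export
wall_tension <- function(r_a, A, constants = rh_constants()) {
  if (any(A < 0) || any(A > 1)) stop("A must lie in [0, 1]")
  elastic_tension(r_a, constants) + A * muscular_tension(r_a, constants)
}

#' Laplace balance: mid-arteriolar pressure from radius and activation
#'
#' The transmural balance is `T = P_a r_a - P_im (r_a + h_a)`; given the wall
#' tension `T_e + A T_m` this solves explicitly for the luminal pressure:
#' `P_a = (T_e + A T_m + P_im (r_a + h_a)) / r_a`.
#'
#' @inheritParams wall_tension
#' @return Pressure `P_a`, mmHg.
#' @seealso [tension_balance_radius()] for the inverse solve.
#' @export
tension_balance_pressure <- function(r_a, A, constants = rh_constants()) {
  if (any(r_a <= 0)) stop("r_a must be strictly positive")
  r <- r_a * 1e-4
  h <- wall_thickness(r_a, constants) * 1e-4
  (wall_tension(r_a, A, constants) + constants$P_im * (r + h)) / r
}

#' Laplace balance: equilibrium radius from pressure and activation
#'
#' Inverts [tension_balance_pressure()] by bracketed root finding on
#' `r_a` in `[10, 400]` um.  Errors (rather than clamping) when no root lies
#' in the bracket, which signals a calibration failure upstream.
#'
#' @param P_a Mid-arteriolar pressure, mmHg.
#' @inheritParams wall_tension
#' @param interval Search bracket for the radius, um.
#' @return Radius, um.
#' @export
tension_balance_radius <- function(P_a, A, constants = rh_constants(),
                                   interval = c(10, 400)) {
  g <- function(r) tension_balance_pressure(r, A, constants) - P_a
  lo <- g(interval[1]); hi <- g(interval[2])
  if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0)
    stop("tension balance has no root in [", interval[1], ", ", interval[2],
         "] um at P_a = ", format(P_a), ", A = ", format(A))
  stats::uniroot(g, interval, tol = 1e-10)$root
}

#' Arteriolar resistance and volume as power laws of the radius
#'
#' `R_a = K_R / r_a^4` and `V_a = K_V r_a^2`, with the constants fixed so that
#' at the reference radius `r_a0` the resistance equals `delta_P_a / Q_r`, the
#' arteriolar time constant `R_a C_a` is 1 s, and `V_a = C_a delta_P_a`.
#'
#' @inheritParams wall_thickness
#' @return A tibble with columns `r_a` (um), `R_a` (mmHg*min/mL), `V_a` (mL).
#' @export
arteriolar_resistance_volume <- function(r_a, constants = rh_constants()) {
  if (any(r_a <= 0)) stop("r_a must be strictly positive")
  r <- r_a * 1e-4
  tibble::tibble(r_a = r_a,
                 R_a = constants$K_R / r^4 / 60,
                 V_a = constants$K_V * r^2)
}

#' Segment flows and ASL perfusion at a circuit state
#'
#' Evaluates the half-split Ohm's-law flows at the given node pressures and
#' arteriolar radius.  The mid-arteriolar pressure is obtained from the
#' tension balance at the current radius and activation.
#'
#' @param P_p,P_v Node pressures, mmHg.
#' @param r_a Arteriolar radius, um.
#' @param A Smooth-muscle activation in `[0, 1]`.
#' @param constants An [rh_constants()] list.
#' @return A tibble with `Q_a`, `Q_v` (mL/min), `P_a` (mmHg) and `f_asl`
#'   (mL/100mL/min).
#' @export
segment_flows <- function(P_p, r_a, P_v, A, constants = rh_constants()) {
  P_a <- tension_balance_pressure(r_a, A, constants)
  R_a <- constants$K_R / (r_a * 1e-4)^4
  Q_a <- 2 * (P_p - P_a) / R_a                       # mL/s
  Q_v <- 2 * (P_a - P_v) / (R_a + constants$R_v)
  f_asl <- Q_v / constants$V_m * 100 * 60
  tibble::tibble(Q_a = Q_a * 60, Q_v = Q_v * 60, P_a = P_a, f_asl = f_asl)
}
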