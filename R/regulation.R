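# Smooth-muscle activation and the four vasoregulation mechanisms.
#
# Four first-order regulatory states x_i (myogenic, shear, ATP, adenosine)
# relax toward stimulus functions y_i that are zero at the calibrated
# baseline.  Their gain-weighted sum plus the baseline offset x_init gives
# the total influence z, mapped to a muscle activation A in (0, 1) by a
# sigmoid.  Sign convention: elevated wall tension raises A (myogenic
# constriction); elevated shear, ATP or adenosine lowers A (dilation), so
# that metabolite accumulation during ischemia de-activates the muscle.

#' Sigmoidal activation of arteriolar smooth muscle
#'
#' `A(z) = 1 / (1 + exp(-2 z))`, strictly increasing, `A(0) = 0.5`, and
#' `A(z) + A(-z) = 1`.
#'
#' @param z Total regulatory influence (dimensionless).
#' @return Activation in `(0, 1)`.
#' @export
activation <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  1 / (1 + exp(-2 * z))
}

#' Total regulatory influence
#'
#' `z = x_init + g_myo x_myo - g_sh x_sh - g_atp x_atp - g_ado x_ado`.
#' The constrictive myogenic influence enters with a positive sign, the three
#' dilatory influences with negative signs.
#'
#' @param x Named list or vector with `x_myo`, `x_sh`, `x_atp`, `x_ado`.
#' @param gains Named list or vector with `g_myo`, `g_sh`, `g_atp`, `g_ado`.
#' @param x_init Baseline influence offset (from [rh_calibrate()]).
#' @return The scalar influence `z`.
#' @export
total_influence <- function(x, gains, x_init) {
  x <- as.list(x); gains <- as.list(gains)
  x_init + gains$g_myo * x$x_myo - gains$g_sh * x$x_sh -
    gains$g_atp * x$x_atp - gains$g_ado * x$x_ado
}

#' Stimulus functions of the four regulatory mechanisms
#'
#' All four are deviations from calibrated baseline references and therefore
#' vanish at rest:
#' `y_myo = s_my (T - T_0)`, `y_sh = s_sh Q_v / r_a^3 - 1`,
#' `y_atp = s_atp (C_atp - C_atp0)`, `y_ado = s_ado (C_ado - C_ado0)`.
#' With the flow stopped (`Q_v = 0`) the shear stimulus is exactly -1.
#'
#' @param T_wall Current arteriolar wall tension, mmHg*cm.
#' @param Q_v Venous-segment flow, mL/min.
#' @param r_a Arteriolar radius, um.
#' @param C_atp Intravascular ATP concentration, uM.
#' @param C_ado Interstitial adenosine concentration, uM.
#' @param calib An [rh_calibrate()] result (baseline references).
#' @param constants An [rh_constants()] list.
#' @return A tibble with columns `y_myo`, `y_sh`, `y_atp`, `y_ado`.
#' @export
regulation_stimuli <- function(T_wall, Q_v, r_a, C_atp, C_ado, calib,
                               constants = rh_constants()) {
  tibble::tibble(
    y_myo = constants$s_my * (T_wall - calib$T_0),
    y_sh  = calib$s_sh_scale * (Q_v / 60) / (r_a * 1e-4)^3 - 1,
    y_atp = constants$s_ATP * (C_atp - calib$C_atp0),
    y_ado = constants$s_ado * (C_ado - calib$C_ado0))
}

#' First-order relaxation of the regulatory states
#'
#' `dx_i/dt = (y_i - x_i) / tau_i`.
#'
#' @param x Current states (named, `x_myo`..`x_ado`).
#' @param y Current stimuli (named, `y_myo`..`y_ado`).
#' @param tau Time constants in s (named, `tau_myo`..`tau_ado`).
#' @return Named numeric vector of derivatives (per second).
#' @export
regulation_rhs <- function(x, y, tau) {
  x <- as.list(x); y <- as.list(y); tau <- as.list(tau)
  if (any(unlist(tau) <= 0)) stop("time constants must be strictly positive")
  c(x_myo = (y$y_myo - x$x_myo) / tau$tau_myo,
    x_sh  = (y$y_sh  - x$x_sh)  / tau$tau_sh,
    x_atp = (y$y_atp - x$x_atp) / tau$tau_atp,
    x_ado = (y$y_ado - x$x_ado) / tau$tau_ado)
}
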