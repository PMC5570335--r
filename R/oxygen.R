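# Two-compartment oxygen transport, RBC ATP release, interstitial adenosine.
#
# Capillary blood carries oxygen bound to hemoglobin (Hill binding) plus a
# dissolved fraction; tissue carries myoglobin-bound (hyperbolic) plus
# dissolved oxygen.  Oxygen diffuses between compartments through a constant
# permeability-surface-area product and is consumed by Michaelis-Menten
# metabolism.  RBCs release ATP at a rate that rises as hemoglobin
# desaturates; the endothelium degrades it.  Interstitial adenosine forms at
# a low aerobic rate that switches to a high rate below the critical tissue
# oxygen pressure, and is cleared by saturable cellular uptake.

#' Oxygen content of capillary blood
#'
#' Hill-bound plus dissolved:
#' `O2c = 4 C_Hb PO2^n / (PO2^n + P50_Hb^n) + w_b alpha PO2`.
#'
#' @param PO2 Oxygen partial pressure, mmHg (values below zero are treated
#'   as zero).
#' @param constants An [rh_constants()] list.
#' @return Concentration, uM.
#' @export
blood_o2_content <- function(PO2, constants = rh_constants()) {
  p <- pmax(PO2, 0)
  n <- constants$n_hill
  s <- p^n / (p^n + constants$P50_Hb^n)
  s[p == 0] <- 0
  4 * constants$C_Hb * s + constants$w_b * constants$alpha * p
}

#' Oxygen content of muscle tissue
#'
#' Myoglobin-bound plus dissolved:
#' `O2t = C_Mb PO2 / (PO2 + P50_Mb) + w_t alpha PO2`.
#'
#' @inheritParams blood_o2_content
#' @return Concentration, uM.
#' @export
tissue_o2_content <- function(PO2, constants = rh_constants()) {
  p <- pmax(PO2, 0)
  constants$C_Mb * p / (p + constants$P50_Mb) + constants$w_t * constants$alpha * p
}

#' Oxygen capacitance slopes of the two compartments
#'
#' The exact analytic derivatives `gamma = dO2/dPO2` of the two content
#' curves, used to convert oxygen fluxes into partial-pressure rates:
#' `gamma_c = 4 C_Hb n P50^n PO2^(n-1) / (PO2^n + P50^n)^2 + w_b alpha` and
#' `gamma_t = C_Mb P50_Mb / (PO2 + P50_Mb)^2 + w_t alpha`.
#'
#' @param PO2c Capillary oxygen tension, mmHg.
#' @param PO2t Tissue oxygen tension, mmHg.
#' @inheritParams blood_o2_content
#' @return A tibble with columns `gamma_c`, `gamma_t` (uM/mmHg), both
#'   strictly positive.
#' @export
o2_capacitance_slopes <- function(PO2c, PO2t, constants = rh_constants()) {
  n <- constants$n_hill; p50 <- constants$P50_Hb
  pc <- pmax(PO2c, 0); pt <- pmax(PO2t, 0)
  gc <- 4 * constants$C_Hb * n * p50^n * pc^(n - 1) / (pc^n + p50^n)^2 +
    constants$w_b * constants$alpha
  gt <- constants$C_Mb * constants$P50_Mb / (pt + constants$P50_Mb)^2 +
    constants$w_t * constants$alpha
  tibble::tibble(gamma_c = gc, gamma_t = gt)
}

#' Michaelis-Menten oxygen consumption of muscle
#'
#' `VO2 = V_max_m O2t / (O2t + K_m_O2)`.  Because `K_m_O2` (0.7 uM) is far
#' below the resting tissue oxygen content, consumption stays essentially at
#' the baseline metabolic rate until the tissue is nearly depleted.
#'
#' @param O2t Tissue oxygen content, uM.
#' @param V_max_m Maximal consumption rate, uM/min (from [rh_calibrate()]).
#' @inheritParams blood_o2_content
#' @return Consumption rate, uM/min.
#' @export
metabolic_rate <- function(O2t, V_max_m, constants = rh_constants()) {
  if (any(O2t < 0)) stop("O2t must be non-negative")
  V_max_m * O2t / (O2t + constants$K_m_O2)
}

#' Saturation-dependent ATP release by red blood cells
#'
#' `R(PO2c) = R0 (1 - R1 S(PO2c))` with `S` the hemoglobin Hill saturation;
#' release is maximal (`R0`) in fully deoxygenated blood and falls to
#' `R0 (1 - R1)` at full saturation.
#'
#' @param PO2c Capillary oxygen tension, mmHg.
#' @inheritParams blood_o2_content
#' @return Release rate, uM/min.
#' @export
atp_release <- function(PO2c, constants = rh_constants()) {
  p <- pmax(PO2c, 0)
  n <- constants$n_hill
  s <- p^n / (p^n + constants$P50_Hb^n)
  s[p == 0] <- 0
  60 * constants$R0 * (1 - constants$R1 * s)
}

#' Two-mode interstitial adenosine formation rate
#'
#' 0.05 uM/min while the tissue oxygen tension is at or above the critical
#' pressure (aerobic), 0.5 uM/min below it (anaerobic).  The boundary uses
#' `>=`; an optional logistic blend (`smooth_fado = 1` in the constants) is
#' available for integrator robustness and is off by default.
#'
#' @param PO2t Tissue oxygen tension, mmHg.
#' @inheritParams blood_o2_content
#' @return Formation rate, uM/min.
#' @export
adenosine_formation <- function(PO2t, constants = rh_constants()) {
  lo <- 60 * constants$F_ado_low; hi <- 60 * constants$F_ado_high
  if (constants$smooth_fado > 0) {
    w <- constants$smooth_width
    hi + (lo - hi) / (1 + exp(-(PO2t - constants$PO2_cr) / w))
  } else {
    ifelse(PO2t >= constants$PO2_cr, lo, hi)
  }
}

#' Right-hand side of the metabolic state equations
#'
#' The four coupled rates for capillary and tissue oxygen tension,
#' intravascular ATP and interstitial adenosine, at perfusion `f`
#' (mL/100mL/min; zero during cuffing, when the convective terms vanish).
#'
#' @param PO2c,PO2t Oxygen tensions, mmHg.
#' @param C_atp,C_ado Metabolite concentrations, uM.
#' @param f Perfusion, mL/100mL/min.
#' @param calib An [rh_calibrate()] result (supplies `D`, `V_max_m`, `O2art`).
#' @param constants An [rh_constants()] list.
#' @return Named numeric vector of derivatives per second
#'   (`PO2c`, `PO2t` in mmHg/s; `C_atp`, `C_ado` in uM/s).
#' @export
metabolite_rhs <- function(PO2c, PO2t, C_atp, C_ado, f, calib,
                           constants = rh_constants()) {
  cst <- constants
  f_s <- f / 100 / 60                       # 1/s
  O2c <- blood_o2_content(PO2c, cst)
  O2t <- tissue_o2_content(PO2t, cst)
  g <- o2_capacitance_slopes(PO2c, PO2t, cst)
  J_d <- cst$alpha * calib$D * (PO2c - PO2t)            # uM/s
  VO2 <- metabolic_rate(O2t, calib$V_max_m, cst) / 60   # uM/s
  dPO2c <- (f_s * (calib$O2art - O2c) - J_d) / (cst$v_c * g$gamma_c)
  dPO2t <- (J_d - VO2) / (cst$v_t * g$gamma_t)
  R_atp <- atp_release(PO2c, cst) / 60                  # uM/s
  dC_atp <- f_s / cst$v_c * (1 - cst$h_d) / (1 - cst$h_t) *
      (cst$C_ATP_in - C_atp) +
    cst$h_t / (1 - cst$h_t) * R_atp -
    2 * cst$k_d / (cst$r_c * (1 - cst$h_t)) * C_atp
  F_ado <- adenosine_formation(PO2t, cst) / 60          # uM/s
  dC_ado <- F_ado - cst$V_max_ado * C_ado / (C_ado + cst$K_m_ado)
  c(PO2c = dPO2c, PO2t = dPO2t, C_atp = dC_atp, C_ado = dC_ado)
}
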