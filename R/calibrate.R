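# Baseline calibration.
#
# The calibration turns a subject's resting perfusion into a complete
# steady state of all eleven model states, plus every derived constant the
# dynamics need.  The construction makes all right-hand sides exactly zero
# at the baseline: node pressures follow from Ohm's law at the resting flow,
# the arteriolar radius from the resistance power law, the baseline
# activation from the Laplace tension balance (its inverse sigmoid is the
# regulatory offset x_init), and the oxygen/metabolite references from the
# steady state of the transport equations.

#' Calibrate the model to a subject's baseline
#'
#' @param subject An [rh_subject()] parameter set.
#' @param constants An [rh_constants()] list.
#' @return An object of class `"rh_calibration"`: a list with the derived
#'   circuit elements (`R_p`, `C_p`, `R_v`, `C_v`, `K_R`, `K_V`), the baseline
#'   operating point (`Q_base` mL/s, `P_p_base`, `P_a_base`, `P_v_base`,
#'   `r_a_base` cm, `A_base`, `x_init`), the regulatory references (`T_0`,
#'   `s_sh_scale`, `C_atp0`, `C_ado0`), the oxygen calibration (`O2art` uM,
#'   `D` 1/s, `V_max_m` uM/min, `PO2c_base`, `PO2t_base`) and the full
#'   baseline state vector `state0`.
#' @examples
#' cal <- rh_calibrate(rh_subject(f_r = 4.8))
#' cal$x_init
#' @export
rh_calibrate <- function(subject = rh_subject(), constants = rh_constants()) {
  cst <- constants
  Q <- subject$f_r / 100 * cst$V_m / 60          # mL/s

  R_p <- subject$r_p_scale * cst$R_p_std
  C_p <- subject$tau_p / R_p       # tau_p is the effective arterial time constant

  P_p <- cst$P_ai - Q * R_p
  P_v <- cst$P_vo + Q * cst$R_v
  R_a <- (P_p - P_v) / Q - cst$R_v / 2
  if (!is.finite(R_a) || R_a <= 0)
    stop("calibration failure: non-positive arteriolar resistance at f_r = ",
         subject$f_r, " (R_p scale ", subject$r_p_scale, ")")
  r_a <- (cst$K_R / R_a)^0.25                    # cm
  if (r_a < 10e-4 || r_a > 400e-4)
    stop("calibration failure: baseline radius ", format(r_a * 1e4),
         " um outside [10, 400] um")
  P_a <- P_p - Q * R_a / 2

  r_um <- r_a * 1e4
  h <- wall_thickness(r_um, cst) * 1e-4
  T_0 <- P_a * r_a - cst$P_im * (r_a + h)
  A <- (T_0 - elastic_tension(r_um, cst)) / muscular_tension(r_um, cst)
  if (!is.finite(A) || A <= 0 || A >= 1)
    stop("calibration failure: baseline activation ", format(A),
         " outside (0, 1); the tension balance cannot hold at this baseline")
  x_init <- -log(1 / A - 1) / 2

  s_sh_scale <- r_a^3 / Q                        # shear stimulus scale

  ## oxygen transport: delivery = diffusion = consumption at baseline
  f_s <- Q / cst$V_m                             # 1/s
  O2art <- blood_o2_content(cst$PO2_art, cst)
  O2c_b <- blood_o2_content(cst$PO2c_base, cst)
  O2t_b <- tissue_o2_content(cst$PO2t_base, cst)
  VO2_b <- f_s * (O2art - O2c_b)                 # uM/s
  if (VO2_b <= 0)
    stop("calibration failure: arterial oxygen content must exceed the ",
         "baseline capillary content")
  D <- VO2_b / (cst$alpha * (cst$PO2c_base - cst$PO2t_base))   # 1/s
  V_max_m <- 60 * VO2_b * (O2t_b + cst$K_m_O2) / O2t_b         # uM/min

  ## metabolite fixed points
  a_conv <- f_s / cst$v_c * (1 - cst$h_d) / (1 - cst$h_t)
  k_deg <- 2 * cst$k_d / (cst$r_c * (1 - cst$h_t))
  R_b <- cst$R0 * (1 - cst$R1 * cst$PO2c_base^cst$n_hill /
                     (cst$PO2c_base^cst$n_hill + cst$P50_Hb^cst$n_hill))  # uM/s
  C_atp0 <- (a_conv * cst$C_ATP_in + cst$h_t / (1 - cst$h_t) * R_b) /
    (a_conv + k_deg)
  C_ado0 <- cst$F_ado_low * cst$K_m_ado / (cst$V_max_ado - cst$F_ado_low)

  state0 <- c(P_p = P_p, r_a = r_a, P_v = P_v,
              x_myo = 0, x_sh = 0, x_atp = 0, x_ado = 0,
              PO2c = cst$PO2c_base, PO2t = cst$PO2t_base,
              C_atp = C_atp0, C_ado = C_ado0)

  structure(list(
    subject = subject, constants = cst,
    R_p = R_p, C_p = C_p, R_v = cst$R_v, C_v = cst$C_v,
    K_R = cst$K_R, K_V = cst$K_V,
    Q_base = Q, P_p_base = P_p, P_a_base = P_a, P_v_base = P_v,
    r_a_base = r_a, A_base = A, x_init = x_init,
    T_0 = T_0, s_sh_scale = s_sh_scale,
    O2art = O2art, D = D, V_max_m = V_max_m,
    PO2c_base = cst$PO2c_base, PO2t_base = cst$PO2t_base,
    C_atp0 = C_atp0, C_ado0 = C_ado0,
    state0 = state0), class = "rh_calibration")
}

#' @export
print.rh_calibration <- function(x, ...) {
  cat("<rh_calibration>\n",
      "  f_r = ", x$subject$f_r, " mL/100mL/min  (Q = ", format(x$Q_base * 60, digits = 5),
      " mL/min)\n",
      "  P_p/P_a/P_v = ", format(x$P_p_base, digits = 4), "/",
      format(x$P_a_base, digits = 4), "/", format(x$P_v_base, digits = 4), " mmHg,",
      "  r_a = ", format(x$r_a_base * 1e4, digits = 4), " um\n",
      "  A_base = ", format(x$A_base, digits = 4),
      ",  x_init = ", format(x$x_init, digits = 4), "\n",
      "  D = ", format(x$D * 60, digits = 4), " /min,  V_max_m = ",
      format(x$V_max_m, digits = 4), " uM/min,  C_atp0 = ",
      format(x$C_atp0, digits = 4), " uM\n", sep = "")
  invisible(x)
}

#' @rdname rh_calibrate
#' @param x An `rh_calibration` object.
#' @param ... Unused.
#' @export
tidy.rh_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("R_p", "C_p", "R_v", "C_v", "Q_base", "P_p_base", "P_a_base",
             "P_v_base", "r_a_base", "A_base", "x_init", "T_0", "D",
             "V_max_m", "C_atp0", "C_ado0"),
    value = c(x$R_p / 60, x$C_p, x$R_v / 60, x$C_v, x$Q_base * 60, x$P_p_base,
              x$P_a_base, x$P_v_base, x$r_a_base * 1e4, x$A_base, x$x_init,
              x$T_0, x$D * 60, x$V_max_m, x$C_atp0, x$C_ado0),
    unit = c("mmHg.min/mL", "mL/mmHg", "mmHg.min/mL", "mL/mmHg", "mL/min",
             "mmHg", "mmHg", "mmHg", "um", "", "", "mmHg.cm", "1/min",
             "uM/min", "uM", "uM"))
}
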