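# Fixed physiological and geometric constants of the calf-perfusion model.
#
# Everything downstream of this file works in one canonical unit system:
# mmHg, seconds, mL, cm, uM.  The user-facing constant list (and the YAML
# config schema) uses the units the quantities are conventionally quoted in
# (mL/min for flows, um for radii, L for limb volume, mM for hemoglobin,
# per-minute for metabolic rates); `rh_constants()` converts once at the
# boundary so that no internal code ever mixes minutes and seconds.

# Defaults in conventional ("table") units.
.rh_table_defaults <- function() {
  list(
    ## circuit
    P_vo    = 14,      # mmHg, venous output pressure
    P_im    = 10,      # mmHg, intramuscular fluid pressure
    Q_r     = 144,     # mL/min, resting flow to the lower leg
    V_m     = 3,       # L, volume of one lower leg
    eta_b   = 3e-5,    # mmHg*s, blood viscosity
    r_a0    = 75,      # um, unstressed arteriolar inner radius
    h_a0    = 25,      # um, unstressed arteriolar wall thickness
    sigma_1 = 11.19,   # mmHg, elastic tension constant
    sigma_2 = 52.51,   # mmHg, elastic tension constant
    k_e     = 4.5,     # -, elastic tension exponent
    T_m0    = 3,       # mmHg*cm, maximal muscular tension
    r_am    = 128,     # um, radius of maximal muscular tension
    r_at    = 174,     # um, muscular tension width constant
    n_m     = 1.75,    # -, muscular tension exponent
    r_p     = 0.25,    # cm, popliteal artery radius
    l_p     = 40,      # cm, popliteal artery length
    delta_P_a = 70,    # mmHg, arteriolar pressure drop P_p - P_v at Q_r
    delta_P_v = 1,     # mmHg, venous pressure drop P_v - P_vo at Q_r
    tau_v   = 10,      # s, venous time constant R_v*C_v
    tau_a   = 1,       # s, arteriolar time constant R_a*C_a at baseline
    ## regulation (wall-derived gains and time constants are fixed)
    g_myo   = 1,       # -, myogenic gain
    g_sh    = 1,       # -, shear gain
    tau_myo = 6,       # s
    tau_sh  = 60,      # s
    s_my    = 3.33,    # 1/(mmHg*cm), myogenic stimulus scale
    s_ATP   = 2.5,     # 1/uM, ATP stimulus scale
    s_ado   = 0.61,    # 1/uM, adenosine stimulus scale
    ## oxygen transport
    alpha   = 1.46,    # uM/mmHg, oxygen solubility
    v_c     = 0.03,    # -, capillary volume fraction
    v_t     = 0.97,    # -, tissue volume fraction
    C_Hb    = 2.33,    # mM, hemoglobin concentration (per blood volume)
    C_Mb    = 365,     # uM, myoglobin concentration
    w_b     = 0.8095,  # -, water fraction of blood
    w_t     = 0.78,    # -, water fraction of tissue
    P50_Hb  = 26.8,    # mmHg, hemoglobin half-saturation pressure
    n_hill  = 2.7,     # -, Hill coefficient of hemoglobin
    P50_Mb  = 2.39,    # mmHg, myoglobin half-saturation pressure
    K_m_O2  = 0.7,     # uM, Michaelis constant of oxygen consumption
    PO2_cr  = 10,      # mmHg, critical oxygen pressure (anaerobic switch)
    ## RBC ATP release / degradation
    R0      = 84,      # uM/min, maximal ATP release rate
    R1      = 0.891,   # -, saturation-dependence of release
    C_ATP_in = 0.1,    # uM, arterial inflow ATP concentration
    r_c     = 3,       # um, capillary radius
    h_t     = 0.4,     # -, tube hematocrit
    h_d     = 0.3,     # -, discharge hematocrit
    k_d     = 2e-4,    # cm/s, ATP degradation constant (endothelial surface)
    ## interstitial adenosine
    V_max_ado  = 100,  # uM/min, adenosine clearance capacity
    K_m_ado    = 200,  # uM, Michaelis constant of clearance
    F_ado_low  = 0.05, # uM/min, aerobic adenosine formation rate
    F_ado_high = 0.5,  # uM/min, anaerobic adenosine formation rate
    ## oxygen baselines used by the calibration (documented assumptions)
    PO2_art   = 95,    # mmHg, arterial oxygen tension
    PO2c_base = 40,    # mmHg, baseline capillary (end-capillary) tension
    PO2t_base = 30,    # mmHg, baseline tissue tension
    ## ASL acquisition
    TI1    = 0.7,      # s, labeling bolus duration
    PLD    = 1.4,      # s, post-labeling delay
    lambda = 0.9,      # mL/g, blood-tissue partition coefficient
    T1b    = 1.65,     # s, arterial blood T1 at 3 T
    dt_sample = 3.35,  # s, ASL repetition interval
    ## numerical options
    smooth_fado  = 0,  # 1 = logistic blend of the adenosine formation switch
    smooth_width = 0.1 # mmHg, blend width when smooth_fado = 1
  )
}

#' Model constants
#'
#' Builds the full set of fixed physiological, geometric and acquisition
#' constants of the calf reactive-hyperemia model, converted to the canonical
#' internal unit system (mmHg, s, mL, cm, uM).  Values can be overridden from
#' a YAML/JSON-style config file and/or by named arguments, both given in the
#' conventional units listed below.
#'
#' Conventional units accepted for overrides: pressures in mmHg; `Q_r` in
#' mL/min; `V_m` in L; radii `r_a0`, `h_a0`, `r_am`, `r_at`, `r_c` in um;
#' `r_p`, `l_p` in cm; `C_Hb` in mM; metabolic rates `R0`, `V_max_ado`,
#' `F_ado_low`, `F_ado_high` in uM/min; times in s.
#'
#' @param file Optional path to a YAML config file whose top-level keys are
#'   constant names (conventional units).
#' @param ... Named overrides (conventional units), applied after `file`.
#' @return A named list of class `"rh_constants"` in canonical units, with the
#'   resolved conventional-unit values kept in `attr(, "table_units")`.
#' @examples
#' cst <- rh_constants()
#' cst$Q_r            # 2.4 mL/s
#' rh_constants(Q_r = 120)$Q_r
#' @export
rh_constants <- function(file = NULL, ...) {
  tab <- .rh_table_defaults()
  if (!is.null(file)) {
    ov <- yaml::read_yaml(file)
    bad <- setdiff(names(ov), names(tab))
    if (length(bad)) stop("unknown constant(s) in config: ", paste(bad, collapse = ", "))
    tab[names(ov)] <- ov
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(tab))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    tab[names(dots)] <- dots
  }
  stopifnot(all(vapply(tab, is.numeric, logical(1))))
  if (any(unlist(tab[c("Q_r", "V_m", "eta_b", "r_a0", "h_a0", "r_p", "l_p")]) <= 0))
    stop("geometry, flow and viscosity constants must be strictly positive")
  if (tab$r_am <= tab$r_a0) stop("r_am must exceed r_a0")

  um <- 1e-4  # um -> cm
  cst <- tab
  cst$Q_r   <- tab$Q_r / 60          # mL/s
  cst$V_m   <- tab$V_m * 1000        # mL
  cst$r_a0  <- tab$r_a0 * um
  cst$h_a0  <- tab$h_a0 * um
  cst$r_am  <- tab$r_am * um
  cst$r_at  <- tab$r_at * um
  cst$r_c   <- tab$r_c * um
  cst$C_Hb  <- tab$C_Hb * 1000       # uM
  cst$R0        <- tab$R0 / 60       # uM/s
  cst$V_max_ado <- tab$V_max_ado / 60
  cst$F_ado_low <- tab$F_ado_low / 60
  cst$F_ado_high <- tab$F_ado_high / 60

  ## derived circuit constants (independent of the subject)
  cst$R_p_std <- poiseuille_resistance(tab$r_p, tab$l_p, tab$eta_b,
                                       units = "mmHg.s/mL")
  cst$P_p_rest <- cst$P_vo + cst$delta_P_v + cst$delta_P_a     # 85 mmHg
  cst$P_ai <- cst$P_p_rest + cst$Q_r * cst$R_p_std             # ~86.877 mmHg
  cst$R_v <- cst$delta_P_v / cst$Q_r          # venous drop is across the full R_v
  cst$C_v <- cst$tau_v / cst$R_v
  R_a0 <- cst$delta_P_a / cst$Q_r                              # R_a at r_a0
  cst$K_R <- R_a0 * cst$r_a0^4
  C_a0 <- cst$tau_a / R_a0
  cst$K_V <- C_a0 * cst$delta_P_a / cst$r_a0^2                 # V_a = C_a*dP_a

  structure(cst, class = "rh_constants", table_units = tab)
}

#' @export
print.rh_constants <- function(x, ...) {
  cat("<rh_constants> ", length(unclass(x)), " constants (canonical units: mmHg, s, mL, cm, uM)\n",
      sep = "")
  cat("  R_p = ", format(x$R_p_std / 60, digits = 4), " mmHg*min/mL, P_ai = ",
      format(x$P_ai, digits = 6), " mmHg, Q_r = ", x$Q_r * 60, " mL/min\n", sep = "")
  invisible(x)
}

#' Subject-level free parameters
#'
#' The seven quantities that vary between subjects and are targeted by the
#' fitting schedules.  Defaults are the healthy-group mean values, which also
#' serve as the "standard parameters" for scenario simulations.
#'
#' @param f_r Resting perfusion, mL/100mL/min.
#' @param g_atp Gain of intravascular ATP-mediated regulation (dimensionless).
#' @param g_ado Gain of interstitial adenosine-mediated regulation.
#' @param tau_atp Time constant of the ATP regulatory state, s.
#' @param tau_ado Time constant of the adenosine regulatory state, s.
#' @param tau_p Arterial time constant at the standard popliteal resistance, s
#'   (sets the popliteal compliance `C_p = tau_p / R_p_std`; the effective
#'   arterial time constant is `r_p_scale * tau_p`).
#' @param r_p_scale Popliteal resistance as a multiple of the standard
#'   Poiseuille value (1 for healthy vessels).
#' @return A named list of class `"rh_subject"`.
#' @examples
#' rh_subject()                  # healthy-group means
#' rh_subject(r_p_scale = 2)     # simulated arterial stenosis
#' @export
rh_subject <- function(f_r = 4.95, g_atp = 15.66, g_ado = 4.18,
                       tau_atp = 15.86, tau_ado = 43.20, tau_p = 4.25,
                       r_p_scale = 1) {
  p <- list(f_r = f_r, g_atp = g_atp, g_ado = g_ado, tau_atp = tau_atp,
            tau_ado = tau_ado, tau_p = tau_p, r_p_scale = r_p_scale)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1, logical(1))))
  if (f_r <= 0 || tau_atp <= 0 || tau_ado <= 0 || tau_p <= 0 || r_p_scale <= 0)
    stop("subject parameters must be strictly positive")
  structure(p, class = "rh_subject")
}

#' @export
print.rh_subject <- function(x, ...) {
  cat("<rh_subject> f_r=", x$f_r, " g_atp=", x$g_atp, " g_ado=", x$g_ado,
      " tau_atp=", x$tau_atp, "s tau_ado=", x$tau_ado, "s tau_p=", x$tau_p,
      "s R_p x", x$r_p_scale, "\n", sep = "")
  invisible(x)
}

#' Fitting bounds for the two cohorts
#'
#' @param mode `"healthy"` or `"patient"`.
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
rh_bounds <- function(mode = c("healthy", "patient")) {
  mode <- match.arg(mode)
  if (mode == "healthy") {
    tibble::tibble(
      param = c("f_r", "g_atp", "g_ado", "tau_atp", "tau_ado", "tau_p"),
      lower = c(2, 1, 1, 6, 12, 1.5),
      upper = c(10, 20, 15, 24, 60, 30))
  } else {
    tibble::tibble(
      param = c("f_r", "g_atp", "tau_atp", "tau_p", "r_p_scale"),
      lower = c(3, 1, 12, 1.5, 1),
      upper = c(8, 12, 36, 25, 6))
  }
}

#' Cuff-occlusion protocol
#'
#' Timing of a post-occlusive reactive hyperemia acquisition.  Time zero is
#' cuff inflation; release occurs at `t_cuff`; samples are spaced `dt_sample`
#' seconds apart (the ASL repetition interval).
#'
#' @param t_cuff Cuff (ischemia) duration, s.
#' @param t_baseline Pre-cuff baseline duration, s.
#' @param t_recovery Post-release recording duration, s.
#' @param dt_sample Sampling interval, s.
#' @return A named list of class `"rh_protocol"`.
#' @examples
#' rh_protocol(120)    # the 2-min cuffing protocol
#' @export
rh_protocol <- function(t_cuff = 120, t_baseline = 120, t_recovery = 300,
                        dt_sample = 3.35) {
  stopifnot(t_cuff > 0, t_baseline > 0, t_recovery > 0, dt_sample > 0)
  structure(list(t_cuff = t_cuff, t_baseline = t_baseline,
                 t_recovery = t_recovery, dt_sample = dt_sample),
            class = "rh_protocol")
}

#' @export
print.rh_protocol <- function(x, ...) {
  cat("<rh_protocol> baseline ", x$t_baseline, " s | cuff ", x$t_cuff,
      " s | recovery ", x$t_recovery, " s | dt ", x$dt_sample, " s\n", sep = "")
  invisible(x)
}
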