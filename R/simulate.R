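# Assembly and integration of the full 11-state system.
#
# The cuff protocol is integrated in three segments (baseline, cuff,
# recovery) with the state carried across the switch times, so the stiff
# solver never steps over a discontinuous right-hand side.  The compiled
# right-hand side (src/rh_deriv.c) is used for speed; a pure-R twin
# (`rh_rhs_r`) built from the exported model operations serves as an
# independent oracle and fallback engine.

# Parameter vector for the compiled RHS; order must match the enum in
# src/rh_deriv.c.
.rh_parms <- function(calib, cuff = FALSE) {
  cst <- calib$constants
  sub <- calib$subject
  c(cuff = as.numeric(cuff), P_ai = cst$P_ai, R_p = calib$R_p, C_p = calib$C_p,
    R_v = calib$R_v, C_v = calib$C_v, K_R = calib$K_R, K_V = calib$K_V,
    P_im = cst$P_im, P_vo = cst$P_vo,
    r_a0 = cst$r_a0, h_a0 = cst$h_a0, sigma_1 = cst$sigma_1,
    sigma_2 = cst$sigma_2, k_e = cst$k_e, T_m0 = cst$T_m0,
    r_am = cst$r_am, r_at = cst$r_at, n_m = cst$n_m,
    x_init = calib$x_init, g_myo = cst$g_myo, g_sh = cst$g_sh,
    g_atp = sub$g_atp, g_ado = sub$g_ado,
    tau_myo = cst$tau_myo, tau_sh = cst$tau_sh,
    tau_atp = sub$tau_atp, tau_ado = sub$tau_ado,
    s_my = cst$s_my, s_sh = calib$s_sh_scale, s_atp = cst$s_ATP,
    s_ado = cst$s_ado, T_0 = calib$T_0,
    C_atp0 = calib$C_atp0, C_ado0 = calib$C_ado0,
    alpha = cst$alpha, v_c = cst$v_c, v_t = cst$v_t, C_Hb = cst$C_Hb,
    P50n = cst$P50_Hb^cst$n_hill, n_hill = cst$n_hill,
    C_Mb = cst$C_Mb, P50_Mb = cst$P50_Mb, w_b = cst$w_b, w_t = cst$w_t,
    O2art = calib$O2art, D = calib$D, V_max_m = calib$V_max_m / 60,
    K_m_O2 = cst$K_m_O2, V_m = cst$V_m,
    conv_atp = (1 - cst$h_d) / ((1 - cst$h_t) * cst$v_c),
    frac_ht = cst$h_t / (1 - cst$h_t),
    R0 = cst$R0, R1 = cst$R1,
    k_deg = 2 * cst$k_d / (cst$r_c * (1 - cst$h_t)),
    C_ATP_in = cst$C_ATP_in,
    V_max_ado = cst$V_max_ado, K_m_ado = cst$K_m_ado,
    F_lo = cst$F_ado_low, F_hi = cst$F_ado_high,
    PO2_cr = cst$PO2_cr,
    smooth_w = if (cst$smooth_fado > 0) cst$smooth_width else 0)
}

#' Pure-R right-hand side of the full model
#'
#' The same 11 coupled derivatives as the compiled engine, assembled from the
#' exported model operations.  Signature follows [deSolve::ode()]: returns a
#' list of the derivative vector and the observables `A`, `Qv` (mL/s), `z`.
#' Mainly of interest for verification; simulation normally runs the
#' compiled twin.
#'
#' @param t Time, s (unused; the system is autonomous within a phase).
#' @param y Named state vector (`P_p`, `r_a` in cm, `P_v`, `x_myo`, `x_sh`,
#'   `x_atp`, `x_ado`, `PO2c`, `PO2t`, `C_atp`, `C_ado`).
#' @param parms Parameter vector from the calibration (internal layout).
#' @return `list(derivatives, observables)`.
#' @export
rh_rhs_r <- function(t, y, parms) {
  q <- parms
  PO2c <- max(y[["PO2c"]], 0); PO2t <- max(y[["PO2t"]], 0)
  ra <- y[["r_a"]]

  z <- q[["x_init"]] + q[["g_myo"]] * y[["x_myo"]] - q[["g_sh"]] * y[["x_sh"]] -
    q[["g_atp"]] * y[["x_atp"]] - q[["g_ado"]] * y[["x_ado"]]
  A <- 1 / (1 + exp(-2 * z))
  ha <- sqrt(ra^2 + 2 * q[["r_a0"]] * q[["h_a0"]] + q[["h_a0"]]^2) - ra
  Te <- (q[["sigma_1"]] * exp(q[["k_e"]] * (ra - q[["r_a0"]]) / q[["r_a0"]]) -
           q[["sigma_2"]]) * ha
  Tm <- q[["T_m0"]] *
    exp(-abs((ra - q[["r_am"]]) / (q[["r_at"]] - q[["r_am"]]))^q[["n_m"]])
  Twall <- Te + A * Tm
  Pa <- (Twall + q[["P_im"]] * (ra + ha)) / ra

  Ra <- q[["K_R"]] / ra^4
  Qa <- 2 * (y[["P_p"]] - Pa) / Ra
  Qv <- 2 * (Pa - y[["P_v"]]) / (Ra + q[["R_v"]])
  cuff <- q[["cuff"]] > 0.5
  Qai <- if (cuff) 0 else (q[["P_ai"]] - y[["P_p"]]) / q[["R_p"]]
  Qvo <- if (cuff) 0 else (y[["P_v"]] - q[["P_vo"]]) / q[["R_v"]]

  y_myo <- q[["s_my"]] * (Twall - q[["T_0"]])
  y_sh <- q[["s_sh"]] * Qv / ra^3 - 1
  y_atp <- q[["s_atp"]] * (y[["C_atp"]] - q[["C_atp0"]])
  y_ado <- q[["s_ado"]] * (y[["C_ado"]] - q[["C_ado0"]])

  # occlusion is complete for transport: convective terms see zero perfusion
  f <- if (cuff) 0 else Qv / q[["V_m"]]
  n <- q[["n_hill"]]; p50n <- q[["P50n"]]
  pcn <- PO2c^n
  sat <- if (PO2c > 0) pcn / (pcn + p50n) else 0
  O2c <- 4 * q[["C_Hb"]] * sat + q[["w_b"]] * q[["alpha"]] * PO2c
  O2t <- q[["C_Mb"]] * PO2t / (PO2t + q[["P50_Mb"]]) +
    q[["w_t"]] * q[["alpha"]] * PO2t
  gc <- (if (PO2c > 0)
    4 * q[["C_Hb"]] * n * p50n * PO2c^(n - 1) / (pcn + p50n)^2 else 0) +
    q[["w_b"]] * q[["alpha"]]
  gt <- q[["C_Mb"]] * q[["P50_Mb"]] / (PO2t + q[["P50_Mb"]])^2 +
    q[["w_t"]] * q[["alpha"]]
  Jd <- q[["alpha"]] * q[["D"]] * (y[["PO2c"]] - y[["PO2t"]])
  VO2 <- q[["V_max_m"]] * O2t / (O2t + q[["K_m_O2"]])
  Ratp <- q[["R0"]] * (1 - q[["R1"]] * sat)
  Fado <- if (q[["smooth_w"]] > 0) {
    q[["F_hi"]] + (q[["F_lo"]] - q[["F_hi"]]) /
      (1 + exp(-(PO2t - q[["PO2_cr"]]) / q[["smooth_w"]]))
  } else if (PO2t >= q[["PO2_cr"]]) q[["F_lo"]] else q[["F_hi"]]

  dy <- c(
    P_p = (Qai - Qa) / q[["C_p"]],
    r_a = (Qa - Qv) / (2 * q[["K_V"]] * ra),
    P_v = (Qv - Qvo) / q[["C_v"]],
    x_myo = (y_myo - y[["x_myo"]]) / q[["tau_myo"]],
    x_sh = (y_sh - y[["x_sh"]]) / q[["tau_sh"]],
    x_atp = (y_atp - y[["x_atp"]]) / q[["tau_atp"]],
    x_ado = (y_ado - y[["x_ado"]]) / q[["tau_ado"]],
    PO2c = (f * (q[["O2art"]] - O2c) - Jd) / (q[["v_c"]] * gc),
    PO2t = (Jd - VO2) / (q[["v_t"]] * gt),
    C_atp = f * q[["conv_atp"]] * (q[["C_ATP_in"]] - y[["C_atp"]]) +
      q[["frac_ht"]] * Ratp - q[["k_deg"]] * y[["C_atp"]],
    C_ado = Fado - q[["V_max_ado"]] * y[["C_ado"]] / (y[["C_ado"]] + q[["K_m_ado"]]))
  list(dy, c(A = A, Qv = Qv, z = z))
}

.rh_integrate <- function(state, times, parms, engine, method, rtol, atol, hini) {
  if (engine == "C") {
    out <- deSolve::ode(y = state, times = times, func = "rh_derivs",
                        parms = parms, dllname = "rhasl", initfunc = "rh_init",
                        nout = 3, outnames = c("A", "Qv", "z"),
                        method = method, rtol = rtol, atol = atol,
                        hini = hini, maxsteps = 50000)
  } else {
    out <- deSolve::ode(y = state, times = times, func = rh_rhs_r,
                        parms = parms, method = method, rtol = rtol,
                        atol = atol, hini = hini, maxsteps = 50000)
  }
  if (attr(out, "istate")[1] < 0)
    stop("integrator failure at t = ", utils::tail(out[, 1], 1),
         "; last state: ",
         paste(signif(utils::tail(out, 1)[-1], 4), collapse = ", "))
  out
}

#' Simulate a cuff-occlusion protocol
#'
#' Integrates the full model (circuit, regulation, oxygen, metabolites) from
#' the calibrated baseline through baseline, cuff and recovery phases, and
#' returns the trajectory sampled on the requested grid.  Time zero is cuff
#' inflation; the cuff is released at `protocol$t_cuff`.
#'
#' @param subject An [rh_subject()] parameter set.
#' @param protocol An [rh_protocol()].
#' @param constants An [rh_constants()] list.
#' @param times Output times, s (default: the protocol's ASL sampling grid
#'   from `-t_baseline` to `t_cuff + t_recovery`).  Use a fine grid for
#'   continuous-curve work.
#' @param engine `"C"` (compiled RHS, default) or `"R"` (pure-R twin).
#' @param method Integrator: `"lsoda"` (stiff, default) or `"rk4"` (fixed
#'   step `hini`, for verification).
#' @param rtol,atol Solver tolerances.
#' @param hini Fixed step for `method = "rk4"`, s.
#' @param calib Optionally a precomputed [rh_calibrate()] result (must match
#'   `subject`/`constants`).
#' @return A tibble with columns `time_s`, `perfusion` (mL/100mL/min),
#'   `phase` (`baseline`/`cuff`/`recovery`), the 11 state variables (radius
#'   reported as `r_a_um`), and the observables `A` and `z`.  The protocol,
#'   subject and calibration ride along as attributes.
#' @examples
#' \donttest{
#' sim <- rh_simulate(rh_subject(), rh_protocol(t_cuff = 120))
#' rh_characterize(sim)
#' }
#' @export
rh_simulate <- function(subject = rh_subject(), protocol = rh_protocol(),
                        constants = rh_constants(), times = NULL,
                        engine = c("C", "R"), method = c("lsoda", "rk4"),
                        rtol = 1e-8, atol = 1e-8, hini = NULL, calib = NULL) {
  engine <- match.arg(engine); method <- match.arg(method)
  if (is.null(calib)) calib <- rh_calibrate(subject, constants)
  if (is.null(times))
    times <- seq(-protocol$t_baseline, protocol$t_cuff + protocol$t_recovery,
                 by = protocol$dt_sample)
  times <- sort(unique(times))
  t_rel <- protocol$t_cuff
  if (is.null(hini)) hini <- if (method == "rk4") 0.005 else 0

  segs <- list(
    list(from = min(times[1], 0), to = 0, cuff = FALSE),
    list(from = 0, to = t_rel, cuff = TRUE),
    list(from = t_rel, to = max(times[length(times)], t_rel), cuff = FALSE))

  state <- calib$state0
  rows <- list()
  for (s in segs) {
    if (s$to <= s$from) next
    tt <- sort(unique(c(s$from, times[times > s$from & times <= s$to], s$to)))
    out <- .rh_integrate(state, tt, .rh_parms(calib, cuff = s$cuff),
                         engine, method, rtol, atol, hini)
    state <- out[nrow(out), 2:12]
    names(state) <- names(calib$state0)
    keep <- out[, 1] %in% times & out[, 1] > s$from | out[, 1] == times[1]
    if (any(keep)) rows[[length(rows) + 1]] <- out[keep, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, 1]), , drop = FALSE]

  res <- tibble::as_tibble(as.data.frame(out))
  names(res)[1] <- "time_s"
  res$perfusion <- res$Qv / constants$V_m * 100 * 60
  res$r_a_um <- res$r_a * 1e4
  res$phase <- dplyr::case_when(
    res$time_s < 0 ~ "baseline",
    res$time_s < t_rel ~ "cuff",
    TRUE ~ "recovery")
  res <- res[, c("time_s", "perfusion", "phase", "P_p", "r_a_um", "P_v",
                 "x_myo", "x_sh", "x_atp", "x_ado", "PO2c", "PO2t",
                 "C_atp", "C_ado", "A", "z")]
  attr(res, "protocol") <- protocol
  attr(res, "subject") <- subject
  attr(res, "calibration") <- calib
  res
}

#' Peak and time-to-peak of a reactive hyperemia response
#'
#' The peak is the maximum perfusion among post-release samples; TTP is
#' measured from cuff release to that sample, with ties broken by the
#' earliest sample.
#'
#' @param trace A tibble with `time_s`, `perfusion` and `phase` columns (as
#'   produced by [rh_simulate()], [rh_generate_trace()] or [rh_read_trace()]).
#' @param t_release Cuff release time, s; defaults to the trace's protocol
#'   attribute.
#' @return A one-row tibble with `peak` (mL/100mL/min), `ttp` (s), and
#'   `t_peak` (absolute time of the peak sample).
#' @export
rh_characterize <- function(trace, t_release = NULL) {
  if (is.null(t_release)) {
    prot <- attr(trace, "protocol")
    if (is.null(prot)) stop("no protocol attribute; supply t_release")
    t_release <- prot$t_cuff
  }
  post <- trace[trace$time_s >= t_release & trace$phase != "cuff", ]
  if (nrow(post) == 0) stop("trace contains no post-release samples")
  i <- which.max(post$perfusion)           # which.max takes the earliest tie
  tibble::tibble(peak = post$perfusion[i],
                 ttp = post$time_s[i] - t_release,
                 t_peak = post$time_s[i])
}
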