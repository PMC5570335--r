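test_that("blood oxygen content follows Hill binding plus dissolved oxygen", {
  cst <- fix_constants()
  expect_equal(blood_o2_content(0), 0)
  # half-saturation: 2 C_Hb bound + dissolved
  expect_equal(blood_o2_content(26.8), 2 * 2330 + 0.8095 * 1.46 * 26.8,
               tolerance = 1e-10)
  p <- seq(0, 150, by = 1)
  o <- blood_o2_content(p)
  expect_true(all(diff(o) > 0))
  expect_lt(max(o), 4 * 2330 + 0.8095 * 1.46 * 150)   # saturating toward 4 C_Hb
})

test_that("tissue oxygen content follows hyperbolic myoglobin binding", {
  cst <- fix_constants()
  expect_equal(tissue_o2_content(0), 0)
  expect_equal(tissue_o2_content(cst$P50_Mb),
               365 / 2 + 0.78 * 1.46 * cst$P50_Mb, tolerance = 1e-10)
  p <- seq(0, 150, by = 0.5)
  expect_true(all(diff(tissue_o2_content(p)) > 0))
})

test_that("capacitance slopes equal numerical derivatives of the content curves", {
  cst <- fix_constants()
  p <- c(2, 5, 10, 20, 26.8, 40, 60, 95, 140)
  h <- 1e-4
  g <- o2_capacitance_slopes(p, p, cst)
  gc_num <- (blood_o2_content(p + h) - blood_o2_content(p - h)) / (2 * h)
  gt_num <- (tissue_o2_content(p + h) - tissue_o2_content(p - h)) / (2 * h)
  expect_lt(max(abs(g$gamma_c - gc_num) / gc_num), 1e-6)
  expect_lt(max(abs(g$gamma_t - gt_num) / gt_num), 1e-6)
  expect_true(all(g$gamma_c > 0) && all(g$gamma_t > 0))
})

test_that("metabolic rate is Michaelis-Menten and near-maximal at baseline", {
  cal <- fix_calib()
  expect_equal(metabolic_rate(0.7, 100), 50)
  expect_equal(metabolic_rate(0, 100), 0)
  O2t_b <- tissue_o2_content(cal$PO2t_base)
  expect_equal(metabolic_rate(O2t_b, cal$V_max_m) / cal$V_max_m, 1,
               tolerance = 0.01)
})

test_that("RBC ATP release rises with desaturation", {
  expect_equal(atp_release(0), 84)
  expect_equal(atp_release(1e6), 84 * (1 - 0.891), tolerance = 1e-4)
  expect_equal(atp_release(26.8), 84 * (1 - 0.891 / 2), tolerance = 1e-10)
  p <- seq(0, 120, by = 1)
  expect_true(all(diff(atp_release(p)) < 0))
})

test_that("adenosine formation switches at the critical oxygen pressure", {
  expect_equal(adenosine_formation(30), 0.05)
  expect_equal(adenosine_formation(5), 0.5)
  expect_equal(adenosine_formation(10), 0.05)    # boundary belongs to >= branch
})

test_that("metabolic state equations are stationary at the calibrated baseline", {
  cal <- fix_calib()
  d <- metabolite_rhs(cal$PO2c_base, cal$PO2t_base, cal$C_atp0, cal$C_ado0,
                      fix_subject()$f_r, cal, fix_constants())
  expect_lt(max(abs(d)), 1e-12)
  # adenosine clearance at its baseline equals the aerobic formation rate
  expect_equal(60 * fix_constants()$V_max_ado * cal$C_ado0 /
                 (cal$C_ado0 + fix_constants()$K_m_ado), 0.05,
               tolerance = 1e-10)
})

test_that("a closed two-compartment system conserves total oxygen", {
  cal <- fix_calib()
  cst <- fix_constants()
  cal0 <- cal
  cal0$V_max_m <- 0                               # consumption off, f = 0
  rhs <- function(t, y, p) {
    d <- metabolite_rhs(y[1], y[2], cal$C_atp0, cal$C_ado0, 0, cal0, cst)
    list(c(d[["PO2c"]], d[["PO2t"]]))
  }
  out <- deSolve::ode(c(60, 10), times = seq(0, 300, by = 5), rhs,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  tot <- cst$v_c * blood_o2_content(out[, 2]) +
    cst$v_t * tissue_o2_content(out[, 3])
  expect_lt(diff(range(tot)) / tot[1], 1e-7)
  # the two tensions equilibrate
  expect_equal(unname(out[nrow(out), 2]), unname(out[nrow(out), 3]),
               tolerance = 1e-3)
})

test_that("tissue PO2 crosses the critical pressure on the myoglobin schedule", {
  sim <- fix_sim_5min()
  cuff <- sim[sim$phase == "cuff", ]
  cross <- cuff$time_s[which(cuff$PO2t < 10)[1]]
  expect_gte(cross, 100)
  expect_lte(cross, 300)
  # adenosine flat before the crossing, rising after
  pre <- cuff$C_ado[cuff$time_s < cross - 5]
  post <- cuff$C_ado[cuff$time_s > cross + 20]
  expect_lt(max(pre) - min(pre), 1e-3)
  expect_gt(max(post), max(pre) + 0.05)
})

test_that("concentrations stay non-negative through a 10-minute occlusion", {
  sim <- rh_simulate(fix_subject(), rh_protocol(600, t_baseline = 30),
                     times = seq(-30, 900, by = 1))
  expect_gt(min(sim$C_atp), 0)
  expect_gt(min(sim$C_ado), 0)
  expect_gt(min(sim$PO2c), -1e-6)      # solver-tolerance guard at depletion
  expect_gt(min(sim$PO2t), -1e-6)
  expect_lt(max(sim$C_atp), 1)         # intravascular ATP stays sub-micromolar
})
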