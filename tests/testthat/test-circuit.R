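test_that("Poiseuille resistance reproduces the standard popliteal values", {
  R <- poiseuille_resistance(0.25, 40, 3e-5)
  expect_equal(R, 0.013, tolerance = 0.05)                      # printed precision
  expect_equal(R * 144, 1.8775, tolerance = 1e-4)               # drop at 144 mL/min
  # r^-4 scaling and linear length/viscosity scaling
  expect_equal(poiseuille_resistance(0.5, 40, 3e-5), R / 16)
  expect_equal(poiseuille_resistance(0.25, 80, 3e-5), 2 * R)
  expect_error(poiseuille_resistance(-1, 40, 3e-5), "positive")
  expect_error(poiseuille_resistance(0.25, 40, 0), "positive")
})

test_that("wall thickness conserves wall volume and has the right limits", {
  cst <- fix_constants()
  expect_equal(wall_thickness(75), 25, tolerance = 1e-12)
  # direct evaluation at 128 um
  expect_equal(wall_thickness(128), sqrt(128^2 + 2 * 75 * 25 + 25^2) - 128,
               tolerance = 1e-12)
  r <- seq(20, 350, by = 5)
  h <- wall_thickness(r)
  annulus <- (r + h)^2 - r^2
  expect_lt(diff(range(annulus)) / annulus[1], 1e-10)   # conservation
  expect_true(all(diff(h) < 0))                          # h -> 0+ monotonically
  expect_true(all(h > 0))
})

test_that("elastic tension is negative at rest, zero at the bracket root, increasing", {
  cst <- fix_constants()
  expect_equal(elastic_tension(75), (11.19 - 52.51) * 25e-4, tolerance = 1e-10)
  r0 <- 75 * (1 + log(52.51 / 11.19) / 4.5)    # bracket-root radius, um
  expect_equal(elastic_tension(r0), 0, tolerance = 1e-12)
  r <- seq(75, 300, by = 1)
  expect_true(all(diff(elastic_tension(r)) > 0))
})

test_that("muscular tension peaks at r_am with the stated shape", {
  expect_equal(muscular_tension(128), 3)
  expect_equal(muscular_tension(174), 3 / exp(1))
  expect_equal(muscular_tension(128 + 17), muscular_tension(128 - 17))  # even
  r <- seq(20, 350, by = 1)
  Tm <- muscular_tension(r)
  expect_true(all(Tm > 0 & Tm <= 3))
})

test_that("tension balance forward and inverse solves are consistent", {
  # at low-to-moderate activation the balance pressure is monotone in the
  # radius, so the inverse solve must reproduce the radius exactly
  grid <- expand.grid(r = c(40, 60, 75, 100, 130, 180, 250),
                      A = c(0, 0.1, 0.45))
  for (i in seq_len(nrow(grid))) {
    Pa <- tension_balance_pressure(grid$r[i], grid$A[i])
    r2 <- tension_balance_radius(Pa, grid$A[i])
    expect_equal(r2, grid$r[i], tolerance = 1e-8)
  }
  # at high activation multiple equilibria exist (myogenic instability); the
  # inverse solve must still return a valid root of the balance
  for (A in c(0.8, 1)) {
    Pa <- tension_balance_pressure(130, A)
    r2 <- tension_balance_radius(Pa, A)
    expect_equal(tension_balance_pressure(r2, A), Pa, tolerance = 1e-8)
  }
  # A = 0: pressure balancing the elastic tension alone round-trips
  Pa0 <- tension_balance_pressure(120, 0)
  expect_equal(tension_balance_radius(Pa0, 0), 120, tolerance = 1e-8)
  expect_error(tension_balance_radius(-1000, 0.5), "no root")
})

test_that("arteriolar resistance/volume power laws meet the calibration", {
  cst <- fix_constants()
  rv <- arteriolar_resistance_volume(75, cst)
  expect_equal(rv$R_a, 70 / 144, tolerance = 1e-10)   # delta_P_a / Q_r
  rv2 <- arteriolar_resistance_volume(37.5, cst)
  expect_equal(rv2$R_a, 16 * rv$R_a)
  expect_equal(rv2$V_a, rv$V_a / 4)
  # C_a = V_a / delta_P_a and R_a * C_a = 1 s at baseline
  C_a <- rv$V_a / 70
  expect_equal(rv$R_a * 60 * C_a, 1, tolerance = 1e-10)
  # monotone decrease of R_a in r_a
  Ra <- arteriolar_resistance_volume(seq(20, 300, 5), cst)$R_a
  expect_true(all(diff(Ra) < 0))
})

test_that("segment flows recover resting flow at baseline and vanish at equal pressures", {
  cal <- fix_calib()
  cst <- fix_constants()
  s <- cal$state0
  fl <- segment_flows(s[["P_p"]], s[["r_a"]] * 1e4, s[["P_v"]], cal$A_base, cst)
  expect_equal(fl$Q_v, fix_subject()$f_r / 100 * cst$V_m, tolerance = 1e-8)
  expect_equal(fl$Q_a, fl$Q_v, tolerance = 1e-8)
  expect_equal(fl$f_asl, fix_subject()$f_r, tolerance = 1e-8)
  # equal node pressures at the tension-balance pressure: no flow anywhere
  Pa <- tension_balance_pressure(90, 0.3, cst)
  fl0 <- segment_flows(Pa, 90, Pa, 0.3, cst)
  expect_equal(fl0$Q_a, 0, tolerance = 1e-12)
  expect_equal(fl0$Q_v, 0, tolerance = 1e-12)
  # identity: f_asl * V_m == Q_v
  expect_equal(fl$f_asl * cst$V_m / 100, fl$Q_v)
})

test_that("circuit right-hand side is stationary at baseline and decays under cuff", {
  cal <- fix_calib()
  d0 <- rh_rhs_r(0, cal$state0, rhasl:::.rh_parms(cal, cuff = FALSE))[[1]]
  expect_lt(max(abs(d0)), 1e-9)
  dc <- rh_rhs_r(0, cal$state0, rhasl:::.rh_parms(cal, cuff = TRUE))[[1]]
  expect_lt(dc[["P_p"]], 0)          # arterial pressure decays with inflow cut
})

test_that("radius dynamics match a discrete volume balance", {
  # independent oracle: integrate 0.5 s of cuffing densely and compare the
  # arteriolar volume change K_V (r1^2 - r0^2) with the trapezoid integral of
  # Q_a - Q_v computed from the recorded states
  cal <- fix_calib()
  cst <- fix_constants()
  sim <- rh_simulate(fix_subject(), rh_protocol(60, t_baseline = 10),
                     times = seq(0, 30, by = 0.01))
  r <- sim$r_a_um * 1e-4
  dV <- cst$K_V * (r[length(r)]^2 - r[1]^2)
  q <- vapply(seq_len(nrow(sim)), function(i) {
    fl <- segment_flows(sim$P_p[i], sim$r_a_um[i], sim$P_v[i], sim$A[i], cst)
    (fl$Q_a - fl$Q_v) / 60
  }, numeric(1))
  intQ <- sum(diff(sim$time_s) * (utils::head(q, -1) + utils::tail(q, -1)) / 2)
  expect_equal(dV, intQ, tolerance = 1e-4)
})

test_that("total blood volume is conserved while both switches are open", {
  cst <- fix_constants()
  cal <- fix_calib()
  sim <- rh_simulate(fix_subject(), rh_protocol(120, t_baseline = 10),
                     times = seq(0, 120, by = 1), rtol = 1e-10, atol = 1e-10)
  cuff <- sim[sim$phase == "cuff", ]
  vol <- cal$C_p * cuff$P_p + cst$K_V * (cuff$r_a_um * 1e-4)^2 +
    cst$C_v * cuff$P_v
  expect_lt(diff(range(vol)) / vol[1], 1e-7)
})

test_that("baseline steady state reproduces the stated pressure ledger", {
  cst <- fix_constants()
  cal <- rh_calibrate(rh_subject(f_r = fix_f_group()), cst)
  expect_equal(cst$P_ai - cal$P_p_base, 1.8775, tolerance = 1e-4)
  expect_equal(cal$P_p_base - cal$P_v_base, 70, tolerance = 1e-9)
  expect_equal(cal$P_v_base - cst$P_vo, 1, tolerance = 1e-9)
  expect_equal(cal$Q_base * 60, 144, tolerance = 1e-9)
})
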