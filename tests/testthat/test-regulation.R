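test_that("activation sigmoid has the stated midpoint, value at 0.45, and symmetry", {
  expect_equal(activation(0), 0.5)
  expect_equal(activation(0.45), 1 / (1 + exp(-0.9)), tolerance = 1e-12)
  expect_equal(activation(0.45), 0.7109, tolerance = 1e-3)
  z <- seq(-4, 4, by = 0.25)
  expect_equal(activation(z) + activation(-z), rep(1, length(z)))
  expect_true(all(diff(activation(z)) > 0))
  expect_error(activation(Inf), "finite")
})

test_that("total influence applies the dilation/constriction sign convention", {
  gains <- list(g_myo = 1, g_sh = 1, g_atp = 15.66, g_ado = 4.18)
  x0 <- list(x_myo = 0, x_sh = 0, x_atp = 0, x_ado = 0)
  expect_equal(total_influence(x0, gains, 0.45), 0.45)
  # accumulating ATP or adenosine de-activates the muscle
  xA <- x0; xA$x_atp <- 0.3
  expect_lt(activation(total_influence(xA, gains, 0.45)),
            activation(total_influence(x0, gains, 0.45)))
  # elevated wall tension (myogenic) activates it (constriction)
  xM <- x0; xM$x_myo <- 0.3
  expect_gt(activation(total_influence(xM, gains, 0.45)),
            activation(total_influence(x0, gains, 0.45)))
})

test_that("stimuli vanish at baseline, and shear is -1 under arrested flow", {
  cal <- fix_calib()
  cst <- fix_constants()
  s <- cal$state0
  T0 <- cal$T_0
  y <- regulation_stimuli(T0, cal$Q_base * 60, s[["r_a"]] * 1e4,
                          cal$C_atp0, cal$C_ado0, cal, cst)
  expect_equal(unlist(y), c(y_myo = 0, y_sh = 0, y_atp = 0, y_ado = 0),
               tolerance = 1e-10)
  y0 <- regulation_stimuli(T0, 0, s[["r_a"]] * 1e4, cal$C_atp0, cal$C_ado0,
                           cal, cst)
  expect_equal(y0$y_sh, -1)
  # s_ATP = 2.5 per uM
  y1 <- regulation_stimuli(T0, cal$Q_base * 60, s[["r_a"]] * 1e4,
                           cal$C_atp0 + 0.4, cal$C_ado0, cal, cst)
  expect_equal(y1$y_atp, 1)
})

test_that("regulatory states relax first-order toward their stimuli", {
  tau <- list(tau_myo = 6, tau_sh = 60, tau_atp = 15.86, tau_ado = 43.2)
  x <- list(x_myo = 0.2, x_sh = -0.5, x_atp = 1, x_ado = 0)
  y <- list(y_myo = 0.2, y_sh = -0.5, y_atp = 1, y_ado = 0)
  expect_equal(unname(regulation_rhs(x, y, tau)), rep(0, 4))   # fixed point
  # step response against the closed-form linear-ODE solution at t = tau
  step_ode <- function(t, x, p)
    list(regulation_rhs(as.list(stats::setNames(x, names(x))),
                        list(y_myo = 1, y_sh = 1, y_atp = 1, y_ado = 1), tau))
  x0 <- c(x_myo = 0, x_sh = 0, x_atp = 0, x_ado = 0)
  out <- deSolve::ode(x0, times = c(0, 6, 15.86, 43.2, 60), step_ode,
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  expect_equal(out[out[, 1] == 6, "x_myo"][[1]], 1 - exp(-1), tolerance = 1e-6)
  expect_equal(out[out[, 1] == 15.86, "x_atp"][[1]], 1 - exp(-1), tolerance = 1e-6)
  expect_equal(out[out[, 1] == 60, "x_sh"][[1]], 1 - exp(-1), tolerance = 1e-6)
  expect_equal(out[out[, 1] == 43.2, "x_ado"][[1]], 1 - exp(-1), tolerance = 1e-6)
  # linearity: an added stimulus offset shifts each rate by offset / tau
  y_off <- list(y_myo = 1.2, y_sh = 0.5, y_atp = 2, y_ado = 1)
  expect_equal(unname(regulation_rhs(x, y_off, tau)) -
                 unname(regulation_rhs(x, y, tau)),
               unname((unlist(y_off) - unlist(y)) / unlist(tau)),
               tolerance = 1e-12)
  expect_error(regulation_rhs(x, y, list(tau_myo = 0, tau_sh = 1, tau_atp = 1,
                                         tau_ado = 1)), "positive")
})

test_that("with all gains zero the circuit is a passive RC network", {
  cst0 <- rh_constants(g_myo = 0, g_sh = 0)
  sub0 <- rh_subject(g_atp = 1e-12, g_ado = 1e-12)
  sim <- rh_simulate(sub0, rh_protocol(120, t_baseline = 60),
                     cst0, times = seq(-60, 420, by = 0.5))
  cal <- attr(sim, "calibration")
  # activation pinned at sigmoid(x_init)
  expect_lt(diff(range(sim$A)), 1e-9)
  expect_equal(sim$A[1], activation(cal$x_init), tolerance = 1e-9)
  # monophasic recovery: no hyperemic overshoot above baseline
  post <- sim[sim$phase == "recovery", ]
  expect_lt(max(post$perfusion), sub0$f_r * 1.01)
})

test_that("each regulatory state stays within the extrema of its stimulus", {
  sim <- fix_sim_5min()
  cal <- fix_calib()
  cst <- fix_constants()
  Tw <- wall_tension(sim$r_a_um, sim$A, cst)
  Qv <- sim$perfusion / 100 * cst$V_m          # mL/min (circuit flow)
  y <- regulation_stimuli(Tw, Qv, sim$r_a_um, sim$C_atp, sim$C_ado, cal, cst)
  eps <- 1e-6
  expect_true(all(sim$x_myo >= min(y$y_myo) - eps & sim$x_myo <= max(y$y_myo) + eps))
  expect_true(all(sim$x_sh >= min(y$y_sh) - eps & sim$x_sh <= max(y$y_sh) + eps))
  expect_true(all(sim$x_atp >= min(y$y_atp) - eps & sim$x_atp <= max(y$y_atp) + eps))
  expect_true(all(sim$x_ado >= min(y$y_ado) - eps & sim$x_ado <= max(y$y_ado) + eps))
})
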