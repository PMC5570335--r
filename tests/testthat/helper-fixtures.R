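# Shared fixtures.  Everything is generated in code; expensive simulations
# are cached per test run.

.fix <- new.env(parent = emptyenv())

fix_constants <- function() {
  if (is.null(.fix$cst)) .fix$cst <- rh_constants()
  .fix$cst
}

fix_subject <- function() rh_subject()      # healthy-group means

fix_calib <- function() {
  if (is.null(.fix$cal)) .fix$cal <- rh_calibrate(fix_subject(), fix_constants())
  .fix$cal
}

# group-average resting perfusion: Q_r / V_m in mL/100mL/min
fix_f_group <- function() {
  cst <- fix_constants()
  cst$Q_r * 60 / cst$V_m * 100
}

# dense 5-min-cuff simulation at standard parameters (used by several files)
fix_sim_5min <- function() {
  if (is.null(.fix$sim5))
    .fix$sim5 <- rh_simulate(fix_subject(), rh_protocol(300, t_baseline = 60),
                             times = seq(-60, 600, by = 0.5))
  .fix$sim5
}
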