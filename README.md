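# rhasl — physiological modelling of ASL reactive hyperemia in calf muscle

Post-occlusive reactive hyperemia — the transient overshoot of perfusion
after a thigh cuff is released — is measurable in calf muscle with arterial
spin labeling (ASL) MRI, and its shape is altered both by arterial stenoses
and by microvascular dysfunction in peripheral arterial disease.  The raw
summary indices (peak, time-to-peak) cannot tell those two lesions apart.
`rhasl` implements a lumped-parameter physiological model that can: a
three-segment flow circuit (popliteal artery, arterioles, veins) coupled to
two-compartment oxygen transport, RBC ATP release, interstitial adenosine
kinetics, and four first-order vasoregulation mechanisms driving arteriolar
smooth-muscle activation

$$A = \frac{1}{1+e^{-2z}}, \qquad
z = x_{init} + g_{myo}x_{myo} - g_{sh}x_{sh} - g_{ATP}x_{ATP} - g_{ado}x_{ado},$$

with the arteriolar wall obeying the Laplace balance
$P_a r_a - P_{im}(r_a+h_a) = T_e(r_a) + A\,T_m(r_a)$ and ASL perfusion
$f_{ASL} = Q_v/V_m = 2(P_a - P_v)/((R_a + R_v)V_m)$.

The package provides:

* `rh_constants()`, `rh_subject()`, `rh_protocol()` — model constants
  (YAML-overridable), the seven subject parameters
  `[f_r, g_ATP, g_ado, tau_ATP, tau_ado, tau_p, R_p-scale]`, cuff protocols;
* `rh_calibrate()` — baseline steady-state calibration (exact fixed point);
* `rh_simulate()` / `rh_characterize()` — stiff-ODE simulation of
  baseline–cuff–recovery (compiled right-hand side), peak and TTP;
* `rh_generate_trace()` — synthetic ASL traces (3.35 s sampling, cuff gap,
  Gaussian noise, optional drift);
* `rh_fit_healthy()` / `rh_fit_patient()` — bounded multi-start nonlinear
  least squares (two-step healthy schedule; five-parameter patient
  schedule), with broom-style `tidy()`/`glance()` and `autoplot()`;
* `rh_run_scenarios()` — duration / stenosis / dysfunction experiment
  tables; `rh_read_trace()` / `rh_write_trace()` and ASL signal conversion
  `rh_signal_to_perfusion()`;
* a thin CLI at `inst/cli/rhasl` (`simulate`, `synth`, `fit`, `scenarios`,
  `asl2perf`).

## Worked example

```r
library(rhasl)

# baseline calibration at the group-average resting perfusion
rh_calibrate(rh_subject(f_r = 4.8))
#> <rh_calibration>
#>   f_r = 4.8 mL/100mL/min  (Q = 144 mL/min)
#>   P_p/P_a/P_v = 85/50.25/15 mmHg,  r_a = 75.13 um
#>   A_base = 0.454,  x_init = -0.09216
#>   D = 7 /min,  V_max_m = 102.4 uM/min,  C_atp0 = 0.14 uM

# a 2-minute cuff at the healthy-mean parameters
sim <- rh_simulate(rh_subject(), rh_protocol(t_cuff = 120))
rh_characterize(sim)
#> # A tibble: 1 × 3
#>    peak   ttp t_peak
#>   <dbl> <dbl>  <dbl>
#> 1  33.3  14.6   135.

# recover a simulated patient (stenosis x2, ATP gain 6) from a noisy trace
tr  <- rh_generate_trace(rh_subject(f_r = 4.5, g_atp = 6, tau_atp = 20,
                                    tau_p = 4, r_p_scale = 2),
                         rh_protocol(120), sigma = 0.5, seed = 42)
fit <- rh_fit_patient(tr)
fit
#> <rh_fit> mode=patient, chi2_red=0.7306, N=126, n_free=5
#> <rh_subject> f_r=4.519531 g_atp=6.040923 g_ado=4.18 tau_atp=19.17448s
#>   tau_ado=43.2s tau_p=4.028763s R_p x2.345206
```

The calibration prints the resting operating point: 144 mL/min of leg flow
distributed over the 85/50/15 mmHg pressure ledger at a 75 µm arteriolar
radius, with the smooth muscle ~45% activated at rest.  The 2-min cuff
response peaks at 33.3 mL/100mL/min, 14.6 s after release.  The patient
fit reads back the injected microvascular gain (6.04 vs 6) and a popliteal
resistance about twice normal from a single noisy 2-min recording, with a
reduced chi-square of 0.73 — consistent with the injected noise.
`rh_run_scenarios()` tabulates the protocol-design result behind the
package: the peak deficit caused by microvascular dysfunction is several
times larger (relatively) after 2-min than after 5-min cuffing, whereas a
stenosis depresses and delays the response at every duration.

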