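/* Right-hand side of the 11-state reactive-hyperemia model, in the deSolve
 * compiled-model convention.  All quantities are in the package's canonical
 * units: mmHg, seconds, mL, cm, uM.
 *
 * State vector:
 *   0 P_p   popliteal node pressure
 *   1 r_a   arteriolar radius (cm)
 *   2 P_v   venous node pressure
 *   3 x_myo  4 x_sh  5 x_atp  6 x_ado   regulatory states
 *   7 PO2c  8 PO2t   oxygen tensions
 *   9 C_atp 10 C_ado metabolite concentrations
 *
 * The parameter vector layout must match .rh_parms() on the R side.
 */
#include <R.h>
#include <math.h>

enum {
  iCUFF, iPAI, iRP, iCP, iRV, iCV, iKR, iKV, iPIM, iPVO,
  iRA0, iHA0, iS1, iS2, iKE, iTM0, iRAM, iRAT, iNM,
  iXINIT, iGMYO, iGSH, iGATP, iGADO,
  iTMYO, iTSH, iTATP, iTADO,
  iSMY, iSSH, iSATP, iSADO, iT0, iCATP0, iCADO0,
  iALPHA, iVC, iVT, iCHB, iP50N, iNHILL, iCMB, iP50MB, iWB, iWT,
  iO2ART, iD, iVMAXM, iKMO2, iVM,
  iCONVATP, iFRACHT, iR0S, iR1, iKDEG, iCATPIN,
  iVMAXADO, iKMADO, iFLO, iFHI, iPO2CR, iSMOOTHW,
  NPARMS
};

static double p[NPARMS];

void rh_init(void (*odeparms)(int *, double *)) {
  int n = NPARMS;
  odeparms(&n, p);
}

void rh_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip) {
  const double cuff = p[iCUFF];
  const double Pp = y[0], ra = y[1], Pv = y[2];
  const double x_myo = y[3], x_sh = y[4], x_atp = y[5], x_ado = y[6];
  const double PO2c = y[7] > 0 ? y[7] : 0;
  const double PO2t = y[8] > 0 ? y[8] : 0;
  const double Catp = y[9], Cado = y[10];

  /* activation and wall mechanics */
  const double z = p[iXINIT] + p[iGMYO] * x_myo - p[iGSH] * x_sh
                   - p[iGATP] * x_atp - p[iGADO] * x_ado;
  const double A = 1.0 / (1.0 + exp(-2.0 * z));
  const double ra0 = p[iRA0], ha0 = p[iHA0];
  const double ha = sqrt(ra * ra + 2.0 * ra0 * ha0 + ha0 * ha0) - ra;
  const double Te = (p[iS1] * exp(p[iKE] * (ra - ra0) / ra0) - p[iS2]) * ha;
  const double Tm = p[iTM0] *
      exp(-pow(fabs((ra - p[iRAM]) / (p[iRAT] - p[iRAM])), p[iNM]));
  const double Twall = Te + A * Tm;
  const double Pa = (Twall + p[iPIM] * (ra + ha)) / ra;

  /* flows (half-split resistances) */
  const double ra2 = ra * ra;
  const double Ra = p[iKR] / (ra2 * ra2);
  const double Qa = 2.0 * (Pp - Pa) / Ra;
  const double Qv = 2.0 * (Pa - Pv) / (Ra + p[iRV]);
  const double Qai = cuff > 0.5 ? 0.0 : (p[iPAI] - Pp) / p[iRP];
  const double Qvo = cuff > 0.5 ? 0.0 : (Pv - p[iPVO]) / p[iRV];

  ydot[0] = (Qai - Qa) / p[iCP];
  ydot[1] = (Qa - Qv) / (2.0 * p[iKV] * ra);
  ydot[2] = (Qv - Qvo) / p[iCV];

  /* regulatory stimuli (zero at baseline) */
  const double y_myo = p[iSMY] * (Twall - p[iT0]);
  const double y_sh = p[iSSH] * Qv / (ra2 * ra) - 1.0;
  const double y_atp = p[iSATP] * (Catp - p[iCATP0]);
  const double y_ado = p[iSADO] * (Cado - p[iCADO0]);
  ydot[3] = (y_myo - x_myo) / p[iTMYO];
  ydot[4] = (y_sh - x_sh) / p[iTSH];
  ydot[5] = (y_atp - x_atp) / p[iTATP];
  ydot[6] = (y_ado - x_ado) / p[iTADO];

  /* oxygen transport.  Occlusion is complete for transport: the convective
   * terms see zero perfusion while the cuff is on, even though the circuit
   * compliances keep redistributing a small internal flow. */
  const double f = cuff > 0.5 ? 0.0 : Qv / p[iVM];   /* perfusion, 1/s */
  const double n = p[iNHILL], p50n = p[iP50N];
  const double pcn = pow(PO2c, n);
  const double sat = PO2c > 0 ? pcn / (pcn + p50n) : 0.0;
  const double O2c = 4.0 * p[iCHB] * sat + p[iWB] * p[iALPHA] * PO2c;
  const double O2t = p[iCMB] * PO2t / (PO2t + p[iP50MB])
                     + p[iWT] * p[iALPHA] * PO2t;
  const double gc = (PO2c > 0
      ? 4.0 * p[iCHB] * n * p50n * pow(PO2c, n - 1.0)
        / ((pcn + p50n) * (pcn + p50n))
      : 0.0) + p[iWB] * p[iALPHA];
  const double gt = p[iCMB] * p[iP50MB]
      / ((PO2t + p[iP50MB]) * (PO2t + p[iP50MB])) + p[iWT] * p[iALPHA];
  const double Jd = p[iALPHA] * p[iD] * (y[7] - y[8]);   /* uM/s */
  const double VO2 = p[iVMAXM] * O2t / (O2t + p[iKMO2]); /* uM/s */
  ydot[7] = (f * (p[iO2ART] - O2c) - Jd) / (p[iVC] * gc);
  ydot[8] = (Jd - VO2) / (p[iVT] * gt);

  /* intravascular ATP */
  const double Ratp = p[iR0S] * (1.0 - p[iR1] * sat);
  ydot[9] = f * p[iCONVATP] * (p[iCATPIN] - Catp)
            + p[iFRACHT] * Ratp - p[iKDEG] * Catp;

  /* interstitial adenosine */
  double Fado;
  if (p[iSMOOTHW] > 0) {
    Fado = p[iFHI] + (p[iFLO] - p[iFHI])
           / (1.0 + exp(-(PO2t - p[iPO2CR]) / p[iSMOOTHW]));
  } else {
    Fado = PO2t >= p[iPO2CR] ? p[iFLO] : p[iFHI];
  }
  ydot[10] = Fado - p[iVMAXADO] * Cado / (Cado + p[iKMADO]);

  if (ip[0] >= 3) {            /* optional observables */
    yout[0] = A;
    yout[1] = Qv;
    yout[2] = z;
  }
}
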