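#ifndef EADCLUMP_CELL_H
#define EADCLUMP_CELL_H

// Modified O'Hara-Rudy (2011) endocardial human ventricular myocyte:
//  - fast Na+ current replaced by the Ten Tusscher-Panfilov (2006)
//    formulation (original ORd INa is too slow for realistic tissue CV);
//  - current roster restricted to the 14 currents of the study
//    (INaL and its gates are not part of the roster);
//  - every current carries a dimensionless conductance multiplier.
// Units follow the ORd source: mV, ms, mM, uA/uF.

#define N_STATE 35

// state vector layout
enum {
  IX_V = 0,
  IX_NAI, IX_NASS, IX_KI, IX_KSS, IX_CAI, IX_CASS, IX_CANSR, IX_CAJSR,
  IX_M, IX_H, IX_J,                              // TP06 INa gates
  IX_A, IX_IF, IX_IS, IX_AP, IX_IFP, IX_ISP,     // Ito
  IX_D, IX_FF, IX_FS, IX_FCAF, IX_FCAS, IX_JCA,  // ICaL
  IX_NCA, IX_FFP, IX_FCAFP,
  IX_XRF, IX_XRS,                                // IKr
  IX_XS1, IX_XS2,                                // IKs
  IX_XK1,                                        // IK1
  IX_JRELNP, IX_JRELP, IX_CAMKT
};

// voltage-dependent quantity table layout (LUT columns)
#define NQ 44
#define N_GATE 22            // inf/tau gates with Rush-Larsen updates
#define NQTOT (NQ + N_GATE)  // extra columns: exp(-dt/tau) per gate
enum {
  Q_MINF = 0, Q_RTM, Q_HINF, Q_RTH, Q_RTJ,
  Q_ASS, Q_RTA, Q_ISS, Q_RTIF, Q_RTIS, Q_AIF, Q_ASSP, Q_RTIFP, Q_RTISP,
  Q_DSS, Q_RTD, Q_FSS, Q_RTFF, Q_RTFS, Q_RTFCAF, Q_RTFCAS, Q_AFCAF,
  Q_RTFFP, Q_RTFCAFP,
  Q_XRSS, Q_RTXRF, Q_RTXRS, Q_AXRF, Q_RKR,
  Q_XS1SS, Q_RTXS1, Q_RTXS2,
  Q_XK1SS, Q_RTXK1, Q_RK1,
  Q_A1, Q_A2, Q_EXPV, Q_EXP2V,
  Q_HCA, Q_HNA, Q_KNAI, Q_KNAO, Q_XKB
};

#define N_CURRENT 14
// order matches the current roster used throughout the R level
enum {
  C_NA = 0, C_TO, C_CAL, C_CANA, C_CAK, C_KR, C_KS, C_K1,
  C_NACA, C_NAK, C_NAB, C_CAB, C_PCA, C_KB
};

struct Mult {
  double m[N_CURRENT]; // conductance/permeability multipliers, order as enum
};

// LUT over membrane potential
#define LUT_VMIN (-160.0)
#define LUT_VMAX 620.0
#define LUT_DV 0.02
#define LUT_N 39001

// fill q[NQ] with the exact voltage-dependent quantities at v
void compute_vdep(double v, double *q);

// fill q[NQTOT] exactly (rates + Rush-Larsen exp factors for step dt)
void compute_vdep_full(double v, double dt, double *q);

// (re)build the global LUT for time step dt (no-op if already built)
void lut_ensure(double dt);

// interpolate the global LUT at v into q[NQTOT] (v clamped to table range)
void lut_lookup(double v, double *q);

// compute all state derivatives (dS, length N_STATE, dS[IX_V] = -Iion only,
// stimulus/gap/diffusion added by the caller) and the 14 current components;
// istim enters the K+ bookkeeping exactly as in the ORd source.
// stiff (optional, length 2) receives the frozen-coefficient linear form
// dcass/dt = P - Q*cass used by the exponential subspace-Ca update.
// returns Iion (uA/uF).
double cell_rhs(const double *S, const double *q, const Mult &mult,
                double istim, double *dS, double *currents,
                double *stiff = 0);

// advance all states except V by one forward-Euler (or Rush-Larsen gate)
// step of size dt; returns Iion evaluated at the pre-step state.
double cell_advance(double *S, const double *q, const Mult &mult,
                    double istim, double dt, int rush_larsen);

// published resting initial condition
void cell_initial_state(double *S);

#endif
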