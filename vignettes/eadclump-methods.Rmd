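---
title: "Methods: EAD clumps, fibroblast coupling, and PVC triggering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EAD clumps, fibroblast coupling, and PVC triggering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early afterdepolarizations (EADs) are depolarizing oscillations of the
membrane potential during the repolarization phase of a cardiac action
potential.  A single EAD-capable myocyte embedded in healthy tissue is
electrotonically loaded by its repolarized neighbours (source-sink
mismatch) and usually cannot express its EADs; a sufficiently large,
contiguous *clump* of such cells can, and then fires premature
ventricular complexes (PVCs) -- ectopic waves that propagate into the
surrounding tissue between paced beats.  This package simulates that
multiscale problem end to end: single cells, myocyte-fibroblast
composites, 1D cables and 2D monodomain sheets, plus the analysis used to
decide whether a given configuration triggered PVCs.

## Cell model

The myocyte is the O'Hara-Rudy (2011) endocardial human ventricular cell
with two modifications:

* the fast Na$^+$ current uses the Ten Tusscher-Panfilov (2006)
  formulation ($G_{Na}$ = 14.838 nS/pF), because the original ORd
  $I_{Na}$ yields unrealistically slow conduction in tissue;
* the membrane current is the 14-entry roster
  $I_{ion} = I_{Na}+I_{to}+I_{CaL}+I_{CaNa}+I_{CaK}+I_{Kr}+I_{Ks}+I_{K1}
  +I_{NaCa}+I_{NaK}+I_{Nab}+I_{Cab}+I_{pCa}+I_{Kb}$.  The ORd late
  sodium current is not part of this roster and is omitted (with its
  three gating variables); everything else follows the published ORd
  endocardial formulation, including the CaMK-phosphorylated channel
  fractions, with 35 state variables.

Every current carries a positive dimensionless multiplier (1 = control).
EAD-capable cells are produced by reducing the repolarization reserve:

* **type-I** (`make_ead_parameters("type-I")`): $G_{CaL}\times 4$,
  $G_{Kr}\times 0.21$.  APs show EAD oscillations of *growing* amplitude
  that eventually repolarize completely.  At PCL 1000 ms the single cell
  alternates EAD-bearing and normal beats; the EAD-bearing AP spans more
  than one cycle.
* **type-II** (`make_ead_parameters("type-II")`): $G_{CaL}\times 4$,
  $G_{Kr}\times g$ with $g < 0.21$.  Only the figure inset of the source
  study records the exact value, so $g$ was fixed by scanning downward
  over $\{0.18, 0.15, 0.12, 0.10, 0.07, 0.05\}$ on a single paced beat
  and keeping the largest value with *strictly* decaying EAD amplitudes
  and a final potential well above rest.  At 0.18 the oscillations still
  grow (22 to 70 mV); at 0.15 they are nearly flat (18.4 to 14.2 mV over
  twelve oscillations, a borderline case); at **0.12** they decay
  unambiguously (15.5 to 2.7 mV, relaxing to about -11 mV), as they do
  for every smaller value.  The package constant is therefore
  `GKR_TYPE_II = 0.12`; the EAD amplitudes are visibly smaller than the
  type-I case (15 mV versus 27-56 mV), matching the reported contrast
  between the two phenotypes.

The `I_CaL` multiplier scales the L-type *channel permeability* $P_{Ca}$.
In the source model the channel's Na$^+$ and K$^+$ permeabilities are
defined proportional to $P_{Ca}$ ($P_{CaNa}=0.00125 P_{Ca}$,
$P_{CaK}=3.574\times10^{-4} P_{Ca}$), so scaling "G$_{CaL}$" scales all
three fluxes; the separate `I_CaNa`/`I_CaK` multipliers act on top of
that.  This whole-channel reading reproduces the reported EAD phenotypes
considerably more robustly than scaling the Ca$^{2+}$ component alone.

The fibroblast is the MacCannell-type passive cell:
$C_f\,dV_f/dt = I_{gap} - G_f(V_f)(V_f - E_f)$ with $C_f$ = 6.3 pF and
$G_f$ = 4 nS, or the piecewise variant $G_f$ = 2 nS for $V_f <$ -20 mV
and 4 nS above.  The myocyte-fibroblast gap current is
$I_{gap} = G_{gap}(V_m - V_f)$ in pA (default $G_{gap}$ = 8 nS); it is
subtracted from the myocyte after conversion through $C_m$ = 185 pF
(pA/pF = mV/ms) and added to the fibroblast, so the charge transfer is
exactly antisymmetric.  The governing equation is
$\partial V_m/\partial t = -(I_{ion} + I_{gap}/C_m)$: with the stimulus
current included in $I_{ion}$'s sign convention, an amplitude of
-150 uA/uF is depolarizing.

## Numerics

* **Explicit time stepping, $\delta t$ = 0.02 ms**, forward Euler for
  $V_m$, $V_f$ and the concentration variables.
* **Rush-Larsen gates by default.**  Plain forward Euler for the gating
  variables -- nominally the stated method -- is impossible at
  $\delta t$ = 0.02 ms: the TP06 $m$-gate time constant is
  $\sim10^{-3}$ ms at resting potentials, so the explicit update diverges
  within a few steps.  The 22 inf/tau gates therefore use the exact
  exponential (Rush-Larsen) update, the standard remedy in this field
  (the TP06 authors used it themselves); `gate_method = "euler"` restores
  plain forward Euler for reference use at much smaller $\delta t$.
* **Exponential subspace-Ca update.**  With $P_{Ca}\times4$ the negative
  feedback between the subspace calcium `cass` and $I_{CaL}$ (which is
  linear in `cass`) becomes stiffer than $\delta t$; forward Euler
  overshoots, `cass` goes negative and the model NaNs.  Freezing all
  other quantities, $d\,\mathrm{cass}/dt = P - Q\,\mathrm{cass}$ with
  $Q > 0$ is integrated exactly over each step.  The SR release fluxes
  (whose relaxation time can fall to 0.001 ms during strong release) use
  the same exponential form.  For control parameters these updates agree
  with forward Euler to $O(\delta t^2)$.
* **Voltage lookup table.**  All purely voltage-dependent rate functions
  and driving-force factors (66 quantities) are tabulated on a 0.02 mV
  grid over [-160, 620] mV in single precision and linearly
  interpolated; accuracy is ~1e-6 relative, and the measured conduction
  velocity is unchanged to 5 significant digits versus exact evaluation.
  The upper bound accommodates the transient overshoot (to roughly
  +350 mV) inside the stimulated region during the -150 uA/uF x 3 ms
  tissue pulse, which injects far more charge than the ionic currents
  can oppose; the single-cell default stimulus is the source model's
  -80 uA/uF x 0.5 ms pulse instead.
* **Diffusion.**  $D$ = 0.0012 **cm^2/ms** ($\delta x$ = 0.02 cm, one
  grid point per cell).  The source text prints both cm^2/ms and cm^2/s
  in different places; cm^2/ms is the value consistent with the reported
  conduction velocity of 65 cm/s (the package measures 64.2 cm/s, -1.2%).
  Heterogeneous $D$ uses the conservative face-flux divergence form
  $\nabla\!\cdot\!(D\nabla V)$ with arithmetic face averages, which
  reduces exactly to the five-point stencil wherever $D$ is uniform;
  domain boundaries are no-flux, and obstacle sites are removed nodes
  whose faces carry zero flux (equivalent to local $D = 0$).
* Integration is bitwise deterministic for a given configuration; an
  instability report names the site and time.

## Protocols and sensors

Tissue pacing is the asymmetric protocol: -150 uA/uF for 3 ms over a
3 cm x 0.14 cm rectangle abutting the lower-right boundary (150 x 7
sites), first pulse at 50 ms (the source is silent on this; it is
configurable), then every PCL (1000 or 1400 ms).  Cables are paced at
their left end over 7 sites.  S1-S2 cross-field initiation applies a
planar S1 along the left edge and a half-domain S2; the S2 delivery time
defaults to $t_{S1} + (L_x/2)/\mathrm{CV} + \mathrm{ERP}$ (CV 65 cm/s,
ERP 320 ms), both exposed.  Sensors: four corner points inset 0.5 cm
(spectra), a ring at $R$ + 0.2 cm around the clump (PVC counting), or
every cable site.

## Scenario generator (the stated world)

All inputs are generated, seeded and pure: circular clumps by
site-centre distance $\le R$; diffuse fibrosis as exactly
round(P_f% x region) obstacles sampled uniformly without replacement
(exact-count, not per-site Bernoulli); fibroblast layers uniform or
exact-count random; the four 280-cell cable patterns with half-open
index ranges [60, 220) and [120, 160) so the stated counts (160 EAD
cells, 40 fibroblasts) hold exactly; percentage-to-count rounding is
round-half-up.  The generator does **not** emulate correlated fibrosis
textures, histology-derived maps, anisotropy, or fibroblast:myocyte
ratios above 1.

## Analysis conventions

AP start: upward -40 mV crossing; AP end: 90% repolarization or the next
upstroke; the *final potential* is taken at the end of the AP's full
span (just before the next upstroke), which is what "relaxes to an
elevated potential" refers to.  EADs: local minimum-maximum pairs after
the AP peak with amplitude >= 1 mV.  Classification: normal (no EADs,
repolarized), type-I (non-decreasing amplitudes, repolarizes), type-II
(decreasing amplitudes, final potential >= 10 mV above rest).  All
thresholds are arguments with these defaults.

PVC counting: the study never defines how $N$ is counted.  Here a sensor
upstroke is attributed to pacing when it falls within a conduction-delay
window (domain diagonal / cv_min, default cv_min 40 cm/s, 25 cm/s for
clumps with reduced internal coupling) after a pacing pulse; remaining
upstrokes, merged across sensors within 50 ms, are PVC episodes.
Absolute $N$ therefore differs from the study's by construction;
zero/nonzero outcomes and orderings are the comparable surface.

Spectra: per-trace mean removal, one-sided periodogram (Parseval-exact
normalisation), averaged over the four corner sensors, last 10 s window,
optional Hann taper (off by default), peak frequencies refined by
parabolic interpolation of log power.  Peak indexing classifies a peak
set as periodic if all peaks are integer multiples (order <= 4) of one
base, else quasiperiodic if a combination $n_1\omega_1 + n_2\omega_2$
with $|n| \le 4$ fits all peaks within 2% of the base.  Two design
points deserve note: the harmonic-order bound applies to the one-base
route as well, and only *integer* base ratios are excluded from the
two-base route.  The study's quasiperiodic bases (2.73, 3.64 Hz) have
ratio exactly 3/4 at printed precision, so with the difference tone
$\omega_2-\omega_1 = 0.91$ Hz present the set is formally harmonic on
0.91 Hz with indices {1, 3, 4, 7}; bounding the harmonic order at 4
rejects that degenerate reading and yields the intended quasiperiodic
classification with $|n| \le 1$.  The price is that a genuinely periodic
spectrum with more than four strong harmonics can be mis-indexed; the
spectra this package produces (pacing and spiral regimes) stay within
that bound.

## Reduced-scale proxies

The full-size experiments (448 x 448 sites, 15 s; 960 x 960 for spirals)
take hours on one CPU, so every experiment has a documented reduced
variant used by the test suite:

* single-cell and cable studies run at full fidelity (they are cheap);
* the 2D threshold studies (clump radius, clump coupling, fibrosis) use
  a 360 x 8 site strip (7.2 x 0.16 cm), $\delta t$ = 0.04 ms, 5 s of
  end pacing at PCL 1000 ms, with the clump disc intersecting the strip
  as a band of length $2R$.  Calibration on cables shows the EAD-segment
  PVC threshold for type-I cells at PCL 1000 ms lies between 180 and
  240 cells, so the reduced radii are 1.8 cm (silent) and 2.6 cm
  (triggers).  In this quasi-1D geometry the high-fibrosis extinction
  arises partly from percolation blocking of the band, which in the full
  2D domain is only one of the contributing mechanisms -- a green
  reduced-scale test therefore establishes the *orderings* (threshold in
  $R$, triggering enabled by reduced $D/D_0$, non-monotonic $N(P_f)$
  with high-$P_f$ extinction), not the study's absolute $N$ values,
  threshold radii, or the $P_f \simeq 40\%$ maximum location;
* the spiral studies are emitted as runnable full-scale configurations
  (S1-S2 schedule plus clump geometry); their spectral targets
  (4.38 Hz free, 3.64 Hz anchored at $R$ = 2 cm, quasiperiodic bases
  $\simeq$ (2.73, 3.64) Hz at $R$ = 3 cm) are quantitative only at the
  19.2 x 19.2 cm domain and are not asserted by the desk-scale suite.

## Known limitations

Isotropic 2D monodomain only (no bidomain, anisotropy or 3D); passive
fibroblasts only, at most one per myocyte; spiral-tip trajectories are
not tracked; absolute PVC counts depend on the documented attribution
rule; the type-II $G_{Kr}$ value and several protocol details
(single-cell stimulus, first-pulse time, S2 timing) are package choices
where the source is silent, each recorded above with its rationale.
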