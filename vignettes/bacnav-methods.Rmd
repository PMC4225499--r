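---
title: "Models and methods behind bacnav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bacnav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bacnav)
```

bacnav analyses whole-cell and single-channel voltage-clamp recordings from
prokaryotic voltage-gated sodium (Nav) channels — the nonselective NsvBa
channel of alkaliphilic *Bacillus alcalophilus* and its Na⁺-selective
relatives NaChBac and NavBp — and ships a deterministic simulator so that
every analysis stage can be validated against known ground truth. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the simulator does and does not capture.

## Ion activities

Selectivity inference works on effective activities, not concentrations:
$\alpha_x = \gamma_x [X]$. Activity coefficients come from the extended
Debye-Hückel equation

$$\log_{10}\gamma = \frac{-A z^2 \sqrt{I}}{1 + B a \sqrt{I}},$$

with $A = 0.509\ \mathrm{(mol/L)^{-1/2}}$, $B = 0.328$ per Å per
$\mathrm{(mol/L)^{1/2}}$ and Kielland ion-size parameters $a$ (Na⁺ 4.5,
Li⁺ 6, K⁺ 3, Rb⁺/Cs⁺ 2.5, Mg²⁺ 8, Ca²⁺ 6, Sr²⁺/Ba²⁺ 5 Å). Ionic strength
$I = \tfrac12\sum_i c_i z_i^2$ counts every charged species in the recipe:
fully dissociated salts, the pH-dependent anionic fraction of sulfonate
buffers (HEPES pKₐ 7.5, TAPS 8.4, MES 6.15), EGTA at net charge −2 (its
H₂EGTA²⁻ and CaEGTA²⁻ forms are isovalent near neutral pH), and the titrant
counter-cations those anions require. Ca²⁺ co-dissolved with excess EGTA is
treated as fully chelated: it keeps its chloride in the ionic-strength sum
but contributes no free permeant Ca²⁺. For the standard monovalent bath this
bookkeeping gives $I \approx 0.17$ mol/L and reproduces the classical
coefficient table for Na⁺, Li⁺, K⁺, Rb⁺, Cs⁺, Mg²⁺ and Ca²⁺ within ±0.02.
For Sr²⁺ and Ba²⁺ the Kielland parameter of 5 Å yields γ ≈ 0.24 at the
divalent-bath ionic strength, a little below the value of 0.27 often quoted
for these ions; the discrepancy has no effect on any other quantity and is a
known limitation of the single-parameter extended form at $I > 0.3$ mol/L.

```{r}
ionic_strength(bath_monovalent("Na"))
debye_huckel_gamma("Na", ionic_strength(bath_monovalent("Na")))
```

## Permeation model

The simulator's open-pore current is the Goldman-Hodgkin-Katz (GHK)
constant-field flux summed over permeant ions. With $u = FV/RT$ and
activities in mM,

$$I = p_{\max} \sum_x \frac{P_x}{P_{Na}}\; z_x^2\, u\,
\frac{\alpha_{x,i} - \alpha_{x,e} e^{-z_x u}}{1 - e^{-z_x u}},$$

with the $V \to 0$ singularity replaced by its analytic limit
$z(\alpha_i - \alpha_e)$ below $|z u| < 10^{-6}$. The zero-current potential
of this model is *exactly* the bi-ionic permeability equation used for
inference, which is what makes selectivity round-trips on synthetic data a
meaningful end-to-end check rather than a tautology: the analysis path goes
through simulated sweeps, leak subtraction, peak tables and I–V fits, while
the oracle is a numeric root of the flux model.

Selectivity is inferred from reversal potentials in the pseudo-bi-ionic
configuration (internal NMDG⁺ impermeant, 20 mM internal Na⁺):

* monovalent, against the Na⁺ reference condition in the same cell:
  $P_x/P_{Na} = (\alpha_{Na,e}/\alpha_{x,e}) \exp(\Delta E_{rev} F/RT)$,
  with $\Delta E_{rev} = E_{rev,x} - E_{rev,Na}$, so equal reversal
  potentials mean $P_x/P_{Na} = 1$;
* divalent (Fatt–Ginsborg):
  $P_x/P_{Na} = \alpha_{Na,i}\, e^{u}(e^{u}+1) / (4 \alpha_{x,e})$ with
  $u = E_{rev} F/RT$, evaluated with the internal Na⁺ activity at the
  *internal* ionic strength.

$RT/F$ always uses the recorded bath temperature of the sweep (25.4 mV at
22 °C), not a fixed constant, because the thermal experiments span
20–37 °C. Conditions where no voltage-activated inward current can be
elicited and the measured reversal potential sits at or below −4 mV are
reported at the detection floor $P_x/P_{Na} = 0.1$ with a `floored` flag —
in a real HEK cell, small endogenous chloride and nonselective conductances
dominate the reversal measurement in that regime. The "no inward current"
criterion defaults to a peak inward current smaller than 100 pA, roughly
the residual-leak QC scale.

## Gating and the synthetic recordings

Whole-cell sweeps are generated from an m¹h scheme: one activation gate and
one inactivation gate with Boltzmann steady states
($V_{1/2,a}$, $k_a$; $V_{1/2,h}$, $k_h$) and bell-shaped (sech) voltage
dependence of the time constants anchored at their 0 mV values. The
recordings the model emulates constrain only $V_{1/2}$, $k$ and
$\tau_{inact}$ at 0 mV (42 ms for NsvBa, 78 ms for NaChBac); the τ(V) width
(60/80 mV), the activation time constant (2–3 ms) and the 0.5 ms floor are
simulator choices, documented here and recovered in tests only against
themselves. Gates are integrated by exponential Euler — exact while the
command voltage is constant, so the step-size accuracy guard
(dt ≤ 0.2 min τ) binds only on ramp epochs; ramp helpers choose dt
accordingly. The cell adds a linear leak (0.5 nS, reversal 0 mV), an RC
capacitive transient (τ = Rₐ·Cₘ, 5 MΩ × 20 pF), and Gaussian noise
(sd 2 pA by default, a typical whole-cell figure at 10–20 kHz). Every
stochastic operation takes an explicit seed and restores the global RNG
state; identical seeds give bit-identical sweep sets.

P/4 subtraction records four quarter-amplitude, opposite-polarity copies of
the command delivered from holding. Subtraction baselines both main sweep
and subsweeps to the holding current, scales the averaged subsweep by −4 and
subtracts; each sweep's residual holding current is kept for QC, and sweeps
with residual leak beyond −100 pA are flagged rather than dropped, because
automatic exclusion would silently bias small-current conditions.

Channel presets encode the reported biophysics: selectivity ratios
(nonselective NsvBa with K⁺ ≈ 1.15, floored Cs⁺/Mg²⁺; Na⁺-selective
NaChBac/NavBp), τ_inact at 0 mV, single-channel conductances (30 pS Na⁺,
36 pS K⁺ for NsvBa), and a `p_max` scaled so the NsvBa preset yields
≈119 pA/pF peak inward density in 150 mM Na⁺ with the default 20 pF cell.
The hNav1.1-like control preset carries a permeation Q10 of 1.3 and a pH
shift below 8 mV so the analyses can distinguish thermally sensitive
bacterial channels from insensitive eukaryotic ones. Drug sensitivities
(tamoxifen 30 µM, nifedipine 100 µM, lidocaine 300 µM, Hill n = 1) are
round placeholder potencies, not measured values.

## Temperature and pH modulation

Modulation is a linear additive model applied as a pure function:

$$V_{1/2}'(T, \mathrm{pH}) = V_{1/2} + \frac{dV_{1/2}}{dT}(T - T_{ref})
 + \frac{dV_{1/2}}{d\mathrm{pH}}(\mathrm{pH} - \mathrm{pH}_{ref}),$$

with `p_max` scaled by $Q_{10}^{(T - T_{ref})/10}$ and gating time constants
by $Q_{10,gating}^{-(T - T_{ref})/10}$ (gating Q10 = 3, a typical channel
kinetics figure). Preset slopes are anchored so that warming 20→37 °C shifts
activation by −19 to −24 mV, raising pH 7.4→9.4 shifts it by −28 to −34 mV,
and the combined condition lands at −95/−102/−100 mV for
NsvBa/NaChBac/NavBp. These three constraints are not perfectly mutually
consistent in the source recordings (the NaChBac numbers imply a pH shift of
−47 mV if forced through its intermediate values), so the linear model
reproduces the endpoint convergence exactly and the intermediate
single-factor shifts within their stated ranges.

## Q10 analysis

`q10_analysis` fits $\log_{10} R$ against temperature (the Arrhenius-plot
reading) and reports $Q_{10} = 10^{10\,\mathrm{slope}}$, alongside the
two-point form $(R_2/R_1)^{10/(T_2 - T_1)}$, which matches the regression
exactly for two points. Two recording designs feed it:

* `simulate_ramp_series` — the experiment as actually performed: peak inward
  current during repeated voltage ramps while the bath heats. This number is
  a *compound* temperature coefficient: the negative shift of activation
  with warming inflates it (channels open earlier on the ramp, where driving
  force is larger) while faster inactivation kinetics deflate it. For the
  NaChBac preset (permeation Q10 = 4.0) the ramp readout is ≈4.5; disabling
  the midpoint shift alone gives ≈2.8, disabling gating kinetics alone
  ≈5.2. The breadth of such compound readouts is consistent with the wide
  ranges reported for this family (3.5–4.4 at neutral pH).
* `simulate_step_series` — a fixed 0 mV step family. At 0 mV the GHK flux
  factor is temperature-independent ($u = 0$ limit), activation is saturated
  for every preset at every temperature, and the m·h trajectory only
  time-rescales with the gating Q10, leaving its peak value unchanged — so
  the peak-current Arrhenius slope isolates the permeation Q10. This is the
  design used for quantitative recovery (within 0.4 % across presets) in
  the test suite.

The depolarization energy barrier between the bacterial resting potential
(≈ −180 mV) and the activation threshold (≈ −40 mV) is the electrical work
$W = zF\Delta\Psi$: 3.23 kcal/mol per unit charge for the 140 mV gap,
reported with a negative sign following the convention that the barrier
opposes activation from rest.

## Curve fitting

All nonlinear fits use Levenberg-Marquardt least squares
(`minpack.lm::nlsLM`) with data-driven starts and physical bounds; failures
and degenerate inputs are flagged, never silently returned.

* I–V: $I = g(V - E_{rev}) / (1 + \exp(-(V - V_{1/2})/k))$. When the
  measured I–V brackets zero current, the reported $E_{rev}$ is refined by a
  local straight-line fit (±15 mV window) around the measured crossing: the
  global least-squares parameter is dominated by the large-current limb and
  can miss the crossing by several mV under GHK rectification, while the
  local crossing is accurate to a fraction of a millivolt. The fitted
  parameter is kept only for true extrapolation. Data indistinguishable
  from a straight line ($R^2_{line} > 0.999$, e.g. pure leak) are flagged
  as carrying no gating information.
* Boltzmann: $y = I_{min} + (I_{max} - I_{min})/(1 + \exp(s(V - V_{1/2})/k))$
  with $s = -1$ for activation and $+1$ for inactivation — the standard
  two-asymptote logistic, which is the only reading of a self-referential
  printed form consistent with fitting both directions. Fits whose sigmoid
  does not turn over within the sampled range are flagged.
* Inactivation: $f(t) = B + A e^{-t/\tau}$ from the time of peak current
  onward (the printed exponent is typographically ambiguous; decay is the
  physically meaningful sign). τ exceeding 10× the fitted segment is a
  flagged failure.
* Hill: $y = 100/(1 + (EC_{50}/C)^n)$, ascending with dose so one form
  serves current block and growth inhibition. Doses flagged as assay
  artifacts (tamoxifen absorbs 600 nm light above 30 µM) are excluded by
  default; fits lacking a low or high plateau are marked low-confidence.

Chord-conductance transforms ($G = I/(V - E_{rev})$, normalized) are exact
when the open-pore I–V is ohmic. Under strongly asymmetric bi-ionic
activities the GHK pore rectifies and chord conductance overstates
activation at negative potentials by a few mV of apparent $V_{1/2}$; the
recovery tests therefore measure G–V in symmetric Na⁺ (pipette and bath
recipes swapped, as in the single-channel configuration), where the flux is
exactly linear in V.

## The selectivity panel, end to end

`selectivity_panel` simulates the ion-substitution experiment: each bath
(150 mM monovalent X-Cl or 110 mM divalent X-Cl₂) against the NMDG/Na
pipette, P/4 subtraction, peak tables, I–V fit, liquid-junction correction
(accepted as per-bath configuration, not computed), and conversion to
$P_x/P_{Na}$ against the in-cell Na⁺ reference. If a bath's I–V does not
bracket zero current the step family is extended (up to +140 mV) before
fitting, as one would at the rig. Ground-truth ratios spanning 0.1–10 are
recovered within ~2 % noise-free and ~2–5 % at 2 pA noise, comfortably
inside the 5 %/15 % targets used in the acceptance tests.

One caveat documented rather than modelled: absolute reversal potentials in
real HEK recordings sit several mV below the clean GHK prediction because of
endogenous background conductances (the reason the detection floor exists).
The simulator contains no such background beyond its linear leak, so
analyses anchored to *differences* of reversal potentials (all permeability
ratios) reproduce reported values, while isolated absolute reversal
potentials from cells with small currents do not — e.g. the ≈40 mV measured
for 150 mM Na⁺ at 34 °C corresponds to ≈57–60 mV for a background-free GHK
pore with the same solutions.

## What the simulator does not capture

Two-state gating only (no slow inactivation, no modal gating); no
series-resistance voltage error; no endogenous HEK conductances beyond the
linear leak; junction potentials are inputs, not computed (no Henderson
equation); activity corrections stop at the extended Debye-Hückel form (no
Pitzer/SIT); single-channel records are two-level by construction. Passing
recovery tests therefore demonstrates that the analysis chain is unbiased
for data obeying these models at realistic noise, not that real recordings
are free of the excluded artifacts.

## Problem sizes and determinism

Default sweeps are 10–20 kHz, 0.25–0.5 s families of ≤ 19 steps; the full
test suite simulates a few hundred sweeps. Every simulation takes an
explicit integer seed; reruns of a pipeline configuration
(`run_pipeline`) are bit-identical, and every output table carries the
configuration hash and seed.
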