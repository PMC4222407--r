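---
title: "Modelling PKC-linked excitability changes in a layer 5 pyramidal neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PKC-linked excitability changes in a layer 5 pyramidal neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Type I interferons increase the excitability of neocortical layer 5 pyramidal
neurons, and protein kinase C (PKC) activation is a candidate link between the
cytokine receptor cascade and the membrane. PKC is known to reduce the
M-type potassium current, the HCN1-mediated h-current and the BK
calcium-activated potassium current, and to shift the activation of the
persistent sodium current towards rest. `l5sim` implements the in-silico side
of that argument: a multi-compartment conductance-based layer 5 neuron in
which those four modulations can be applied singly or jointly, plus the
electrophysiology feature extraction (rheobase, F-I gain, input resistance,
after-hyperpolarization, spike voltage threshold) and the paired
nonparametric statistics used to evaluate cohorts of such features. A
synthetic-cohort generator stands in for the unavailable raw patch-clamp
data.

# The model

## Morphology and passive properties

The built-in stylized cell (`make_reference_morphology()`) has a 23 µm soma,
an axon consisting of a tapered hillock (15 µm), an initial segment (45 µm)
and a 140 µm unmyelinated continuation, a 650 µm apical trunk carrying a
two-branch tuft (tip path distance 930 µm), and two 190 µm basal dendrites.
Cables are discretized so no electrical compartment exceeds 20 µm, a
standard accuracy/runtime compromise for this cell class. Arbitrary
morphologies can be supplied as SWC (`load_swc()`).

Passive properties: specific capacitance 1.5 µF/cm² and axial resistivity
68.0 Ω·cm uniformly (the resistivity unit is taken as Ω·cm, the standard
usage, and is exposed as the `ra` argument of `assign_passive()`). Specific
membrane resistance follows a logistic profile of dendritic path distance
from 36.0 kΩ·cm² at the soma to 5.4 kΩ·cm² at the most distal tip, with the
midpoint at half the maximal dendritic path distance and a steepness that
spans 99% of the range, affinely rescaled so the end points are met exactly.
Soma and axon take the somatic value. Dendritic spines are represented by
doubling specific capacitance and active channel densities and halving the
membrane resistance from 20 µm (basal) and 100 µm (apical) outwards; the
boundary is inclusive and the correction is idempotent.

## Channels and their spatial distribution

Twelve conductances are implemented in Hodgkin–Huxley form (transient
sodium in somatodendritic and axonal variants, persistent sodium, delayed
rectifier, M-type potassium, proximal and distal A-type potassium, BK,
high-threshold and T-type calcium, HCN1 and HCN2), with densities following
the model's published table: e.g. axonal Na 3500 pS/µm², somatic Na 420,
A-type 150 at the soma and 300 (apical) with a linear proximal→distal
variant exchange over the first 300 µm, exponentially decaying dendritic
delayed rectifier (start 20, length constant 80 µm), M-current restricted to
the soma (10), axon (50) and the proximal dendrites (5, first 100 µm apical
/ 20 µm basal), uniform BK (0.6) and high-threshold calcium (2), T-type
(0.5) beyond 300 µm, and an exponentially growing h-conductance from
0.95 pS/µm² with length constant 323 µm capped at 40×, split 2/3 HCN1 :
1/3 HCN2. All densities live in a declarative YAML table
(`inst/extdata/density_rules.yaml`) and all kinetics in
`inst/extdata/channels.yaml`; both are user-replaceable.

Where the kinetics of the source models were not reproducible from the
primary text, standard published parameter families were adopted
(trap-function sodium/potassium rates, thermodynamic A-type kinetics,
Boltzmann persistent-sodium activation) and positioned so that the
*calibrated control* matches the study's derived control excitability
(rheobase ≈ 304 pA, F-I gain ≈ 74.4 Hz/nA) — the scientific content of this
model is the *ratios* under modulation, not absolute kinetics. Temperature
is 32 °C with a Q10 of 2.3 for gating rates. Reversal potentials are fixed
(Na +60, K −90, h −45, Ca +140 mV). Calibration of conductances was
restricted to the sodium and delayed-rectifier families within ±30% of the
printed values (shipped factor: K_V × 1.3).

The BK model gates jointly on voltage and sub-membrane calcium: its
activation midpoint slides 50 mV per tenfold rise in [Ca]i from −10 mV at
1 µM, with slope 12 mV and a 2 ms time constant. Calcium enters a single
sub-membrane shell from the two calcium conductances, with first-order decay
(τ = 150 ms) and an influx scale of 0.10 mM·cm²/(ms·mA) that implicitly
accounts for fast buffering. Only this pool drives BK; no buffered diffusion
or GHK flux is modelled — the simplest description sufficient for
modulation ratios.

## Numerical scheme

The cable equation is integrated implicitly (backward Euler) on the branched
tree via Hines elimination — unconditionally stable for the passive system —
with gates advanced by exponential (Rush–Larsen) updates against tabulated
steady-state and exp(−dt/τ) curves (voltage grid 0.05 mV; the BK surface is
tabulated on a voltage × log-calcium grid). The default step is 25 µs;
recordings are stored at 50 µs. Protocols start from a 2 s settle to steady
state at −70 mV initial potential, and inter-step recovery in step families
is modelled as full re-equilibration (equivalent to the 5 s inter-step
interval of the experimental protocol, at a fraction of the runtime).
Halving the step changes no spike count on the control sweep. Voltage clamp
is an ideal (zero series resistance) somatic clamp implemented by a penalty
row; tail-current measurements apply leak subtraction (the same command
sequence on the passivated cell) to remove clamp transients, the in-silico
analogue of P/N subtraction.

# Feature extraction

Spikes are upward crossings of −10 mV separated by ≥ 2 ms. The F-I relation
is summarized by a least-squares line through its first linear portion;
the rheobase is the abscissa intercept and the slope is the gain. The
selection rule starts at the first suprathreshold amplitude, skips a leading
flat low-rate shelf (a lone onset spike repeated across amplitudes is not
part of the linear rising limb), and extends while the fit stays linear
(R² ≥ 0.95) and the incremental slope keeps at least half of the initial
pairwise slope, using 3–5 points. The originally envisaged stricter gate
(R² ≥ 0.98, 2-point minimum) proved degenerate with integer spike counts at
50 pA increments: count quantization alone breaks R² ≥ 0.98 on genuinely
linear portions, and two-point fits on onset shelves produce unbounded
intercepts.

Input resistance is the slope of the steady-state I–V line through the −50,
0 and +50 pA steps (mean of the last 200 ms of each step). The
after-hyperpolarization is the settled post-stimulus potential (last 100 ms)
minus the deepest hyperpolarization within 500 ms of stimulus offset,
reported as a positive magnitude and zero for monotone relaxations. The
spike voltage threshold is the membrane potential at the first local maximum
of the third time derivative before the first spike peak, computed on a
quartic Savitzky–Golay smooth over a 1 ms window; sampling coarser than
0.1 ms is refused.

# The modulation experiments

`pkc_modulation_set()` encodes the four PKC-linked changes: HCN1 × 0.425,
K_M × 0.76, K_BK × 0.50 and a −2 mV half-activation shift of the persistent
sodium conductance. `screen_single_modulations()` reproduces the
omnidirectional ±25/50% single-channel screen, and `pkc_subset_analysis()`
evaluates all 16 subsets, flagging subsets that reach at least 80% of the
full set's gain increase *and* rheobase decrease (the published claim is
qualitative; 80% is this package's operationalization).

```r
library(l5sim)
model <- build_l5_model()
ctrl <- fi_features(run_fi_protocol(model))
mod <- fi_features(run_fi_protocol(apply_modulation(model, pkc_modulation_set())))
c(ctrl$rheobase, ctrl$fi_slope)   # 269 pA, 72 Hz/nA
c(mod$rheobase, mod$fi_slope)     # 168 pA, 110 Hz/nA
```

## What the calibrated model does and does not reproduce

With the shipped calibration the control model sits at 269 pA / 72 Hz·nA⁻¹
(targets 304 / 74.4, both within 20%) and the fully modulated model at
168 pA / 110 Hz·nA⁻¹ (published 146 pA / 116 Hz·nA⁻¹, both within 20%). The
gain ratio is 1.53 (published 1.56). Known quantitative departures, each
explored extensively during model construction:

* **Rheobase ratio.** The modulated/control rheobase ratio is 0.62 versus
  the published 0.48. The joint advantage of the four modulations saturates
  near 100 pA here because reducing HCN1 does not lower the rheobase in this
  model: with the h reversal at −45 mV and a spike threshold near −50 mV,
  any resting HCN1 current is net depolarizing, so scaling it down
  hyperpolarizes rest and cancels its input-resistance benefit. Increasing
  the persistent-sodium steepness to compensate trades against onset
  bistability and depolarization block.
* **Subset necessity.** As a direct consequence, the {K_M, K_BK, Na_P}
  subset reaches the full effect, so the claim that all four modulations are
  necessary does not reproduce; the single-modulation contribution ranking
  I_h < I_M < I_BK < I_Nap does.
* **Onset spike at 250 pA.** The control fires exactly one onset spike at
  250 pA (sustained firing from 350 pA); the published model is silent
  there. Configurations without that spike push the modulated rheobase out
  of its band.
* **Threshold invariance.** At each model's own first suprathreshold
  amplitude the third-derivative threshold moves 1.9 mV under the full set
  (1.4 mV under a −4 mV Na_P shift) — above the 1 mV tolerance — because the
  slower sub-rheobase trajectory of the modulated cell pre-activates the
  persistent sodium conductance. At matched injection (400 pA) the shift is
  0.5 mV, consistent with the published invariance.
* **Post-train AHP under modulation.** At matched injection the modulated
  model fires roughly twice as many spikes and accumulates more adaptation,
  so its AHP is not smaller than control's, unlike the ex vivo observation;
  in this model the AHP is dominated by activity-dependent (M-current and
  calcium-pool) build-up rather than by the fixed conductance complement.

# Synthetic cohorts

`generate_paired_cohort()` emulates the paired study design: per cell a
log-normal baseline around the control group means (features are positive
and right-skewed), a multiplicative treatment effect (optionally
age-modulated; ages uniform on P11–P27), and additive Gaussian measurement
noise in both arms, with negative values prevented by redrawing the noise
(truncation). The group variance implied by the published SEMs is split
90/10 into between-cell and measurement components — patch-clamp feature
estimates are dominated by biological heterogeneity, and an 80/20 split
would push two of the study's own presets over the 1% negative-value
feasibility bound. Specs whose implied negative-value probability exceeds 1%
are rejected. Presets for each published comparison column ship in
`inst/extdata/cohort_presets.yaml`, including a named scenario reproducing
the reported negative age-trend of the input-resistance effect.

`generate_trace_fixture()` produces piecewise-analytic current-clamp
families (RC subthreshold charging, stereotyped spikes at the rate implied
by the target F-I line, a parametrized post-train undershoot) whose features
are recovered exactly by the extractor at zero noise and within ±10 pA
rheobase in ≥ 95% of seeds at 0.3 mV noise. The fixtures emulate the
*statistics* of recordings, not their biophysics: spike shapes are
stereotyped, adaptation is absent, and noise is white — so pipeline tests
on them validate the extraction and statistics stages, not the neuron model.

# Statistics

`paired_compare()` follows the study's rule: Wilcoxon signed-rank for
n < 8 or non-normal paired differences, paired t otherwise; normality is
assessed on the differences by Shapiro–Wilk at α = 0.05 (the study names
neither the test nor the level; both are exposed as arguments). The Wilcoxon
null is exact for n ≤ 25 without ties. Percent changes are rounded
half-to-even for reporting, with unrounded values retained; no
multiple-testing correction is applied, as none was applied in the study.

# Reproducibility

All simulations are deterministic; all stochastic components (cohorts,
fixtures) are seeded. `scripts/acceptance.R` rebuilds the calibrated model,
applies the four modulations, runs the 50 pA-increment step family and
reports the modulated F-I slope and rheobase. The problem sizes used
throughout (one F-I sweep of 13 one-second steps; 16-subset analysis on a
7-amplitude grid; cohort recovery at n = 200; 50-seed fixture calibration)
were chosen to keep a full verification run in the minutes range on one
core.
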