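---
title: "Single-channel gating analysis for Tim23-like channels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel gating analysis for Tim23-like channels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tim23ephys)
```

# Scope

`tim23ephys` analyses planar lipid bilayer recordings of a Tim23-like
mitochondrial protein-conducting channel: a large (~460 pS at 250 mM KCl),
cation-selective, voltage-gated pore whose gating responds to positively
charged presequence peptides. The package covers the full desk workflow:

1. a continuous-time Markov **simulator** that generates realistic traces
   with exact ground truth,
2. **idealization** of noisy traces into piecewise-constant level sequences,
3. **event analysis**: gating frequency, conductance-change classes, open
   probability,
4. **selectivity**: I–V assembly, reversal potentials, GHK permeability
   ratios, Boltzmann voltage dependence,
5. **dose–response** quantification of presequence activation, and
6. a **helical wheel** module for pore-lining helix geometry.

Because no public raw recordings exist for this channel, the simulator is a
first-class citizen: every estimator in the package is validated against the
simulator's ground truth rather than against irreproducible archival traces.

# The gating model

## States and conductances

The default model has four gating states around a star topology centred on
the fully open state:

| state    | conductance | transition from open | amplitude class |
|----------|-------------|----------------------|-----------------|
| `open`   | 460 pS      | —                    | —               |
| `sub290` | 290 pS      | partial closure      | 170 pS          |
| `sub400` | 400 pS      | partial closure      | 60 pS           |
| `closed` | 0 pS        | full closure         | 460 pS          |

The observable in a gating-event histogram is the conductance *change* of a
transition, not the absolute conductance of a state. The sub-state
conductances are therefore chosen so that the transition amplitudes seen
from the open level are 460, 170 and 60 pS — the three most prominent
classes of the channel's event histograms. All transitions pass through the
open state ("star" topology): partial and full closures are excursions from
the conducting pore, which is what constant-voltage recordings of this
channel show at moderate potentials.

## Baseline rates

Absolute dwell times and gating rates are not available for this channel,
so the defaults are declared calibrations, chosen once:

* `open → sub290` 1.2 s⁻¹, `sub290 → open` 600 s⁻¹ (mean sub-state dwell
  1.7 ms),
* `open → sub400` 0.35 s⁻¹, `sub400 → open` 280 s⁻¹ (3.6 ms),
* `closed → open` 10 s⁻¹ (mean closed dwell 100 ms); the `open → closed`
  rate is tied to voltage (below).

The criteria for this calibration were (a) a detected gating frequency of
order 10² events per minute at +80 mV, so that a histogram of ≥ 2000 events
is reachable in ~15 minutes of simulated recording, as in the experimental
histograms; (b) sub-state dwells comfortably above the idealizer's
resolution so detection efficiency is high and stable; and (c) sub-state
occupancy small enough that the channel "stays primarily in an open state"
at +80 mV even under saturating substrate activation.

## Voltage-dependent closure

The channel closes at high potentials of either sign. The open→closed rate
is tied to the reopening rate `rc` by a Boltzmann factor,

$$k_{\mathrm{close}}(V) = r_c \exp\!\left(\frac{|V| - V_{1/2}}{s}\right),$$

so that the stationary open probability of the open/closed pair is
$P_o(|V|) = \left(1 + e^{(|V| - V_{1/2})/s}\right)^{-1}$, a Boltzmann in
$|V|$ with midpoint $V_{1/2}$ (default 140 mV) and slope $s$ (default
12 mV). With these defaults the channel is ~99% open at +80 mV and half
closed at 140 mV. The soluble IMS domain of Tim50 promotes closure; its
presence is modelled as a configurable negative shift of $V_{1/2}$
(`tim50_shift_mV`, default −40 mV). The magnitude of the shift is a
package default, not a measured value; only its sign and qualitative effect
(closure at lower potentials) are constrained by experiment.

## Substrate activation: a fold defined on the observable

Presequence peptides induce rapid small-amplitude gating ("flickering").
The experimentally reported quantity is the *relative increase in gating
frequency* — events per minute under substrate divided by events per minute
before addition, saturating at a factor of ~50 for the wild-type channel
and ~6 for the selectivity mutant N150A.

`flicker_amax` is therefore defined directly on that observable: the target
saturating fold-increase of the stationary gating-event frequency. The
concentration dependence follows a declared Hill form

$$\mathrm{fold}(c) = 1 + (A_{\max} - 1)\,\frac{c^{h}}{c^{h} + EC_{50}^{h}}$$

with defaults $EC_{50} = 1\ \mu M$ and $h = 1.5$ (the experimental titration
did not publish its concentration grid or a fitted functional form). At
simulation time the open→sub-state ("flicker") rates are multiplied by the
factor $B$ that achieves exactly this event-frequency fold; for the star
topology $B$ has a closed form (see `flicker_rate_multiplier`). Two design
points matter here:

* A naive multiplication of the flicker rates by the fold itself would
  *not* reproduce the observed fold: pushing the chain into sub-states
  depresses open-state occupancy, so the realized event-frequency increase
  falls short of the rate multiplier. Solving for $B$ makes the simulated
  observable match the parameter by construction.
* Only the *forward* (open→sub) rates are scaled; the return rates — the
  sub-state dwell times — are substrate-independent. Consequently the dwell
  distribution of flicker events is identical in stimulated and unstimulated
  recordings, and the idealizer's finite detection efficiency cancels in
  the fold ratio. This is what makes the pipeline-estimated fold an
  approximately unbiased estimate of `flicker_amax`.

## Currents, selectivity and noise

Each state conducts ohmically with a common reversal potential:
$I = g_s\,(V - U_{rev})/1000$ pA with $g_s$ in pS and potentials in mV.
$U_{rev}$ comes from the Goldman–Hodgkin–Katz voltage equation for K⁺ and
Cl⁻ in pure KCl buffers,

$$U_{rev} = \frac{RT}{F}\,
\ln\frac{x\,[K]_{cis} + [Cl]_{trans}}{x\,[K]_{trans} + [Cl]_{cis}},
\qquad x = P_K/P_{Cl},$$

with the package-wide sign convention that reported potentials are trans
relative to cis, so a cation-selective channel under the experimental
250:20 mM cis:trans gradient reverses at a *positive* potential (+49.5 mV
at $x = 15$; the Nernst limit for the 12.5-fold gradient is
$(RT/F)\ln 12.5 = 64.9$ mV at 298.15 K). The inversion used to estimate
$x$ from a measured reversal potential is the exact closed form
$x = (r[Cl]_{cis} - [Cl]_{trans})/([K]_{cis} - r[K]_{trans})$,
$r = e^{U_{rev}F/RT}$. Concentrations are used as activities; MOPS/Tris
buffer ions are treated as impermeant. The full GHK *current* equation is
deliberately not used: selectivity in this workflow is determined solely by
the I–V zero crossing, for which the ohmic-with-offset form suffices.

Wild-type defaults use $x = 15$; the N150A variant uses $0.33 \times 15$,
matching the reported drop of the mutant's selectivity to 33% of wild type.
"Percent of wild type" is *defined* here as the ratio of $P_K/P_{Cl}$
values — the experimental normalization was not stated, so the package
declares one and validates parameter recovery under it.

Noise is additive white Gaussian, default 2 pA SD at 10 kHz sampling.
A single-pole low-pass filter is available (`filter_cutoff_Hz`) but off by
default: filtering colours the noise and would quietly invalidate the
idealizer's white-noise penalty calibration, so it is opt-in rather than
silently applied.

Jump times are simulated exactly (Gillespie), then sampled onto the uniform
acquisition grid, so dwell-time distributions are exact regardless of the
sample rate. Identical `(model, protocol, seed)` triples give bit-identical
traces.

# Idealization

`idealize()` fits a piecewise-constant signal by penalized least squares:
the number of change points is chosen by minimizing residual sum of squares
plus a per-change-point penalty. The default penalty is

$$\beta = 3\,\hat\sigma^2 \ln n, \qquad
\hat\sigma = \mathrm{MAD}(\Delta x)/\sqrt{2},$$

a BIC-like choice with the noise scale estimated robustly from first
differences (gating steps are sparse in the difference sequence, so the MAD
ignores them). The optimization is solved *exactly* with functional pruning
(FPOP). Inequality-based pruning (classic PELT) gives the same optimum but
degenerates to quadratic cost precisely on the traces this package cares
about — long recordings with sparse events; functional pruning stays
near-linear (a 60 s, 600k-sample trace idealizes in ~0.2 s). A property
test verifies equality with an exhaustive $O(n^2)$ dynamic program on small
inputs, and a numeric floor on $\beta$ prevents spurious zero-gain splits
on noiseless traces (which also makes idealization idempotent on compliant
piecewise-constant inputs).

Two merge passes follow, in a documented order (durations first, then
amplitudes, because the output depends on it):

1. segments shorter than `min_dwell_s` (default 0.5 ms, i.e. 5 samples at
   10 kHz) are merged into the neighbour with the closer level;
2. adjacent segments closer than `min_step_pA` (default 1.5 pA) are merged,
   smallest difference first.

The 0.5 ms dwell floor is deliberately below the millisecond scale:
substrate-induced flickering lives at low-millisecond dwells, and a 1 ms
floor would censor a substantial fraction of exactly the events the
dose–response analysis counts. Merged levels are recomputed from the sample
means, so per-segment residual means are ~0 and `residual_sd()` recovers
the injected noise SD.

What the segmentation can and cannot see: with $\sigma = 2$ pA at 10 kHz
and +80 mV driving force, a 170 pS step (13.6 pA) is detectable at
essentially any dwell above the 0.5 ms floor, while a 60 pS step (4.8 pA)
requires roughly 1.5–2 ms. Detection efficiency for the smallest class is
therefore well below 1. This matters for absolute event counts, and is the
reason the activation fold is estimated as a *ratio* with matched dwell
distributions (above), and why class *means* — not class weights — are the
validated output of the histogram fit.

# Event analysis

`extract_events()` emits one event per idealized transition: signed
amplitude in pA and conductance change
$|\Delta I| / |V - U_{rev}| \times 1000$ in pS, with `u_rev_mV` taken from
the recording metadata when present (simulated traces store it; symmetric
buffers imply 0). Events below a conductance floor (default 20 pS) are
excluded — the experimental counting rule did not state a floor, so it is
an explicit parameter rather than a hidden constant. Gating frequency is
events per minute over the recording duration.

`fit_conductance_classes()` fits a k-component (default 3) Gaussian mixture
to event conductances by EM. Initialization is deterministic — k-means
seeded at the interior quantiles of the data — so repeated fits of the same
events are identical; components are reported by descending mean; class SDs
are floored to avoid degenerate spikes, and any component whose weight
falls below 1% is reported as an error rather than silently returned. The
implementation is validated two ways: recovery of known synthetic mixtures,
and a fixed-point check against an independent EM implementation (mclust),
which also confirms the log-likelihood of our optimum is at least as high
as the reference optimizer's.

`open_probability()` implements the mean-over-maximum current definition on
idealized levels. Two bias corrections over a literal reading: the
*idealized* levels keep sample noise out of both numerator and denominator,
and the "maximum" is the duration-weighted mean of all segments within a
tolerance of the top level, because the plain maximum over many noisy
per-segment estimates is an extreme-value statistic biased upward (on
simulated recordings the plain maximum depressed $P_o$ by ~0.02; the pooled
estimate tracks ground-truth occupancy to < 0.005). Negative-going
recordings are handled by magnitude.

# Dose–response

`relative_activation()` and `activation_reduction_percent()` are the two
report statistics: stimulated/baseline frequency fold, and
$100(1 - \mathrm{fold}_{var}/\mathrm{fold}_{ref})$ — with folds 50 and 6
this is the 88% reduction of voltage-activated gating from wild type to
mutant. `fit_titration()` fits the Hill form above to a titration series;
the plateau is flagged non-identifiable when the largest tested
concentration is below the fitted $EC_{50}$, and flat series short-circuit
to $A_{\max} \approx 1$ with an undefined $EC_{50}$.
`simulate_titration()` chains the whole pipeline — one fixed-duration
constant-voltage recording per concentration at +80 mV, 60 s by default,
mirroring the experimental one-minute recordings per titration step.

A single one-minute baseline recording carries ~13% counting noise (events
arrive in correlated pairs, doubling Poisson variance), and every fold in a
titration shares that one baseline. Quantitative fold checks therefore
average over seeds (the acceptance suite uses 3) or pool all titration
points through the Hill fit.

# Helical wheel

`wheel_angles()` places residue $i$ of a window at
$(i - \mathrm{start}) \times 100°\ \mathrm{mod}\ 360$ — the ideal α-helix
with 3.6 residues per turn; the step is configurable because projection
figures rarely state it. `face_assignment()` tags residues by a declared
polar set (D, E, K, R, H, N, Q, S, T, Y, C; glycine counted neutral) and
reports the mean polar direction, flagged undefined when the polar vectors
cancel. `hydrophobic_moment()` is the standard Eisenberg-style vector sum
under a per-residue scale (Kyte–Doolittle shipped as the default). For the
pore-lining helix window at residues 150–163, the mutated positions N150,
Y159 and N160 fall on the polar face and L155/A156 on the apolar face under
the default classification.

# Problem sizes and what the tests show

The test and acceptance suites run entirely on simulated data, at sizes
chosen to keep the whole suite under a minute of compute while leaving
clear statistical margins: conductance-class recovery uses recordings grown
in 300 s chunks until ≥ 2000 events (~15 simulated minutes, ~9M samples);
activation folds use one-minute recordings averaged over 3 seeds;
occupancy convergence uses 10⁵ exact jumps; the segmentation oracle uses
traces up to 2000 samples with up to 4 change points, where the exhaustive
dynamic program is feasible.

Passing these suites demonstrates internal correctness — estimators recover
the generator's ground truth under the stated conditions — not fidelity to
any particular archival recording. Real bilayer data differ in ways the
generator deliberately omits: baseline drift, capacitance transients,
50/60 Hz interference, multi-channel insertions, fusion artifacts, missed
events from analog filtering, and activity coefficients below unity in
250 mM salt. The idealizer has no drift model, so slow baseline wander will
be fit as spurious low-amplitude steps; notch filtering and leak
subtraction are explicitly out of scope.

# Known limitations

* The GHK treatment is two-ion (K⁺, Cl⁻) with concentrations for
  activities; divalents, surface charge and junction potentials are out of
  scope.
* Dwell-time distribution fitting, burst analysis and missed-event
  correction are not implemented; gating frequency is a raw detected count.
* The mixture fit assumes Gaussian classes; heavily skewed amplitude
  distributions (e.g. from unresolved brief events) will bias class SDs.
* `flicker_amax` calibration requires the star gating topology; arbitrary
  rate matrices are simulated faithfully but cannot be substrate-scaled.
* The Tim50 midpoint shift and the Hill $EC_{50}/h$ defaults are declared
  package choices, not measured constants.
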