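---
title: "An in silico randomized trial of memantine and DBS in a hippocampal network model of Alzheimer's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hippotrial methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Memantine, an uncompetitive voltage-dependent NMDA-receptor antagonist, and
40 Hz deep brain stimulation (DBS) of the perforant pathway are two
candidate therapies for Alzheimer's disease whose combination has never
been compared head-to-head in a clinical trial. `hippotrial` implements a
mechanistic spiking-network model of the DG–CA3–CA1 hippocampal circuit in
which both therapies have concrete biophysical operators, and runs
randomized four-arm virtual trials (untreated AD, memantine, DBS,
DBS+memantine) on cohorts of simulated patients. The endpoints are
normalized spike counts: the number of principal-cell spikes in a region
divided by the count of the pathology-free control network under the same
stimulation, with CA1 as the primary endpoint and DG and CA3 as secondary
endpoints.

## The circuit

The network contains 8 DG granule cells (G1–G8), one mossy cell, 16 CA3
and 8 CA1 pyramidal cells, six basket cells (two per region), and one O-LM
cell each in CA3 and CA1 — all 16-compartment leaky integrate-and-fire
neurons. External drive comes from nine entorhinal layer-II lines
(Ex1–Ex9, the perforant path) carrying theta-nested gamma bursts — five
spikes at 100 Hz per 8 Hz theta cycle, phase-staggered across lines, with
Ex8 and Ex9 silent. Each granule cell receives two EC2 lines and each CA3
pyramidal cell one to two, so the loss of a single line degrades a cell
gradually instead of silencing it. Drive also arrives from entorhinal layer-III lines projecting to CA1 in
antiphase with EC2, and from nine septal GABAergic lines (T1–T9) that
rhythmically silence the hippocampal interneurons during half of each
theta cycle (disinhibition). Granule cells relay to CA3 via mossy fibers
and CA3 relays to CA1 via Schaffer collaterals (2:1 convergence); basket
cells inhibit the somata of their region's principal cells and O-LM cells
their distal dendrites. The septal cells are represented as external spike
lines rather than simulated neurons; with them excluded the simulated
network is close to the scale of the published formalism this model family
uses, and the discrepancy between that formalism's stated total cell count
and the figure-level cell labels is resolved in favor of the labels.

## Synaptic transmission

Each synapse carries two fixed-length shift registers advancing one slot
per 1 ms step: `E(i)` for AMPA (or GABA) and `M(i)` for NMDA. A
presynaptic spike loads the entry slot with the synapse's base weight
(times the LTP gain); slots decay exponentially as they age (AMPA tau 5
ms, NMDA 50 ms, GABA 10 ms) and expire after 80 slots. The summarized
potential is

S = ReP + power × ΣE(i) [+ ΣM(i) when the NMDA gate is open],

with resting potential ReP = −80 mV. `power` is `powerA` = 9 under normal
transmission; excitotoxicity raises it to `powerB` ∈ {9, 56.7, 63, 135} on
the affected synapses, modeling elevated extracellular glutamate. The NMDA
channel's Mg²⁺ block is removed when S exceeds CaMT = −68 mV; opening both
adds the NMDA register to the drive and triggers long-term potentiation (a
×1.5 weight gain for 200 ms, retriggered while the gate stays open, and
expressed only by NMDA-bearing synapses). Memantine raises the unblock
threshold to CaMem ∈ {−68, −65, −63, −55} mV; the trial's memantine arms
operate at −55 mV, taken as the nominal 10 µM point since the discrete
threshold ladder carries no explicit concentration map. The auxiliary
regulation scalar `clog` multiplies the inhibitory contribution and is 1
(inert) by default; it is exposed in the configuration because the
formalism names it without fixing its semantics.

The postsynaptic drive injected into the target compartment is
proportional to S − ReP (gain `drive_gain`, in mV/ms per mV). Because the
gate compares `power × ΣE` with a fixed threshold, the relationship
between a synapse's weight and the 12 mV gate span is the load-bearing
design constraint: perforant-path synapses onto principal cells are strong
(bursts cross the gate, and excitotoxicity saturates the survivors), while
perforant-path synapses onto basket cells are weak enough that only
excitotoxic drive — and, for DG baskets, only excitotoxic drive topped up
by the DBS train — opens their gates. The CA3 basket perforant synapses
are deliberately heterogeneous (odd lines carry a stronger variant):
the weaker variant's excitotoxic drive sits below the −55 mV memantine
threshold and the stronger variant's above it, so the memantine block of
basket hyperactivity is graded rather than all-or-none. That placement is what makes the
therapy operators act in the directions the circuit-level story requires
(see below).

## Disease and therapy operators

AD pathology disables a severity-dependent fraction of the EC2
projections onto granule cells, CA3 pyramidal cells and the hippocampal
interneurons. Loss is stratified: each of the three projection classes is
disabled in proportion to severity, with a per-class nested permutation
(fixed seed) so damage accumulates progressively. Stratification reflects
the disease description — each named pathway degrades progressively — and
keeps the interneuron-to-principal loss ratio comparable across virtual
patients, which is what makes 20-patient arm means stable enough to
analyze. Pathology also switches every surviving excitatory EC2
synapse into excitotoxic mode. The cohort generator emulates the study
population: 100 distinct networks, half moderate (severity 0.30–0.55,
excitotoxicity 56.7 or 63) and half severe (severity 0.55–0.85,
excitotoxicity 63 or 135); 20 are sampled as trial patients. The
excitotoxicity level list is not tied to stages in the source formalism;
mapping the three elevated levels onto the two severity strata (with 9
reserved for control) is this package's resolution of that ambiguity.

Memantine sets CaMem on every NMDA-bearing synapse network-wide (the drug
is systemic). DBS superimposes a regular 40 Hz spike train on all nine
perforant-path lines, including the silent Ex8/Ex9 — stimulation is
modeled as presynaptic pathway activation, not intracellular current
injection. The two operators touch disjoint state and therefore commute.

The emergent circuit logic is: excitotoxic EC2 drive onto CA3 basket
cells opens their NMDA gates during each passing burst, and the combined
NMDA current and LTP make the baskets hyperactive, suppressing CA3 (and
downstream CA1) well below control. Memantine at −55 mV closes exactly
those gates (excitotoxic drive at levels ≤ 63 stays below the raised
threshold), releasing the over-inhibition — which is why an NMDA
*antagonist* increases CA3/CA1 output in the diseased network while
barely moving DG, whose baskets are driven mainly by memantine-insensitive
granule-cell feedback. DBS adds drive to the surviving granule and CA3
synapses (raising DG and CA3) but also tops up the basket AMPA traces, so
under DBS the DG basket gates open too; memantine closes them, which is
why the combination is super-additive in DG.

## Neuron model and integration

Each cell has 16 compartments: a strongly leaky soma (tau 20 ms for
principal cells, 10 ms for interneurons), an axon segment, and two
seven-compartment dendritic branches with weak leak (tau 100 ms) and
nearest-neighbor diffusive coupling (2 /ms), integrated by forward Euler
with five 0.2 ms substeps per 1 ms step (stable for the stiffest coupling
in the model). Distal compartments (13–16) receive perforant-path and EC3
input, proximal ones (3–6) mossy-fiber and Schaffer input, the soma
receives basket inhibition. The soma fires when it crosses −54 mV and
resets to rest for an absolute refractory period (5 ms principal, 4 ms
basket, 2 ms O-LM/mossy in the cell table); the refractory ceiling is one
of the quantities that pins how far excitotoxic saturation can raise a
surviving cell's rate above control. Zero-mean Gaussian somatic noise (SD
0.3 mV per step, seeded) makes distinct virtual patients yield distinct
endpoint values; all noise is generated in R and passed to the compiled
engine, so a run is bit-reproducible from its seed.

Simulations last 2000 ms (16 theta cycles at 8 Hz); the first cycle is
discarded as transient before counting. Durations are required to be whole
numbers of theta cycles so per-cycle spike counts are unbiased. Stimulus
spike times wrap circularly at the duration boundary, which keeps per-line
counts exactly `cycles × burst_size` under any phase offset.

## The trial and its analysis

The default design is within-subject: every sampled patient is simulated
under all four arms with the same noise seed, giving 20 endpoint values
per arm (80 endpoint simulations) — the source design's "1:2:1" ratio over
four named groups is internally inconsistent, while 20 per arm matches
both its stated total of 80 simulations and its sample-size statement;
simple randomization at a configurable ratio is retained as an option. The
normalization denominator is a single control-network reference run under
the non-DBS program; DBS arms can therefore exceed 1 in DG, as intended.
Endpoints are analyzed as four independent groups per region: arithmetic
means with t-based 95% CIs (box-plot convention: mean ± 1.96 SE), one-way
ANOVA, and Tukey HSD post hoc comparisons (computed unconditionally by
default; gating on ANOVA significance is available). No repeated-measures
correction is applied, matching the analysis the design emulates. The
power calculation uses the two-sample normal-approximation closed form,
n = 2σ²(z₁₋α/₂ + z_power)²/δ²; for δ = 20%, σ = 20%, α = 0.05 and 80%
power it returns 16 per group (a t-based iteration gives 17); the design
uses 20.

## Calibration

The base synaptic weights and severity-range endpoints are free constants:
the source formalism names the mechanisms but not these magnitudes. The
shipped defaults were chosen during model development so that the control
network fires robustly in all three regions and the circuit logic above
operates in its sensitive regime. `calibrate()` then pins the remaining
freedom using only the untreated AD arm: it searches a small grid over a
scale on the feedback-inhibition weights and a shift of the severity
ranges, accepting the candidate whose AD-arm mean normalized CA1 and CA3
counts fall closest to the windows 0.29–0.36 and 0.36–0.43. The
memantine, DBS and combination endpoints are never consulted during
calibration, so the therapy-arm results of a calibrated trial are
emergent predictions of the implemented mechanisms.

## What the generator does and does not emulate

The cohort generator reproduces the study conditions: graded synaptic
loss, discrete excitotoxicity levels, stage mixture, random sampling of
20 patients. It does not model amyloid or tau biology, longitudinal
progression, receptor desensitization, a continuous memantine
dose–response (IC50 0.5–30 µM is out of scope beyond the four threshold
levels), pharmacokinetics, or electrode biophysics. Passing trials
therefore demonstrate that the implemented circuit mechanisms reproduce
the published endpoint pattern — not that the model predicts clinical
outcomes. Inter-patient variance arises only from pathology heterogeneity
and seeded membrane noise, which is narrower than biological variability.

## Numerical choices and degenerate inputs

Time step 1 ms (resolves 100 Hz bursts); register length 80 slots; the
NMDA gate is evaluated on the AMPA-side potential each step, so the open
state carries no hysteresis; LTP retriggering resets the timer rather
than stacking; disabled connections remain in the table with
`enabled = FALSE` (pathology is reversible bookkeeping and topology is
conserved). A silent stimulus yields a provably silent network (no
spontaneous activity), and normalization against a silent control region
raises an error rather than returning infinities. Theta frequency is
validated to [4, 12] Hz and DBS frequency to ≥ 40 Hz, the ranges the
modeled physiology states; "frequencies starting at 40 Hz" is read as a
single fixed train with the rate exposed in configuration.

## Known limitations

The network is small (41 simulated neurons), so endpoint values are
quantized at the single-spike level and arm means rely on cohort
averaging. Even with stratified loss, network-to-network endpoint spread
(SD roughly 0.3–0.5 on the normalized scale) remains several-fold larger
than the published arm CIs imply, so ANOVA/Tukey p-values from a single
20-patient trial are far less extreme than the reported ones and the
post hoc significance pattern is reproduced only in direction, not in
significance. Severity monotonicity of CA1 output holds for the
loss-pattern-averaged response; a single realization can transiently
disinhibit when interneuron projections happen to be lost first. The
untreated-AD dentate mean lands above control (about 1.3–1.5 rather than
near 1.0): the excitotoxic boost on surviving granule synapses outweighs
the modeled loss, and flattening it further would also flatten the DBS
response the dentate endpoints require — this residual bias is a known
trade-off of the implemented mechanism. The within-subject design is
analyzed as independent groups to match the emulated analysis, which
overstates degrees of freedom. The severity-to-excitotoxicity mapping and
the basket-cell weight asymmetries are modeling choices constrained by
the qualitative circuit story rather than measured biology.
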