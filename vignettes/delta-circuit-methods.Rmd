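---
title: "Modelling delta oscillations in a layer-V microcircuit: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling delta oscillations in a layer-V microcircuit: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(deltacircuit)
```

## The scientific problem

Delta-band oscillations (~0.5–5 Hz) are altered in schizophrenia, and many
schizophrenia risk genes encode ion channels. `deltacircuit` implements a
minimal, biophysically detailed layer-V cortical network in which those two
observations can be connected mechanistically: post-mortem bulk
RNA-expression differences between schizophrenia (SCZ) patients and healthy
controls (HC) are converted into multiplicative coefficients on the
corresponding ion-channel conductances, and the network's delta power is
read out before and after that perturbation.

The circuit contains three populations: thick-tufted layer-5 pyramidal
cells (PC, the excitatory backbone and the spectral readout), large basket
cells (LBC, fast GABA_A-receptor-mediated inhibition) and neurogliaform
cells (NGC, slow GABA_B-receptor-mediated inhibition). The default network
has 120 PC, 30 LBC and 30 NGC (one-third inhibitory).

## Cell models

Cells are conductance-based multicompartment models. The PC is a
four-compartment simplified thick-tufted pyramidal cell (soma, basal
dendrite, apical trunk, apical tuft) in the lineage of the full-morphology
Hay-type L5PC: transient and persistent Na⁺, fast (Kv3.1-like), persistent,
transient and M-type K⁺, HVA and LVA Ca²⁺ with a distal LVA hot zone,
Ca²⁺-activated SK, Ih with an apical gradient, and an intracellular Ca²⁺
pool with first-order decay. The interneurons are ball-and-stick reductions
(soma plus two dendrites): the LBC with 301 µm dendrites at 1
subcompartment each, the NGC with 245 µm dendrites at 5 subcompartments
each — geometries produced by the package's own two-stage reduction (below).
The stochastic slow K⁺ channel of the source interneuron models is replaced
by a deterministic variant (`KvDet`), so that every trajectory is exactly
reproducible.

The shipped channel-density sets (`inst/extdata/cells/*.yaml`) are reduced
parameter sets written for this package, tuned to qualitative
electrophysiology (silent at rest; monotone f-I curves spanning roughly
0–100 Hz over the 0–0.8 nA LBC and 0–0.2 nA NGC protocols), not copies of
any published full-morphology parameter files. All kinetics are evaluated
at 34 °C with the Q10 factors of the source kinetics baked in.

## Numerical integration

The integrator (C++, `src/engine.cpp`) advances the membrane equation with
a fixed-step, linearly implicit scheme: gating variables and synaptic
states are updated by their exact per-step exponential solutions evaluated
at the previous voltage, after which the voltage system is solved
implicitly — channels and synapses enter the matrix through their
conductances, so the voltage update is unconditionally stable. Per-cell
systems are solved exactly by tree (Hines-type) elimination in O(number of
compartments). Gap junctions are the only explicit coupling (they are weak,
between LBC somata only).

Design choice: the engine is fixed-step only (default 25 µs for single-cell
work, 100 µs for network runs, both configurable). An adaptive-step solver
contract was considered and rejected: the exact-exponential gating update
plus implicit voltage solve is stable at these steps, the step-refinement
invariant (10× refinement changes spike counts by ≤1 per trace) is part of
the test suite, and a fixed step keeps runs bit-reproducible, which the
deterministic-Kv substitution exists to guarantee. Voltage-dependent rate
functions are tabulated (0.05 mV grid, linear interpolation) for network
runs; the tables can be disabled, and the closed-form gating tests run with
them off.

Divergence (|V| > 200 mV) aborts a run with the offending compartment and
time; the current-clamp driver converts this into an error naming the
amplitude.

## Morphology reduction

The interneuron geometries come from a two-stage search
(`two_stage_length_search()`, `segment_count_search()`): a coarse grid over
dendrite length (50–750 µm in 50 µm steps) followed by a ±75 µm fine pass
at 1 µm, at every candidate adjusting the dendrite diameter so the total
dendritic membrane area is conserved (`d = A / (n·π·L)`, checked to 1e-9
relative in the tests); then the smallest odd subcompartment count whose
f-I error against the 19-subcompartment discretization is below an
adequacy threshold. The error score is the **sum** over amplitudes of
absolute frequency differences (a mean differs only by a constant factor
and has the same argmin; the choice is recorded in the result's
`error_metric`). The adequacy threshold defaults to 1 Hz per amplitude
point — the published criterion is qualitative ("in accordance with"), so a
concrete default had to be chosen; it is configurable. Ties break toward
the smaller length / segment count, favouring the simpler model.

Reference f-I curves are consumed as two-column text tables, so the module
never needs the original full-morphology models. The tables shipped under
`inst/extdata/fi/` are **synthetic**: they are the package's own reduced
models evaluated at the published optimal geometries, provided so the
pipeline runs end-to-end; with the original full-model tables in place the
same code reproduces the published search.

## Network construction

Connections exist for seven ordered class pairs only (PC→PC, PC→LBC,
PC→NGC, LBC→PC, LBC→LBC, NGC→LBC, NGC→PC); class pairs reported with zero
probability carry no synapses. Each ordered neuron pair connects with
probability `min(1, 6·p_base)` — the ×6 scaling compensates for the small
population relative to the full microcircuit the base probabilities come
from — and a connection carries a fixed per-class number of synapse
instances placed uniformly over the postsynaptic dendritic subcompartments.
The per-class base probabilities, synapse counts and base peak conductances
live in `inst/extdata/network.yaml`; they are lineage values adjusted so
that the inhibitory pathways keep dense coverage at small population
sizes. The NGC->PC class in particular is set to full coverage (its scaled
probability clips at 1, which the builder logs): the delta-pacing loop
runs through this pathway, and leaving its in-degree to chance made the
rhythm's strength vary severalfold between wiring realizations at reduced
scale.

Synapses are static dual-exponential conductances (no short-term
plasticity — none is part of this model). AMPA (0.3/3 ms), NMDA (2/65 ms,
sigmoidal Mg²⁺ block, 1 mM), GABA_A (0.5/8 ms, −80 mV) and GABA_B
(30/200 ms, −95 mV) kinetics are configurable; the GABA_B pair is the
experimentally constrained slow time course, and its K⁺-like reversal is a
design default (the source description leaves it open). The five free
weights `g_EE, g_EI, g_EN, g_I, g_N` multiply the class base conductances,
with `g_I` tied across LBC→PC/LBC→LBC and `g_N` across NGC→PC/NGC→LBC.
A wording ambiguity in the source (its parenthetical class lists conflict
with its tying sentence) is resolved in favour of the tying sentence:
`g_EI` drives PC→LBC only, `g_EN` PC→NGC, and the tied pairs as above.

Background drive is Poisson input onto the AMPA, NMDA and GABA_A receptors
of PC dendritic compartments only (LBC and NGC receive none). Its rates
and weights are free calibration constants — no published values exist —
frozen in `network.yaml` after calibrating the healthy-control operating
point. The full-scale calibration target is a ~3 Hz PC rate (the fit
module enforces the [2.5, 3.5] Hz window); the shipped reduced-scale
operating point sits near 1 Hz, because raising the background drive far
enough to reach 3 Hz at 40 PCs washes out the rhythm's coherence — the
oscillation fingerprints were prioritized over the rate target at that
scale. The background "GABA" drive is assumed GABA_A-kinetic.

Receptor blockade zeroes synaptic weights without deleting synapses
(exactly reversible): GABA_A blockade silences LBC→PC (the literal
description; a `block_all_gabaA` switch extends it to LBC→LBC for
pharmacological realism), GABA_B blockade silences NGC→PC and NGC→LBC.
Background drive is never touched by blockade.

## The delta rhythm and its GABA_B dependence

The healthy-control operating point was tuned so that the delta rhythm is
*paced by slow inhibition*, reproducing the pharmacological fingerprint
(GABA_A blockade leaves delta power roughly intact or slightly increased;
GABA_B blockade collapses it): recurrent AMPA excitation (with a small
NMDA component) synchronizes PC firing into population events; each event
recruits the NGCs, whose slow GABA_B conductance (30/200 ms)
hyperpolarizes the PCs toward −95 mV for several hundred milliseconds,
and the synchronized release from that inhibition (helped by
low-voltage-activated Ca²⁺ deinactivation) seeds the next event.
Population events are additionally curtailed by strong Ca²⁺-activated SK
adaptation driven through the HVA Ca²⁺ channels — the same conductances
the expression coefficients act on, which is what makes the circuit's
delta power sensitive to them. Blocking GABA_B removes the pacing: the
network settles into a higher-rate, asynchronous-irregular state
(contained by the disinhibited LBC population via NGC→LBC), whose delta
power is floor rather than rhythm. Two further choices matter for this
regime and are deliberate: the NMDA fraction of recurrence is small so
that the GABA_B-blocked state does not itself slow-oscillate through
regenerative NMDA up-states, and the LVA density is moderate so that the
pacing does not ride primarily on rebound Ca²⁺ spikes (a strongly
LVA-paced rhythm is *strengthened* by the SCZ coefficient set, whose LVA
coefficient exceeds 1, masking the HVA/SK-mediated decrease).

## Spectral readout

All spectral estimates are computed from PC spiking only: the population
spike-count series (1 ms bins, mean-subtracted, first 1000 ms discarded as
transient) is passed through a Welch estimator (Hann window, 50% overlap;
8192 ms segments at full scale, 4096 ms at desk scale — chosen to resolve
the 0.5 Hz delta edge within the simulated durations). Normalization is
Parseval-consistent (the one-sided PSD integrates to the signal variance),
verified against a sinusoid oracle and a flat-spectrum process in the
tests. Band powers are means over in-band frequencies by default; a `sum`
reduction is provided, and between-condition ratios are invariant to the
choice on a common grid (asserted in the tests). Band edges default to
delta [0.5, 5), theta [5, 8), alpha [8, 12), beta [12, 30), gamma
[30, 150) Hz, with a preset for the 13 Hz beta-edge variant. LOESS
smoothing (`loess_smooth()`) exists for presentation only and never feeds
statistics.

## Calibration

`grid_search_conductances()` evaluates the 3⁵ factorial over
`g_EE ∈ {0.2, 0.25, 0.3}`, `g_I ∈ {0.5, 0.6, 0.7}`, `g_EI ∈ {0.7, 0.75,
0.8}`, `g_EN ∈ {1.2, 1.4, 1.6}`, `g_N ∈ {0.6, 0.8, 1.0}` with 3 seeds per
candidate, rejects candidates whose control rates leave the PC [2.5, 3.5]
Hz or LBC [3, 12] Hz windows, confirms survivors with 5 seeds, and scores
them against the blockade targets (GABA_A → 109% of control delta power,
GABA_B → 17%). The wiring and noise seeds are shared across the three
conditions of one evaluation so that blockade is the only difference — this
is a variance-reduction choice the source leaves open. The selection
sentence admits two readings; the default score is the summed absolute
deviation `|ratio_A − 109| + |ratio_B − 17|`, with the alternative
(`alteration_difference`) available, and every result is labelled with the
scoring used. The search is restartable from its persisted evaluation
table and bit-reproducible under a deterministic simulator.

## Expression mapping

`gwas_filter()` keeps genes whose minimal single-SNP p-value is below
5×10⁻⁶ *and* that appear in the closed-world gene→channel map (CACNA1C,
CACNA1D → HVA Ca²⁺; CACNA1I → LVA Ca²⁺; HCN1 → Ih; KCNB1 → persistent K⁺;
KCNQ3 → M-type K⁺; GABBR2 → GABA_B synaptic conductance). Although the Ih
current is a mixed cation current rather than a pure K⁺ conductance, the
HCN1 coefficient targets the Ih mechanism — the mapping follows the
channel, not the label. Glutamatergic and GABA_A receptor genes are
deliberately excluded (antipsychotic confound).

Group ratios are ratios of group means (`mean(SCZ)/mean(HC)` per gene and
region) — the most direct reading of an "average difference between
populations"; subjects with missing mapped genes error out of subject-wise
runs by name. The HVA coefficient is the mean of the CACNA1C and CACNA1D
ratios; all other genes pass through. Subject-wise coefficients divide the
subject's expression by the HC regional mean (HC subjects included), which
makes the mean of subject-wise SCZ coefficients algebraically equal to the
population-averaged coefficient — asserted as an identity in the tests.
Coefficients are scale-invariant to global count rescaling.

`apply_coefficients()` multiplies channel densities wherever the channel
exists in the targeted populations; the GABA_B coefficient multiplies
GABA_B synaptic peak conductances whose *postsynaptic* cell is targeted.
Application is multiplicative and exactly invertible.

## The synthetic data generator

`generate_expression()` emulates the post-mortem cohorts: ACC with 230 SCZ
/ 251 HC and PFC with 263 SCZ / 295 HC subjects, per-gene HC means with
gamma-distributed values (a continuous gamma-Poisson-like model, since
normalized counts are non-integer; dispersion 0.2 by default, i.e. ~45%
coefficient of variation, a typical bulk RNA-seq between-subject spread)
and SCZ means equal to ratio × HC mean, the ratios defaulting to the
published per-gene regional coefficients. Decoy genes (ratio 1, GWAS p
above threshold) exercise the filter. What the generator does **not**
emulate: covariates (sex, age, post-mortem interval), gene–gene
correlation, and library-size artefacts — so passing the recovery tests
shows the pipeline arithmetic is right under the stated count model, not
that it is robust to real-data confounding. Dispersion 0 degenerates to
exact group means, which the tests use as an exactness oracle, and
parameter recovery at default cohort sizes is checked against the gamma
model's delta-method standard error.

## Experiments and statistics

Four experiments mirror the analysis: population-averaged (regional
coefficient set applied to all populations), subject-wise (one simulation
per subject), single-channel (one coefficient at a time) and
per-population (full set in one population at a time). Arms share seed
lists; the HC arm is always the unmodified network. Comparisons use the
two-sided Mann-Whitney U test with tie correction (sidedness is a design
default — the source states only "U-test"); raw p-values are reported with
no multiple-testing correction, matching the reporting style of the
analysis this reproduces, and the output labels them as uncorrected.

Two scale presets exist. `paper`: 120/30/30 cells, 30 seeds, 20 s + 1 s
transient per simulation — full-scale runs, hours of CPU. `desk`: 40/10/10
cells, 5 seeds, 15 s + 1 s transient — the preset used by the test suite
and the acceptance script (longer than a minimal desk window because the
Welch delta estimate needs several 4096 ms segments to be stable at 40
pyramidal cells). The desk preset preserves the qualitative
fingerprints in seed-averages (GABA_B blockade lowers delta power while
GABA_A blockade does not; the SCZ coefficient set lowers delta power and
the PC rate; the PC population carries the effect) but not the published
effect magnitudes: with one-third the neurons the coherent delta peak
shrinks relative to the population shot-noise floor, so the GABA_B
blockade ratio is compressed toward 100% — individual seeds can cross
it — and the GABA_A blockade ratio is inflated far above 100% because
removing fast inhibition raises the PC rate, which inflates all spectral
power at 40 cells. Published full-scale
magnitudes are not expected to reproduce from this reimplementation's
parameter sets in any case, since the original cell parameter files and
background-drive calibration are not part of its inputs.

## Known limitations

- The spectral readout is PC spiking, not an LFP/EEG forward model.
- Channel kinetics are Hay-lineage forms with package-tuned densities, not
  the original full-morphology parameter sets; single-cell f-I curves are
  qualitatively, not quantitatively, matched to the originals.
- The background drive is stationary Poisson and unaffected by the
  SCZ coefficients.
- Fixed-step integration at 100 µs for network runs trades some spike-time
  accuracy for speed; the refinement invariant bounds the effect at one
  spike per trace on the shipped cells.
- Thalamic delta generation, developmental wiring effects and
  antipsychotic confounds are outside the model.
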