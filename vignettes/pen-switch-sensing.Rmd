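---
title: "Modelling small-molecule sensing with PEN-DNA bistable switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling small-molecule sensing with PEN-DNA bistable switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pensense)
```

## The system being modelled

PEN-DNA circuits use three enzymes — a strand-displacing **P**olymerase, an
**E**xonuclease and a **N**icking endonuclease — together with short,
chemically protected DNA templates to build isothermal reaction networks.
Information is carried by short single-stranded "signal" oligonucleotides
(here an 11-mer, B11, and its complement aB11) that are continuously
produced, exchanged and degraded.  `pensense` models the sensing
architecture built from five template modules:

* **aT** (autocatalytic template): a signal binds, is extended and nicked,
  releasing two copies — exponential amplification.
* **pT** (pseudotemplate): binds signal preferentially and deactivates it
  with a short poly-T tail.  The reaction is fast but saturable, so pT acts
  as a finite-capacity sink: below a signal-concentration threshold the
  sink wins, above it amplification takes over.  aT + pT + rT form a
  bistable switch whose state is set by the signal concentration.
* **rT** (reporter template): a fluorophore/quencher hairpin irreversibly
  opened by signal extension — the fluorescence observable.
* **sT** (source template): a constant, unconditional producer of signal.
* **psT / pskT** (protein-sensing templates): hairpin source templates
  whose nicking site overlaps a transcription-factor operator.  A bound TF
  blocks the nickase sterically and shuts production off.  A psT outputs
  signal (direct logic); a pskT outputs antisignal (inverted logic), which
  annihilates signal by hybridisation.

Allosteric TFs couple this DNA layer to small molecules: an *inducer*
(IPTG on LacI) releases the TF from its operator; a *corepressor*
(L-tryptophan on TrpR) is required for operator binding.  An optional
enzyme layer produces the effector in situ (tryptophan synthase B making
L-trp from indole and L-serine), so the circuit reads out enzymatic
activity.

## The kinetic model

`build_network()` translates a `circuit_spec` into mass-action /
Michaelis-type ODEs over free signal $s$, antisignal $a$, deactivated
signal $d$, unreported and reported reporter ($r_U$, $r_R$; their sum is
conserved), and one pool per ligand:

$$
\dot s = k_{amp}\,[aT]\frac{s}{K_{m,a}+s} + k_{src}\,T_{sig}^{free}
 - k_{deact}\,[pT]\frac{s}{K_{m,p}+s} - k_{rep}\,r_U\,s - k_{degr}\,s
 - k_{hyb}\,s\,a
$$
$$
\dot a = k_{src}\,T_{anti}^{free} - k_{degr}\,a - k_{hyb}\,s\,a,
\qquad \dot r_R = k_{rep}\,r_U\,s = -\dot r_U
$$

with $K_{m,p} \ll K_{m,a}$ (trigger binding is biased towards pT) so the
sink dominates at low $s$ but has limited capacity $k_{deact}[pT]$, while
amplification capacity $k_{amp}[aT]$ is larger — the combination that
makes the switch bistable.  Reporting is irreversible, so noise-free
traces are non-decreasing.

**TF binding is quasi-equilibrium.**  TF–operator association is fast
relative to the hour-scale switch, so at each evaluation the
operator-competent TF concentration is recomputed from the current ligand
pool and the free sensing-template concentration follows the exact
two-species binding quadratic (`template_occupancy()`).  The allosteric
model is a simple effective-competence Hill scheme rather than MWC:
corepressors are competent with fraction $L^h/(K_L^h + L^h)$; inducers
fall from 1 to a residual $1/f$ at saturation,
$(K_L^h + L^h/f)/(K_L^h + L^h)$, with induction fold $f = 10^4$
(IPTG weakens LacI binding by over four orders of magnitude).  We use
$h = 2$ for both TFs (TrpR binds two tryptophans; LacI dimers bind two
inducer molecules); this is an implementer choice, not a measured value.

**Enzyme layer.**  Two-substrate Michaelis–Menten kinetics,
$v = k_{cat} E \cdot \frac{I}{K_{m,I}+I} \cdot \frac{S}{K_{m,S}+S}$, with
substrate depletion; the product feeds the TF's ligand pool dynamically.
The $K_m$ defaults (100 uM indole, 1 mM serine) are order-of-magnitude
placeholders and are flagged as non-authoritative; the $k_{cat}$ defaults
only encode the observed activity ordering EcB > PfB T292S > PfB wt at
37 °C.

## Rate-parameter calibration (frozen defaults)

No rate constants for this chemistry at 37 °C are available to us, so
`rate_parameters()` exposes calibration parameters whose defaults were
fixed once, against the behaviour the circuits are known to show, and are
not adjusted per analysis:

| parameter | default | units | role |
|---|---|---|---|
| `k_amp` | 0.01 | /nM/min | autocatalysis on aT (capacity 0.5 nM/min at aT = 50) |
| `km_amp` | 2 | nM | signal Km on aT |
| `k_deact` | 0.0135 | /nM/min | deactivation on pT (capacity 0.095 at pT = 7) |
| `km_deact` | 0.2 | nM | signal Km on pT (10x tighter than aT) |
| `k_report` | 0.0007 | /nM/min | reporting on rT |
| `k_source` | 0.017 | /min | output per free source template |
| `k_degr` | 0.0033 | /min | exonuclease degradation of free strands |
| `k_hyb` | 1.4 | /nM/min | signal–antisignal annihilation |

The calibration anchors were: (i) the unrepressed 5 nM psT circuit fires
the standard switch (aT 50 / pT 7 / rT 10 nM) at Cq ≈ 70 min, inside the
experimental 60–120 min window; (ii) the off state of that switch is
stable while its amplification capacity exceeds the sink capacity
(bistability, threshold ≈ 0.25 nM initial signal); (iii) a 1 nM psT — the
weakest single-input composition used — still fires, with a flux margin of
about 2 over the escape threshold; (iv) the exponential blow-up and
reporting phases are fast (e-fold ≈ 10 min, reporting τ ≈ 30 min) so
traces rise sharply and the steepest-window statistic is robust to
measurement noise; (v) hybridisation is fast enough that the signal /
antisignal competition resolves as winner-take-all, which is what produces
the clean inverted (ultrasensitive) transitions.

Two template-level choices follow from the same calibration rather than
from printed concentrations.  First, the source template in inverted
circuits defaults to **sT = 1.2 nM**: under the shared source turnover
`k_source`, its flux must exceed the switch's escape threshold but stay
below the pT sink capacity, otherwise the circuit either cannot fire when
the killer template is blocked or partially fires during the initial
transient before antisignal accumulates.  (A pM-scale sT cannot satisfy
the first condition under a shared turnover; we treat reported pM-scale sT
concentrations as evidence that the real sT turnover differs from psT's,
which our model deliberately does not resolve.)  Second, operator
affinities are design knobs, as they are experimentally (operators
spanning 1 pM–100 nM exist for LacI): the direct LacI circuits use the
tight 1 pM operator (giving the stoichiometric repressor titration that
saturates near the psT concentration), the TrpR circuits use a tight 5 nM
operator so that a 50–210 nM dimer can fully occlude a 10 nM pskT, and the
two-input classifier circuits use a moderate 10 nM LacI operator so that
occupancy stays graded across the IPTG range — a step-like axis carries no
log-sum weight.

## The Cq statistic

`extract_cq()` implements the time-to-switch measure used on the
experimental traces: normalise each trace affinely onto [0, 1], compute
forward differences between points 10 min apart (start points in the final
10 min are excluded), and report the earliest start time of the maximal
difference.  Ties break to the earliest start point.  Responses are
summarised as $1/C_q$, with flat traces assigned 0.

The flat call in the experiments was manual; reproducibility requires a
rule, so a trace is flat when either (a) its raw dynamic range is below
`min_range` — by default 5% of the set's fluorescence full scale (the
reporter concentration for simulated sets), so measurement noise and slow
sub-threshold reporter creep are never normalised into a response — or (b)
the maximal normalised window difference is below `flat_threshold`
(default 0.05).  Both thresholds are recorded in the `cq_params` attribute
of every `batch_cq()` table.  Non-uniform time grids are rejected rather
than resampled, keeping the statistic bit-stable.

## Dose–response assembly and Hill fitting

`assemble_dose_response()` averages replicate $1/C_q$ per concentration;
flat replicates contribute 0.  The error bar follows the reference
convention: the maximum absolute single-replicate deviation anywhere in
the data set, applied uniformly to every concentration.

`fit_hill()` fits the four-parameter Hill law (floating baseline,
amplitude, $K_d^{app}$, $n$) by Levenberg–Marquardt least squares.  High
Hill coefficients ($n \approx 10$) have narrow convergence basins, so the
fit is multi-started: $K$ from the geometric mean of the positive
concentrations and a decade either side, $n \in \{1, 2, 8\}$, best
residual wins.  Fitting is unweighted (the error-bar convention above is a
display convention, not a variance model) and performed in linear
concentration space so zero-concentration points are retained.  Direction
is inferred from the Spearman rank correlation when not supplied.  Whether
the reference fits floated all four parameters is unknown; we float all
four and report the residual norm.

## What the synthetic data does and does not emulate

`simulate_circuit()` + `add_noise()` generate minute-sampled traces with
sigmoidal activation, ligand-dependent switching times, flat repressed
traces, multiplicative Gaussian noise and optional drift — the features
the downstream statistics consume.  `synth_hill_traceset()` generates
logistic traces whose switching time encodes a known Hill law exactly;
estimator-recovery studies use it so ground truth is available.

Real traces additionally show template-independent parasitic
amplification at long times (excluded from analysis in the reference
workflow and deliberately not modelled here), non-specific dye channels,
pipetting variability between replicates beyond i.i.d. noise, and slow
baseline photobleaching.  Passing tests therefore validate the method's
logic and numerics, not robustness to parasites or instrument artefacts.
Because our rate constants are calibrated rather than measured, simulated
apparent $K_d$ values land in the right order of magnitude but are not
expected to match the experimental values numerically; directions of
response, the sharpening of inverted designs, saturation stoichiometry and
the classifier sign structure are the transferable predictions.

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), rtol 1e-8 / atol 1e-10 on
  the nM scale, output on the 1-min acquisition grid; integration failures
  are reported with the offending condition label.
* Binding quadratic: evaluated as $2q/(s+\sqrt{s^2-4q})$ to avoid
  cancellation at tight binding.
* Cq ties: earliest start point, with a 1e-9 tolerance so floating-point
  noise cannot break exact ties.
* Hill fit bounds: $K > 0$, $0 < n \le 100$, amplitude $\ge 0$; degenerate
  (flat) curves and curves with fewer than 4 concentrations are rejected
  with informative errors rather than fitted.
* Log-sum fit: flat cells ($1/C_q = 0$) are censoring values, not response
  levels, and are excluded from the plane fit.
* Seeds are mandatory wherever noise is generated and are stored in the
  trace-set conditions; the pipeline derives per-replicate seeds
  deterministically from the base seed, so end-to-end runs are
  byte-reproducible.

## Problem sizes used in the shipped analyses

The analysis scripts and tests run at desk scale, chosen as the smallest
sizes that exercise every regime: dose responses use 10–12 concentrations
(3 replicates at 2% noise), classifier maps 6×6 log-spaced grids over
1–1000 uM, estimator-recovery studies 50 seeds per $K_d$ on the grid
{24, 69, 100, 500} uM, and simulations run 500–700 min horizons at 1-min
sampling.

## Known limitations

* One shared `k_source` for sT, psT and pskT; real self-priming turnovers
  likely differ per template (see the sT discussion above).
* TF occupancy is computed per template against the full TF pool;
  competition between two templates for one TF is not modelled (no shipped
  circuit needs it).
* Quasi-equilibrium TF binding: sub-minute TF kinetics are invisible.
* The disruption flag above 10 uM enzyme is a label, not a mechanism — the
  model does not simulate the non-specific interference itself.
* Parasitic amplification, multi-channel readouts and emulsion operation
  are out of scope.
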