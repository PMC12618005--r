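---
title: "Methods: sleep scoring, repair readouts and expression responses"
author: "cavesleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep scoring, repair readouts and expression responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavesleep)
```

`cavesleep` implements the quantitative backbone of studies that compare
sleep behaviour and the DNA-damage response between *Astyanax mexicanus*
surface fish and cavefish: sleep scoring from locomotor velocity traces,
the host-cell-reactivation (HCR) flow-cytometry statistic, fluorescence
quantification over ROIs and nucleus masks, and the downstream
expression-response computations. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices that were
genuinely open.

## Sleep scoring

Sleep in larval fish is defined behaviourally: a **sleep bout** is a
maximal interval of consolidated immobility lasting at least 60 s, where a
frame counts as immobile when its velocity falls below a 6 mm/s cut-off
that separates active swimming from passive drift. Both numbers are
parameters of `scoring_config()` (`velocity_threshold`, mm/s;
`min_bout_s`, s) with those conventional defaults.

Three readings of the definition were open and are fixed as follows:

* **Ties at the cut-off.** Immobility is the *strict* inequality
  `velocity < threshold`: a fish swimming at exactly the cut-off is
  active. The threshold is configurable, so the opposite reading is one
  parameter nudge away.
* **"Consolidated".** Interpreted as *uninterrupted* immobility:
  `max_gap_s = 0`. A gap tolerance exists (interruptions up to
  `max_gap_s` are absorbed into a bout) but defaults off, since no
  tolerance is part of the definition.
* **Missing frames.** Under the default `nan_policy = "break"` a missing
  frame is treated as mobile and breaks any bout — conservative against
  inflating sleep. `"fill_short"` lets gaps of at most 1 s inherit the
  preceding frame's state.

Durations are whole frames times the frame period, so the 60 s rule is a
closed bound: 60 immobile frames at 1 Hz qualify, 59 do not.

**Windowed metrics** (`compute_sleep_metrics()`) follow two different
edge conventions on purpose: total sleep sums each bout's *overlap* with
the window (time is conserved when a bout straddles an edge), while bout
number counts bouts whose *onset* lies in the window and mean bout length
averages the full durations of those counted bouts (counts stay
integral). **Profiles** (`compute_sleep_profile()`) apportion sleep to
consecutive bins by exact overlap, so bins always sum to the windowed
total; the bin axis is Zeitgeber time (ZT0 = lights-on via `zt0_offset`),
with day ZT0–14 and night ZT14–24 under the 14 h:10 h light:dark
schedule.

### Transition probabilities

Sleep pressure and sleep depth are summarised by per-epoch transition
probabilities: P(doze), the probability that a wake epoch is followed by a
sleep epoch, and P(wake), its converse. The estimator in
`transition_probabilities()` is the Markov-chain maximum-likelihood one:
transitions divided by source-state epochs *that have a successor*; a
probability whose source state never occurs is reported as missing, never
as zero. Epochs are 1 s by default, the resolution of the sleep
definition.

Epochs can be labelled two ways, and the choice matters:

* **Bout membership** (pass `bouts`): an epoch is sleep when it starts
  inside a scored bout. This is the scored behavioural state — what a
  sleep/wake-probability figure reports — but the 60 s rule censors every
  quiescent dwell shorter than a minute, so these estimates are *not*
  estimates of an underlying two-state chain's rates when dwells are
  short.
* **Full-epoch immobility** (pass `flags`): an epoch is sleep when all
  its frames are immobile. This labelling estimates the underlying
  mobility-state chain directly and is the one used for parameter
  recovery against the simulator.

## The locomotor simulator

`simulate_locomotor_trace()` generates traces from an explicit two-state
hidden Markov chain on 1 s epochs: active → quiescent with probability
`p_doze` per epoch, quiescent → active with `p_wake`. Defining dynamics on
epochs rather than frames keeps the probabilities frame-rate-independent;
the hidden state is expanded to frames at `frame_rate` and each frame's
velocity is drawn from the state's emission, a normal truncated at zero
(velocities are non-negative; no emission model is part of the behavioural
definition, so the simplest non-negative one is used). State sequences are
sampled as alternating geometric dwell times, which is distributionally
identical to the per-epoch Bernoulli chain and much faster; the test suite
checks the equivalence against an explicit per-epoch simulation.

Default emissions are active 25 ± 4 mm/s and quiescent 0.5 ± 1 mm/s —
realistic larval swim and drift speeds whose mass on the wrong side of the
6 mm/s cut-off is negligible (≈ 10⁻⁶), so scored immobility tracks the
hidden state and recovered transition probabilities can be compared to the
generative ones. The long-run quiescent fraction converges to
`p_doze / (p_doze + p_wake)`; tests verify the empirical fraction within
three standard errors, using the occupancy variance of a two-state chain
(inflated by `(1+ρ)/(1−ρ)` with `ρ = 1 − p_doze − p_wake`).

Cohorts (`simulate_cohort()`) derive per-subject seeds deterministically
from a master seed, giving reproducible cohorts with independent streams.
The simulator emulates two-state locomotor dynamics with emission noise;
it does **not** emulate tracking artefacts, circadian modulation of
transition rates, arousal-threshold dynamics, or inter-individual
parameter variability. Passing tests therefore demonstrate correctness of
the scoring computations, not robustness to every property of real
tracking data.

## Group statistics

The figure-level comparisons — one-way ANOVA on per-fish metrics, unpaired
t-tests, mean ± SEM — are implemented from their closed forms
(`one_way_anova()`, `unpaired_t_test()`, `summarize_groups()`) so that
every number is oracle-checkable; `aov()` and `t.test()` appear only as
independent oracles in the tests. P-values are two-sided throughout, and
the t-test defaults to Welch (pooled available by flag) since sidedness
and variance assumptions are rarely stated alongside reported tests.
SEM uses the sample standard deviation over √n and is undefined at n = 1.
Mixed-effects and repeated-measures analyses are routine delegations to
standard libraries and are not re-derived here.

## Host-cell reactivation

The HCR assay transfects cells with a UV-damaged GFP reporter plasmid;
recovered fluorescence after ~50 h measures repair capacity. From
live-gated events, with N the number of GFP-positive live cells, MFI their
mean GFP intensity and S all live cells,

&nbsp;&nbsp;&nbsp;&nbsp;F = N × MFI / S,&nbsp;&nbsp;&nbsp;
%RE = 100 × F(treated) / F(undamaged).

`%RE` is invariant under a global rescaling of GFP intensities applied to
both samples, and `F = 0` exactly when `N = 0` (MFI is then undefined but
F is defined as zero). When the undamaged sample's F is zero the ratio is
reported as missing with a warning, never as a number.

Gating choices: live gating uses the viability-dye channel alone (live iff
dye below threshold) — the dye is the quantitative criterion, and no gate
geometry for the scatter channels is part of the statistic; scatter
columns are carried but ignored by default. The GFP-positive threshold,
when not supplied manually, is the 0.999 quantile (type-7, linear
interpolation — the common default, fixed for determinism) of a live-gated
*untransfected* control's GFP intensities: a reproducible stand-in for a
hand-drawn positivity line. Events arrive as CSV tables; binary FCS
parsing is out of scope. Published %RE values from real experiments depend
on hand-set gates and raw event data and are not reproducible from summary
statistics; the package instead validates %RE on simulated pairs with a
known efficiency ratio (`simulate_flow_events()`), where a treated
efficiency of half the untreated one must yield %RE ≈ 50.

## Image quantification

Three deterministic operations mirror the fluorescence readouts:

* `z_project_mean()` — pixelwise average-intensity projection over
  slices, the projection run before ROI drawing in the gut-ROS (DHE)
  workflow.
* `roi_mean_fluorescence()` — mean over pixels whose *centers* fall
  inside a named polygon under the even-odd rule, matching common
  ImageJ-style ROI behaviour and unambiguous at boundaries. An ROI with
  no interior pixel centers is an error naming the ROI.
* `nucleus_mean_fluorescence()` — per-label mean over a nucleus label
  mask ("mean fluorescence per nucleus area"); segmentation itself
  (e.g. Cellpose) is an input, not a computation. Background subtraction
  (median of label-0 pixels) is available but off by default, since the
  standard figures report raw means normalised only by region. Whether
  per-nucleus means are taken on a projection or a single section is not
  fixed by convention; the package quantifies whatever 2-D image it is
  given and the examples use the mean projection.

A weighted (by pixel count) average of per-region means over any partition
of the image recomposes the global mean exactly; this conservation
property is tested. The image simulator plants uniform-intensity disk
nuclei on a constant background so that, at zero noise, per-nucleus means
equal `background + intensity` exactly — deliberately simple geometry that
makes quantification exactly checkable, not a model of confocal optics.

## Expression responses

All downstream computations take per-gene differential-expression
summaries (`gene`, `log2fc`, `pvalue`, `padj`) as inputs; alignment and
model fitting live upstream.

* **Significance rule.** A gene responds when its BH-adjusted p-value is
  below 0.05 (`bh_adjust()` wraps the standard step-up adjustment;
  `alpha` is a parameter everywhere it is used).
* **Classification** (`classify_population_response()`): responding in
  both populations ⇒ `shared`; in exactly one ⇒ `surface_specific` /
  `cave_specific`; otherwise `nonresponsive`. Directions come from the
  sign of log2FC. Genes missing from one table count as non-responding
  there, so the categories partition the union universe.
* **Ranking** (`rank_genes()`): score = −log10(p) × sign(log2FC). The
  score is written as a division by sign in some methods sections;
  multiplication and division coincide for sign ±1, and log2FC exactly 0
  maps to score 0, the only direction-free value. p = 0 is clamped to the
  smallest positive p in the table (floor 10⁻³⁰⁰) to keep scores finite.
  Ties break lexicographically by gene id, giving a deterministic total
  order.
* **Enrichment** (`preranked_gsea()`): the weighted Kolmogorov–Smirnov
  running-sum ES (hits weighted by |score|^weight, weight 1 by default;
  weight 0 recovers the classical KS form — tested). The null permutes
  *gene labels* (uniform hit positions), the only permutation available
  for preranked summaries, with a two-sided p-value
  `(1 + #{|ES₀| ≥ |ES|})/(n_perm + 1)` and NES = ES over the mean |null
  ES| of matching sign; BH across sets; set-size bounds default to
  10–500. This is the same statistic family as multilevel preranked GSEA
  implementations but a plain permutation scheme; exact p-value
  equivalence with those implementations is not claimed, and the ES
  itself is cross-checked against an independent implementation in the
  tests. Gene-set membership arrives as GMT files
  (`read_gmt()`); no ontology database is consulted, removing
  network- and version-dependence.
* **qPCR** (`delta_delta_ct()`): technical replicates are averaged on the
  Ct scale (the conventional order of operations), then
  ΔCt = Ct(target) − Ct(housekeeping) per sample,
  ΔΔCt = mean ΔCt(condition) − mean ΔCt(reference), fold change =
  2^(−ΔΔCt). The reference condition's fold change is exactly 1 by
  construction; a sample lacking the housekeeping gene is an error naming
  the sample.

The DE simulator plants responders as independent per-gene z-tests
(log2FC estimate normal around ±`effect_size_log2fc` with standard error
`se_log2fc`; defaults 2 and 0.4, a typical bulk RNA-seq scale), so null
p-values are exactly uniform, BH's FDR guarantee applies, and planted
power is governed by the effect-to-SE ratio. It does not model
inter-gene correlation or dispersion heterogeneity.

## Numerical choices and check sizes

Degenerate inputs are defined rather than left to float arithmetic: zero
within-group variance gives F = 0 (equal means) or F = ∞ with p = 0
(unequal); a zero-variance t comparison with equal means gives t = 0,
p = 1; empty label masks give empty results; a whole-universe gene set has
ES = 1 by convention (no misses). All generators restore the caller's RNG
state and are bit-reproducible given their seed.

The verification suite runs at these problem sizes, chosen to make
Monte-Carlo bounds sharp while keeping the full suite fast: 10,000 random
sequences (10–10,000 frames, 1–30 Hz) for bout-oracle equivalence; 50
subjects × 24 h × 1 Hz for transition-probability recovery (median
relative error < 10%); 20 replicate 50,000-event pairs for %RE; 100
replicates of 2,000-gene tables for FDR/power; 1,000 random instances plus
100 null sets × 1,000 permutations for enrichment calibration.

## Known limitations

Real tracking data bring artefacts (lost frames, reflections, arena
effects) that the generator does not emulate; published group statistics
from specific experiments require the underlying raw recordings and are
not reproducible from summaries. Flow gating here is one-dimensional per
channel, not polygonal in scatter space. Image quantification is 2-D;
volumetric (3-D) quantification and segmentation are out of scope. The
enrichment p-values are permutation-based and bounded below by
1/(n_perm + 1).
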