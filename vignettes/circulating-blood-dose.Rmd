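---
title: "Simulating the dose to circulating blood in radiotherapy plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the dose to circulating blood in radiotherapy plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## Why circulating blood is an organ at risk

Circulating lymphocytes are among the most radiosensitive cells in the body,
and radiation-induced lymphopenia is increasingly treated as a planning
concern in head-and-neck radiotherapy, where large cervical vessels sit next
to the target. Unlike a static organ, blood moves: over a fractionated
course, a substantial fraction of the whole blood pool transits the
irradiated volume during beam-on windows that last only minutes. The dose
absorbed by blood therefore depends jointly on the spatial dose
distribution (summarized per organ by a dose-volume histogram, DVH) and on
the temporal dynamics of the circulation relative to the delivery schedule.

`circdose` estimates this dose with a compartmental Monte-Carlo model: the
blood pool is discretized into computational particles that move between
organ compartments of a whole-body circulation model and, while the beam is
on, accumulate dose sampled from the organ-level DVHs of the plan under
evaluation. The result is a circulating-blood DVH with the usual scalar
metrics (Dmean; D90%, D70%, D50%, D30%, D10%, D2%; V0.9Gy).

## The circulation model

The circulation is represented as parallel compartments with blood volume
$V_o$ (mL) and blood flow $Q_o$ (mL/min). A particle finishing its
residence in one compartment is reassigned to a compartment with
probability proportional to $Q_o$ and stays there for a residence time with
mean equal to the transit time $60\,V_o/Q_o$ seconds. Two residence models
are available: deterministic residence at exactly $V_o/Q_o$ (the default)
and exponential residence with the same mean, switched by the `residence`
argument. The parallel flow-weighted topology is the minimal model with the
correct stationary behaviour: the probability of finding a particle in
compartment $o$ converges to its volume share $V_o/V_{\mathrm{total}}$,
which is what reference physiology implies when residence is $V_o/Q_o$ and
visits are flow-weighted.

Totals are sex-specific reference values (ICRP Publication 89): 5.3 L of
blood and 6.5 L/min of cardiac output for males, 3.9 L and 5.9 L/min for
females. Per-compartment fractions are read from a user-replaceable CSV
(`inst/extdata/icrp89_compartments.csv`) covering the compartments used in
head-and-neck blood-dose estimation (aorta, large arteries, large veins,
superior vena cava, lungs, brain, bone, bronchi, fat, lymph nodes, skeletal
muscle, skin, stomach, esophagus, thyroid, and a residual body). The
`residual_body` row absorbs whatever fraction the named compartments do not
claim, so both conservation sums close exactly:

```{r}
library(circdose)
m <- circulation_model("male")
c(sum(m$compartments$blood_volume), sum(m$compartments$blood_flow))
validate_circulation(m)
```

Two caveats on the shipped table. First, volume fractions follow the
reference regional blood-volume distribution, but pure vascular conduits
(aorta, large arteries and veins, vena cava) physically carry the entire
cardiac output in series; a parallel model cannot represent that while
conserving $\sum Q_o = Q_{\mathrm{total}}$, so conduits are given effective
perfusion fractions and their transit times are correspondingly longer than
physical. This does not affect stationary occupancy (which depends only on
$V_o$) and therefore leaves expected blood doses unchanged; it does damp
fast vascular mixing transients. Second, every numeric test in the package
uses small toy tables, so no correctness claim rests on this transcription.
The model deliberately excludes pediatric or height/weight-scaled blood
volumes and any tumor-specific or pulsatile hemodynamics.

## Dose accumulation

Beam delivery is described by a `beam_schedule`: fields delivered
back-to-back (a configurable inter-field gap defaults to 0 s) starting at
the beginning of each fraction, with per-field beam-on times of 40 s
(photon IMRT, nine fields) or 30 s (proton IMPT, four fields) and 33
fractions by default.

When a particle starts in or enters compartment $o$ during a delivery, it
draws a dose $D$ from the organ's cumulative DVH by inverse-CDF sampling
(`u ~ U(0,1)` mapped through the DVH quantile; blood is assumed uniformly
mixed within the organ volume, and each visit redraws independently, so no
intra-organ dose-position correlation persists across visits). The draw is
converted to a dose rate $D/T$ with $T$ the fraction's total beam-on time,
and the particle accrues rate times the overlap of its residence with the
beam-on windows. Plans report course doses, so each fraction uses the
course DVH with its dose axis divided by the fraction count. Because the
expected resident time in $o$ during a window of length $T$ is
$T\,V_o/V_{\mathrm{total}}$ at stationarity, the expected blood dose per
fraction is $\sum_o (V_o/V_{\mathrm{total}})\,\bar D_o$ — a closed form the
test suite checks against the engine.

The engine is event-driven: residences are consumed in continuous seconds,
which is equivalent to the nominal 0.05 s grid stepping with fractional
remainders carried (the grid introduces no bias for either residence
model); `step_particles()` exposes the per-step view for transient
analyses, and a discrete-time Markov-chain oracle in the tests confirms the
two views agree on a grid-aligned toy model.

Fractions are accumulated with inter-fraction mixing by default
(`fraction_mode = "resample"`): each of the 33 fractions re-randomizes
particle positions, so the course dose is a sum of independent
single-fraction doses. `"scale_single"` simulates one fraction and
multiplies by the fraction count — identical in expectation, but with a
dispersion inflated by the fraction count, so it is only a fast
approximation of the mean. The default particle count is $10^6$; the
package's own tests and the study pipeline run at $10^3$–$10^5$ with
tolerances widened to the corresponding Monte-Carlo error, which keeps the
full test suite under a minute and a 120-plan study under two minutes on
one CPU.

```{r}
model <- toy <- custom_circulation_model(c("vessels", "rest"),
                                         blood_volume = c(1000, 4300),
                                         blood_flow = c(2000, 4500))
dvhs <- list(vessels = delta_dvh(20), rest = delta_dvh(1))
r <- simulate_blood_dose(toy, dvhs, beam_schedule("IMPT"),
                         n_particles = 5000, seed = 1)
summary(r)
```

## DVH representation and metrics

Cumulative DVHs live on a uniform dose grid starting at 0 Gy with
non-increasing volume fractions (1 at 0 Gy). The default bin is 0.01 Gy —
one percent of the smallest blood mean doses of interest — and is
configurable per object. D$n$% is the minimum dose received by the
most-irradiated $n\%$ of the volume, computed by linear interpolation; on a
gridded step DVH this is exact to within one bin, and an exact flat run at
the query level resolves to its lower-dose end (the leading plateau at 1
keeps its upper end so that a uniform-dose DVH returns its dose for every
$n$, including $n = 100$). V$x$Gy is the interpolated volume fraction at
$x$ Gy. The mean dose is the trapezoidal area under the curve, and the
plan-quality indices are the homogeneity index HI = D5%/D95% and the
conformity index CI = 100 × (volume inside the 95% isodose)/(PTV volume),
reported in percent. All metrics are checked against fine-grid brute-force
oracles and are stable to better than 0.5% under grid refinement.

## The synthetic cohort

Real treatment plans live in commercial planning systems; what is
observable about them at the DVH level is what the generator emulates. A
cohort (default 20 patients, 15 male / 5 female) carries six plan
conditions per patient: two modalities (IMRT, IMPT) crossed with three
vessel constraint levels (conventional, vessel mean dose constrained to
90% and to 80% of the conventional plan's value). Prescriptions are 60 Gy
(PTV1) and 52 Gy (PTV2) in 33 fractions.

Per patient, course-level organ mean doses are drawn from organ-class
lognormal priors (vessels and neck structures high, distal organs low) and
expanded into sigmoid survival curves whose dose axis is scaled so the
trapezoid mean matches the draw exactly. The priors are free parameters
chosen once, through the closed-form blood-mean identity above, so that
non-outlier blood mean doses land in the 1–2 Gy range typical of
head-and-neck plans; they are inputs of the emulation, not claims about any
specific planning system. On top of this baseline:

* **IMPT low-dose bath.** Proton conditions scale the out-of-field organ
  classes (muscle, bone, skin, fat, lungs, stomach, bronchi, brain,
  residual body) by `impt_low_dose_factor` (default 0.55), emulating the
  suppressed low-dose bath; target-adjacent structures are untouched.
* **Vessel sparing.** BVS conditions scale the large-artery and large-vein
  DVH dose axes so the vessel mean-dose ratio to the same patient's
  conventional plan equals the configured scaling exactly (0.9 / 0.8).
* **Redistribution.** Vessel-sparing plans nudge the brain DVH up by 1–3%
  and the esophagus mean dose down by 5–10% (both configurable to zero),
  mirroring the localized cost and the concurrent benefit of steering dose
  off the cervical vessels.
* **Overlap outlier.** One patient (the last) has vessels overlapping the
  target: vessel mean doses near the prescription scale and sparing capped
  at 0.995/0.99, so the vessel dose changes by under 2% across levels and
  the blood mean dose sits several-fold above the cohort median.

PTV DVHs are piecewise-linear survival curves through engineered anchors
meeting the coverage bands D0.1% < 1.01 × prescription and
D98% > 0.99 × prescription. Jointly with an HI envelope of 1.02–1.10 these
bands are almost contradictory — they force HI into [1.02, 1.0202) — so PTV
curves use a fine 5 × 10⁻⁴ Gy bin and all synthetic plans sit at the lower
edge of the envelope, with only small jitter between conditions.
Conformity indices are drawn per patient/modality in 97–99.4% and decrease
mildly with tighter vessel constraints, staying above 96%.

What passing tests on this cohort do show: the pipeline reproduces the
expected orderings (BVS-80% < BVS-90% < conventional within each modality,
proton below photon at every level), vessel-scaling fidelity, and the
outlier phenomenology, all under seeded reproducibility. What they cannot
show: agreement with any specific planning system's absolute organ doses,
anatomy-driven correlations between organs, or intra-structure dose
heterogeneity beyond the assumed sigmoid shape.

## Statistics

The inference layer mirrors the paired design: a Friedman test across the
three constraint levels within each modality, followed — only when the
Friedman test is significant at 0.05, unless forced — by pairwise Wilcoxon
signed-rank tests with Bonferroni correction over the three-comparison
family. The Friedman statistic is the classical average-rank chi-square
form (well-defined even when all rows are tied, where the tie-corrected
variant degenerates); a permutation method (exhaustive up to $(k!)^n$ =
250 000 arrangements, Monte Carlo beyond) is available for small samples
where the chi-square reference is coarse. Wilcoxon drops zero differences
(flagged; all-zero input returns p = 1 by documented convention) and uses
the exact distribution for up to 25 tie-free pairs, the tie-corrected
normal approximation otherwise. The modality contrast (IMRT vs IMPT) is
reported descriptively as medians plus the mean per-patient percent
reduction, with an optional paired Wilcoxon. Reduction summaries report
median (range) of the raw metric and the mean per-patient percent
reduction against the conventional baseline, excluding (with a warning)
patients with a zero baseline.

## Reproducibility and numerical choices

* One master seed drives cohort generation and every simulation in
  `run_study()`; reruns are byte-identical, and the output bundle includes
  a JSON manifest with the seed, settings and MD5 checksums of every file.
* Blood DVHs are empirical survival functions on a 0.01 Gy grid; Dmean is
  taken directly from the per-particle doses (exact), quantile metrics
  from the gridded DVH (exact to within a bin).
* Inverse-CDF tables are precomputed per organ; the engine's uniform draws
  are consumed in a fixed order, so plans differing only in DVH values
  share routing and sampling randomness — which is also what makes the
  stochastic-dominance monotonicity property testable with common random
  numbers.
* Degenerate inputs are rejected early with named errors: DVH invariant
  violations cite file rows, missing in-field DVHs name the compartment,
  corrupted cohort files name the patient and condition.

## Worked study run

```{r, eval = FALSE}
st <- run_study(study_config(n_patients = 20, seed = 1, n_particles = 1e4),
                out_dir = "results")
print(st)
st$tables$blood[st$tables$blood$metric == "Dmean", ]
```

A 20-patient, $10^4$-particle study (120 simulated plans) completes in
about 80 s on one CPU. The `scripts/acceptance.R` entry point runs exactly
this study and writes the headline quantities (cohort medians, percent
reductions, outlier ratios, HI/CI medians) as JSON.

## Known limitations

* No voxel-level dose lookup: organ DVHs are the finest spatial
  information, and blood is assumed well mixed within each organ.
* No cell-survival or lymphocyte-kinetics model: outputs are physical
  doses to blood, not toxicity predictions.
* The parallel circulation topology under-resolves conduit transit
  dynamics (see above) and ignores tumor vasculature.
* Synthetic plans are DVH-level emulations; the optimizer itself, monitor
  units and delivery complexity are out of scope (the statistics layer can
  consume externally supplied monitor-unit tables as plain paired
  matrices).
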