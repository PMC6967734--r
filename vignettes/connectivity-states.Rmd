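---
title: "Dynamic cortical connectivity states: methods and design"
author: "conndyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic cortical connectivity states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(conndyn)
```

## The problem

During surgical anesthesia, cortical functional connectivity is not a fixed
property of a brain but a trajectory: phase-coupled oscillations between
prefrontal, frontal, and parietal regions appear, dissolve, and reorganize
on a time scale of tens of seconds. `conndyn` implements a complete
pipeline for quantifying those dynamics from multichannel scalp EEG
recorded during the anesthetic-maintenance phase: a phase-synchronization
spectrum per sliding window, a data-driven taxonomy of recurring
connectivity *states*, Markov-style summaries of how subjects move between
states, and a statistics layer relating those summaries to age and
anesthetic covariates.

Because real operating-room recordings cannot be redistributed, the package
carries a synthetic-cohort generator that plants known states and known
age effects, giving every downstream stage a ground truth to be validated
against.

## Connectivity measure

The core measure is the weighted phase lag index (wPLI). For two signals
with cross-spectral density estimates $S_{xy,j}(f)$ over estimates $j$,

$$\mathrm{wPLI}(f) = \frac{\left|\sum_j \mathrm{Im}\, S_{xy,j}(f)\right|}
                          {\sum_j \left|\mathrm{Im}\, S_{xy,j}(f)\right|}.$$

Only the imaginary part of the cross-spectrum enters, so any zero-lag
(volume-conducted) component — which contributes a purely real term — is
ignored; wPLI approaches 1 when one signal consistently leads or lags the
other and 0 when phase relations are random.

Estimates are formed on a fixed grid: the maintenance epoch is cut into
30-s windows advanced by 10 s; each window is cut into 2-s sub-windows
with 50% overlap (29 per window); each sub-window is tapered with 3 DPSS
tapers (time–bandwidth product 2). Sub-windows and tapers are pooled as
87 i.i.d. estimates per window. Spectra are evaluated by zero-padded FFT
(next power of two above the sub-window length) with nearest-bin lookup
onto the 0.5–35 Hz grid at 0.5 Hz steps — 70 bins. The DPSS tapers are
computed from the standard symmetric tridiagonal eigenproblem and verified
against an independent reference implementation in the test suite.

The raw wPLI of a finite estimate set is biased upward (for 87 estimates
of pure noise the expected value is roughly $0.09$). The bias is estimated
by trial shuffling: channel *y*'s sub-windows are rotated against channel
*x*'s by a cyclic shift of at least 2 (a guaranteed derangement), wPLI is
recomputed on the mispaired estimates, and the mean over 20 seeded shifts
is subtracted from the raw value. Corrected values may be slightly
negative; they are deliberately *not* clipped at zero, because clipping
would bias cluster centroids near the origin. When every imaginary part is
exactly zero (identical signals), wPLI is defined as 0 — "no detectable
lagged interaction" is the conservative reading of a degenerate ratio.

Per window, corrected wPLI spectra are averaged over the 6
prefrontal–frontal channel pairs ({Fp1, Fp2} × {F5, F6, Fz}) and the 9
frontal–parietal pairs ({F5, F6, Fz} × {P5, P6, Pz}), giving the
140-element feature (70 bins × 2 region pairs) used everywhere downstream.
The montage order (Fp1, Fp2, F5, F6, Fz, P5, P6, Pz) is fixed and all
indexing relies on it. No re-referencing or filtering is applied before
spectral estimation: wPLI is insensitive to the reference montage, and
the pipeline deliberately adds no preprocessing the measure does not need.

## State discovery

Features from all subjects are pooled (the state taxonomy is a group-level
object), centered, and projected onto the top 5 principal components; the
projected features are clustered by k-means with squared Euclidean
distance and 100 seeded restarts, keeping the best within-cluster sum of
squares. Windows under an optional burst-suppression mask are excluded
from fitting and labelled `suppressed` in the output sequences; the
package does not include a suppression detector — the mask is an input.

Cluster centroids are named by back-projecting them to the 140-bin space:
the region pair with the greater mean fixes the region, the band of the
spectral peak fixes the name (delta 0.5–4, theta 4–8, alpha 8–13, beta
13–30 Hz): prefrontal–frontal delta is S3, alpha S2, beta S1;
frontal–parietal theta is S4, alpha S5. When two same-region centroids
claim one name, they are ordered by the spectral centroid of their
dominant half and the higher-frequency centroid takes the
higher-frequency name; the peak of a plateau-shaped spectrum is noisy,
while the spectral centroid orders a broad alpha–beta profile above a
narrow alpha profile reliably. An all-zero centroid is labelled
`unnamed` rather than guessed at.

### Choosing the number of states

The cluster count is selected with a split-half stability index: cluster
one half, transfer its labels to the other half by nearest centroid,
cluster that half independently, and compare the two labelings under the
best of the $k!$ label matchings. Two design choices matter here, both
validated against planted ground truth:

* **Worst-cluster aggregation.** The disagreement score for a split is the
  largest per-cluster disagreement, not the average over windows. A
  solution only counts as reproducible when *every* cluster reproduces.
  With averaged disagreement the profile is uninformative on the left:
  merging two well-separated states is exactly as reproducible as keeping
  them apart (the closest pair merges deterministically in both halves),
  so k = 3, 4, 5 all sit at zero and the minimum is noise. The
  worst-cluster score leaves coarsenings stable but jumps by an order of
  magnitude at the first k that forces an arbitrary split of a real
  state.
* **Largest-stable-k selection.** Scores are normalized by the chance
  disagreement of random labelings (1 − 1/k), and the selected k is the
  largest member of the contiguous stable run (normalized instability
  ≤ 0.25, i.e. at least three quarters of every cluster's members keep
  their matched label) containing the instability minimum. Isolated
  stable points at larger k are ignored: window features that mix two
  states (a window straddling a state switch) form low-density ridges on
  which extra clusters occasionally stabilize without being part of the
  nested family.

On synthetic cohorts this rule selects k = 5 with a wide margin (the
stable run is {3, 4, 5} or {2, …, 5} at instability below 0.05; k = 6–8
score 0.3–1.1), and the fitted labels match the hidden states with
adjusted Rand index above 0.9.

## State dynamics

Per subject, three summaries are computed from the window label sequence:

* **Occurrence rate** — the fraction of windows spent in each state
  (unobserved states report 0; suppressed windows count toward time).
* **Transition matrix** — conditional next-window frequencies, including
  self-transitions; rows without outgoing observations are NA and flagged
  rather than silently renormalized.
* **Global transition probability** — distinct-state switches divided by
  the sequence length, i.e. a per-10-s-step switching rate; a constant
  sequence scores 0. The alternative denominator (length − 1) is exposed
  as an option.

Suppressed windows never contribute transitions: a pair straddling a
suppressed window is dropped (the Markov assumption concerns consecutive
observations), but suppressed time stays in the occurrence and global-rate
denominators.

## Statistics layer

Associations with age follow a normality-routed scheme: Shapiro–Wilk at
0.05 on each variable; Spearman if either rejects, else Pearson; two-sided
p-values throughout. The four occurrence-rate tests (S1, S2, S4, S5 —
the delta state S3 is not part of the association analysis) share a
Bonferroni-adjusted alpha of 0.05/4 = 0.0125. Bonferroni-significant
occurrence rates are followed by ordinary least squares of the z-scored
outcome on z-scored age plus covariates — the age-adjusted MAC multiple
for all states and additionally the nitrous-oxide flag for S1 (nitrous
specifically perturbs beta-band oscillations). Standardized coefficients
are reported because occurrence rates live in [0, 1], where per-year raw
slopes are uninformative. The 16 transition-matrix cells are tested as a
family under Benjamini–Hochberg at q = 0.20, with subjects missing a cell
(no outgoing observations) dropped pairwise.

Anesthetic depth is the age-adjusted MAC multiple
$\sum_a F_a / (\mathrm{MAC40}_a \cdot 10^{-0.00269\,(\text{age}-40)})$,
additive across agents including nitrous. The MAC40 reference
concentrations (isoflurane 1.17, sevoflurane 1.80, desflurane 6.6, nitrous
104 vol%) ship as an editable table in `extdata/mac40.csv` — they are
clinical reference constants, not package truths.

## The synthetic cohort

The generator emulates the structure the pipeline is built to detect, not
the biophysics of EEG:

* **Background**: independent per-channel noise with a $1/f^2$ spectrum
  (spectrally colored white noise, unit variance), the simplest EEG-like
  background.
* **States**: each hidden state injects one shared band-limited Gaussian
  source into its leading channel group and a copy phase-shifted by π/2
  into its lagging group — π/2 maximizes the imaginary cross-spectrum,
  the regime wPLI detects. The default taxonomy mirrors the naming table:
  S1 Fp–F 8–20 Hz, S2 Fp–F 8–12, S3 Fp–F 0.5–4, S4 F–P 4–8, S5 F–P 4–12.
  The source amplitude is set so shared in-band power is `coupling_snr`
  (default 1.5) times the background's in-band power — moderate coupling,
  comfortably above the regime where recovery starts to degrade.
* **Dynamics**: hidden states follow a sticky Markov chain (default
  self-transition 0.8 per dwell step) switching on a 30-s grid, a
  multiple of the 10-s analysis step so switches align with window
  starts. Mean dwell is then 150 s, so roughly one window in seven mixes
  two states.
* **Age effect**: age tilts the chain's stationary distribution through a
  softmax over per-state log-odds (defaults: S1 −0.5 and S4 +0.4 per
  decade, matching the direction of the planted findings; others 0), and
  the chain is rebuilt as the reversible resampling chain
  $(1-d)I + d\,\mathbf{1}\pi^\top$ with the base chain's dwell parameter
  $d$, keeping rows stochastic and dwell times unchanged.
* **Cohort**: defaults are 45 subjects, ages uniform on 18–80, 20-minute
  epochs at 250 Hz. Nitrous use and the MAC multiple are drawn
  independently of age, so they are non-confounding unless configured
  otherwise; each subject's end-tidal sevoflurane fraction is derived
  from the drawn MAC multiple so the metadata are self-consistent.
* A **zero-lag confound** toggle adds an identical in-phase signal to all
  channels for volume-conduction robustness experiments.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: eye/muscle/electrode artifacts, burst
suppression waveforms, non-stationary drug levels within an epoch,
realistic volume conduction (a full leadfield), inter-subject variability
in spectra beyond the planted age effect, and any correlation structure
between covariates and age.

## Numerical choices and degenerate inputs

* FFT length: next power of two above the sub-window length; the grid is
  mapped by nearest bin (the 70 grid frequencies map to distinct bins at
  both 250 and 500 Hz).
* wPLI 0/0 convention: 0.
* Surrogates: 20 cyclic shifts drawn without replacement from
  {2, …, n−2}, seeded; shifts of ±1 are excluded because half-overlapping
  neighbors are correlated.
* k-means: `stats::kmeans` (Hartigan–Wong) with seeded restarts; its
  built-in empty-cluster handling keeps k fixed.
* Assignment ties break to the lowest cluster index; stability matching
  enumerates all k! permutations (k ≤ 8).
* Resampling: zero-phase FIR (forward–backward) after zero-stuffing;
  upsampling is refused, irrational ratios are refused.
* Epochs shorter than one 30-s window, constant statistical variables,
  rank-deficient designs, unknown anesthetic agents, and transition rows
  with no outgoing observations all raise typed errors or explicit NA
  flags rather than silent defaults; in the cohort statistics a
  degenerate variable produces an NA row so one empty state cannot void a
  report.

## Problem sizes used by the tests

The validation experiments run at deliberately reduced scale, chosen as
the package's own test-design points: the model-selection and
label-recovery experiment uses 14 subjects × 480 s (≈ 644 windows —
small enough to run in minutes, large enough that every planted state is
well represented under the age tilt); analytic wPLI checks use 300 s of
signal (28 windows); statistical calibrations run on chain-level cohorts
(occupancy read directly off the hidden sequences) with 45 subjects and
200 replicates, since they exercise the statistics layer, not the signal
path.

## Known limitations

* Trial-shuffled surrogate correction slightly *overcorrects* at the
  frequency of a strong common component whose phase drifts: mispaired
  sub-windows see a nonzero imaginary cross-term the aligned pairs do not
  have, producing a small negative dip in corrected wPLI there. Raw wPLI
  is unaffected; the zero-lag robustness guarantee is stated for
  constant-phase common signals and pooled (window-averaged) spectra.
* The stability profile is flat to the left of the true k: coarser
  merges of well-separated states are genuinely reproducible, so the
  index cannot penalize under-clustering; the selection rule compensates
  by taking the largest stable k, which in turn assumes the candidate
  range extends past the true granularity.
* The end of the maintenance epoch is an explicit event label; the
  anesthetic-record criterion used clinically (a MAC threshold late in
  the case) requires drug-record data the package does not model.
* Occurrence rates are compositional (they sum to 1); the statistics
  layer tests them marginally, as in the original analysis scheme, and
  inherits that scheme's interpretive caveats.
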