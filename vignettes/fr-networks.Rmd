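---
title: "Fast-ripple networks and surgical-outcome classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fast-ripple networks and surgical-outcome classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frnet)
```

## The problem

Inter-ictal fast ripples (FR; high-frequency oscillations at 250--600 Hz)
recorded on intracranial EEG mark epileptogenic tissue. In patients whose
seizures persist after resective surgery, FR-generating sites tend to lie
outside the clinically defined seizure onset zone (SOZ) and to be spatially
widespread. `frnet` quantifies this with three per-patient network families
built over stereo-EEG contacts, summarizes them with weighted graph
measures, and classifies prospective surgical non-responders from those
measures with a support-vector machine.

Patient iEEG event catalogs of this kind are not publicly deposited, so the
package ships a synthetic cohort generator whose two phenotypes emulate the
responder and non-responder patterns; every downstream stage is exercised
and tested against it.

## Networks

All networks share one node set convention: a contact is a node if it
recorded at least one event passing the active filter. The default filter
keeps fast ripples (`fRonO` and `fRonS` combined) with peak spectral
frequency strictly above 350 Hz; an event at exactly 350.0 Hz is excluded.

* **Distance network** --- complete graph, edge weight the Euclidean
  distance (mm) between contacts in normalized MNI space.
* **Rate--distance network** --- edge weight `d_ij * (r_i + r_j) / 2`,
  the distance multiplied by the mean filtered-event rate (events/min) of
  the two contacts. Computed over all FR-generating contacts and, in a
  second variant, over non-SOZ contacts only.
* **MI network** --- edge weight the mutual information (bits) between the
  two contacts' event onset trains. Only contacts with at least
  `min_events_per_contact` (default 5) filtered events are eligible;
  patients with fewer than two eligible contacts have no constructible MI
  network, and downstream measures carry missing-value markers.

## The MI estimator

The estimator is the package's own definition, isolated behind
`estimate_mi()` so an alternative can be swapped in. The recording is
partitioned into contiguous, **equal-width** cells whose width is
`target_events_per_cell` times the mean pooled inter-spike interval of the
two trains, with the grid anchored at the first pooled event and truncated
at the last. Per-cell event counts of the two trains, capped at
`count_cap`, form a paired categorical sample; the plug-in mutual
information of that sample, in bits (log2), is returned.

Three design points deserve explanation:

* *Equal widths.* Cells with data-dependent variable widths make both
  trains' counts covary with the local width, which registers as spurious
  mutual information between independent trains. An early variant of this
  estimator that merged inter-event cells until each held a fixed pooled
  count suffered exactly this defect (the pooled count per cell was then
  deterministic, making the two counts perfectly anti-dependent); the
  equal-width grid removes it. Adaptivity survives in the width itself,
  which scales inversely with the pair's pooled event density.
* *Anchoring.* Tying the grid to the first pooled event, not to time zero,
  makes the estimate exactly invariant to a common time shift of both
  trains, and exactly symmetric in its arguments.
* *Capping and defaults.* The plug-in bias grows with the joint alphabet
  and shrinks with the number of cells. With `target_events_per_cell = 1`
  (cells at the mean-ISI scale, acting as coincidence detectors) and
  `count_cap = 2`, independent Poisson trains at 0.5/s over 1200 s measure
  ~0.002 bits, while common-input coupling by mother-process thinning at
  probabilities 0.25/0.5/0.75 measures ~0.04/0.17/0.47 bits --- a steep,
  monotone response. These defaults are fixed; both knobs are exposed in
  `mi_config()`.

Trains shorter than `min_events_per_contact` return `NA` ("not estimable"),
deliberately distinct from an estimated zero.

## Graph measures

Edge weights convert to path lengths by network kind: distance-type weights
are lengths already; MI weights are affinities, so length is the
reciprocal weight (zero weight = no edge), the standard conversion for
correlational networks. On top of the shortest-path metric
(`net_shortest_paths()`, Dijkstra via igraph; per-neighbourhood
subproblems use an internal vectorized Floyd--Warshall):

* **Radius** --- minimum over nodes of the eccentricity (maximum
  shortest-path length). Conventions: empty or single-node networks have
  radius 0, so a patient with no fast ripples above threshold contributes
  the minimal network extent rather than a missing value; disconnected
  networks are measured on the largest connected component. A
  direct-adjacency variant (eccentricities over raw edge weights) is
  exposed via `radius_definition = "adjacency"`; for Euclidean distance
  networks the two coincide, for rate--distance networks they need not.
* **Characteristic path length** --- mean of the finite off-diagonal
  shortest-path lengths (infinite pairs excluded); undefined (`NA`) below
  two nodes.
* **Local efficiency** --- the weighted (cube-root) formulation: for node
  i with neighbours N(i), the mean over ordered neighbour pairs of
  `(w_ij * w_ih / d_jh(N_i))^(1/3)`, where `d_jh(N_i)` is the shortest
  path inside the neighbour subgraph; nodes with fewer than two
  neighbours score 0.
* **Nodal strength** --- the sum of incident edge weights.

The per-patient feature vector (`global_measures()`) is: SOZ distance-network
radius; FR distance-network radius; FR rate--distance radius (all nodes and
non-SOZ only); and three MI-network global measures --- characteristic path
length, mean local efficiency of the non-SOZ nodes, and the difference in
summed nodal strength of non-SOZ versus SOZ nodes. The strength difference
is unnormalized by default; a per-node-normalized variant is exposed
(`normalize_strength_diff`). When an MI network contains no non-SOZ node,
the non-SOZ mean local efficiency is defined as 0 and the strength
difference reduces to minus the summed SOZ strength; this keeps responder
feature vectors finite, which matters because a compact SOZ-concentrated FR
network *is* the responder signature, not a missing observation.

## Statistics

* ROC curves by threshold sweep; the trapezoid AUC equals the
  Mann--Whitney statistic (ties one half) and is property-tested against
  exhaustive pair enumeration to 1e-12. Confidence intervals by
  percentile bootstrap (default 1000 replicates) with resampling
  stratified by class, which also guarantees both classes in every
  replicate; paired-bootstrap two-sided tests for AUC differences.
* Event spectral features are modelled on the natural-log scale with a
  Gaussian linear mixed model: `log(y) ~ soz + location + (1 | patient)`
  (lme4, Wald 95% CIs). Intercepts near 5.5 log-Hz correspond to the
  250--600 Hz FR band. The anatomical location enters as a numeric code
  from a fixed region table (`region_codes()`) that ships with the package
  and can be replaced; singular random-effect fits fall back to OLS with a
  warning.
* Wilcoxon rank-sum tests with Bonferroni--Holm step-down correction;
  PCA of the three MI measures on standardized columns with a
  deterministic sign convention (largest-magnitude loading positive);
  exact Clopper--Pearson binomial CIs for classifier metrics.

## Classifier

An RBF-kernel SVM (e1071/libsvm) predicts the non-responder class from the
six features. "Automatically scaled" is operationalized as the median
heuristic: the kernel bandwidth is the median pairwise Euclidean distance
between z-scored training rows. Because raw SVM margins have no
probability scale, a Platt sigmoid is fitted to the training decision
values so that a 0.5 probability threshold is meaningful. Two
training profiles are provided: `svm1` trains on all patients,
`svm2` excludes patients treated with responsive neurostimulation alone
(who count as non-responders a priori at evaluation). Standardization,
bandwidth, Platt calibration, and imputation statistics are all computed
from training rows only, and the training manifest records the ids so this
can be audited. Missing MI features are median-imputed from training data
by default (sentinel imputation is the alternative; neither is claimed to
be canonical); if a feature column is
missing for every training patient, the pipeline falls back to the
sentinel so that classification degrades gracefully to the radius
features.

## The synthetic cohort generator

Each patient gets 8--16 linear depth electrodes with 7--15 contacts at
5 mm spacing inside a ±70 mm MNI bounding box, one anatomical region per
electrode. Event trains are coupled Poisson processes: an independent
background at the contact's base rate plus events copied from latent
"mother" Poisson processes by independent thinning with Gaussian timing
jitter (the common-input construction, chosen because it gives
analytically controllable dependence: the expected contact rate is
`base_rate + thinning_prob * mother_rate`). Peak spectral frequency is
log-normal with a per-patient random intercept, truncated by rejection to
the 250--600 Hz FR detector band.

The two phenotypes:

| parameter | responder | non-responder |
|---|---|---|
| SOZ layout | clustered on 1--2 electrodes | spread over >= 3 electrodes |
| base FR rate, SOZ / non-SOZ (events/min) | 1.5 / 0.2 | 0.8 / 0.8 |
| log-frequency intercept (log-Hz) | 5.470 | 5.646 |
| SOZ log-frequency shift (log-Hz) | +0.178 | -0.352 |
| coupling graph | one hub mother, SOZ-coupled (0.4 / 0.05) | 3 decentralized mothers, non-SOZ-coupled (0.1 / 0.3) |

The log-frequency intercepts and SOZ shifts are the fitted mixed-model
values for fRonO frequency in the two outcome groups; the rates are
calibration choices, as
are the coupling probabilities, the 10 ms jitter, the residual SD of 0.15
log-Hz (chosen so the +-0.18--0.35 shifts yield clear ROC separability),
the 0.05 log-Hz patient-intercept SD, the 15% fRonS fraction, the 0.1 SOZ
fraction, and the 60 min default recording. The default implant (8
electrodes x 7 contacts) sits at the low end of the clinical range; all
values are `phenotype_params()` fields.

What the generator does *not* emulate: raw voltage, seizures, detector
false positives, montage effects, anatomically realistic trajectories, or
rate nonstationarity across sleep stages. Tests passing on this cohort
therefore demonstrate correctness and discriminative power of the
*pipeline* under the modelled effect structure, not expected performance
on clinical recordings. One visible consequence: with the fitted
non-responder frequency shift, synthetic non-responder SOZ contacts
produce almost no FR above 350 Hz, so their SOZ-classification AUC falls
far below 0.5 --- a more extreme anti-concordance than real cohorts show.

## Numerical and procedural choices

* Frequency threshold is strict (> 350 Hz); time is seconds from
  recording start, durations in minutes, rates per minute.
* Parameter-recovery analyses of the mixed model generate with the
  frequency band lifted (`freq_band = NULL`): band truncation censors the
  Gaussian response and attenuates the SOZ coefficient (for the responder
  parameters the non-SOZ mean, exp(5.470) = 237 Hz, lies below the 250 Hz
  band edge, so censoring is severe). With censoring off, the fitted SOZ
  coefficient recovers the generating value within +-0.03 log-Hz at
  20,000+ events; with the default band on, recovered shifts are
  attenuated --- a detector-physics effect, not an estimator defect.
* `no_resection_rns` outcomes are kept distinct in the data model but map
  to the non-responder class for binary classification.
* Analysis problem sizes: graph oracles on 200 random graphs of <= 10
  nodes; MI properties at 0.5/s over 1200 s with 100 replicates;
  mixed-model recovery at 20,000+ events with 100-replicate null
  coverage; bootstrap calibration over 200 outer replicates; end-to-end
  discrimination over 50 seeded cohorts of 35 patients (22 train / 13
  test).
* Every stochastic stage takes an explicit integer seed; per-patient
  child seeds derive from the cohort seed, so any run is a pure function
  of (config, inputs) and reruns are byte-identical.

## Known limitations

The MI estimator's cell partition and per-cell statistic are package
definitions; other per-cell statistics (binary presence, ISI values) are
plausible alternatives and can be substituted behind the `estimate_mi()`
interface. Estimates at very low event counts (near the 5-event
eligibility floor) are coarse. Radius conventions for disconnected and degenerate networks are
package definitions as well. The classifier is evaluated on synthetic
phenotypes whose separation is, by construction, cleaner than clinical
data; no claim about prospective clinical accuracy is implied.
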