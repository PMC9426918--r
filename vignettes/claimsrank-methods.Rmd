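---
title: "Methods: bipartite centrality and overdose hazard models on claims networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite centrality and overdose hazard models on claims networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claimsrank)
```

## Overview

`claimsrank` studies how well different node-ranking algorithms on a
patient-provider prescription network identify patients whose prescribing
pattern looks like drug-seeking, using subsequent opioid overdose as the
validating outcome. The pipeline is: simulate (or read) longitudinal
claims, build rolling-window bipartite networks, score patients with five
centrality indices, assemble a lagged patient-quarter panel, fit one Cox
proportional-hazards model per index, and compare the models by AIC.

This vignette records the modelling assumptions, the defaults and why they
were chosen, the numerical edge cases, and what the synthetic experiments
do and do not demonstrate.

## The ranking family

All bipartite indices here are damped fixed points of

$$p = \alpha S_p d + (1-\alpha) p^0, \qquad
  d = \beta  S_d p + (1-\beta)  d^0,$$

where $W$ is the provider$\times$patient weight matrix and the transition
pair $(S_p, S_d)$ is an algorithm-specific normalization of $W$ built from
the generalized degree matrices $K_d = \mathrm{diag}(W\mathbf{1})$ and
$K_p = \mathrm{diag}(W^{\mathsf T}\mathbf{1})$: none for HITS, source
out-degree for CoHITS ($W^{\mathsf T}K_d^{-1}$, a random walk), full
symmetric for BGRM, and square-root symmetric for BiRank. PageRank on the
one-mode patient projection (ties weighted by the number of distinct shared
providers) is the conventional baseline.

Decisions worth recording:

* **Orientation.** Rows of $W$ are providers, columns patients; $K_d$ holds
  provider row sums and $K_p$ patient column sums. All formulas are
  implemented in this one orientation to avoid the index ambiguity that
  plagues transposed presentations of this family.
* **HITS.** Classic, undamped ($\alpha=\beta=1$), with both score vectors
  renormalized to unit sum after every iteration — this is the member of
  the family that matches eigenvector-style ranking. Damping is accepted
  but non-default.
* **Damping.** 0.85 on both modes for CoHITS/BGRM/BiRank and for PageRank,
  the customary value for teleporting walks.
* **Zero degrees.** The inverse of a zero generalized degree is defined as
  0: degenerate nodes pass no walk mass and end up with teleportation mass
  only. This also fixes the PageRank contract for isolated patients: their
  score is exactly $(1-\alpha)/N$, and consequently scores sum to exactly 1
  only when the projection has no isolated nodes (no dangling-mass
  redistribution is performed).
* **Convergence.** Declared on the L1 change of the patient vector
  (default tolerance `1e-10`, cap 1000 iterations); both vectors are
  returned with the iteration count and final residual. Hitting the cap
  warns and flags `converged = FALSE` rather than failing.
* **BGRM stability.** BGRM's double normalization $K_d^{-1}WK_p^{-1}$ is
  substochastic only when every generalized degree is at least 1. With
  weights on the MME scale (tens to thousands) this always holds; with
  artificial sub-unit weights the undamped part of the iteration can
  diverge, which the solver detects (non-finite residual) and reports
  instead of looping. BGRM is also the one scheme that is *not* invariant
  to a global rescaling of $W$, because the degree enters twice per edge.
* **Oracle.** For damping below 1 the fixed point solves
  $(I - \alpha\beta S_pS_d)p = \alpha(1-\beta)S_p d^0 + (1-\alpha)p^0$
  exactly; `closed_form_rank()` implements this direct solve and the test
  suite requires iterative/closed-form agreement to $10^{-8}$ on random
  instances. The undamped case is excluded (singular limit).

## Networks and covariates

Ties are "at least one prescription from provider $i$ to patient $j$ in the
window". The primary window is three quarters, the robustness variant one;
windows are inclusive quarter sets ending at the analysis quarter, and the
one-quarter edge set is always a subset of the three-quarter one. Repeated
prescriptions are not valued in the unweighted network; the MME-weighted
variant sums the total morphine milligram equivalents per (provider,
patient) pair, and has the same sparsity pattern as the unweighted network
by construction.

The patient projection weights pairs by the number of distinct shared
providers, with a zero diagonal. The covariate `transitive_ties` counts
*distinct* other patients reachable through a shared provider (the
provider-multiplicity variant is returned alongside but not used in
models): the distinct-alter reading matches "number of connections to other
patients", while repeated shared providers still carry weight inside the
projection itself.

Degree assortativity is the Pearson correlation, across edges, of the
binary degrees of the two endpoints; it is reported as `NA` with a warning
when either endpoint degree is constant (e.g. complete bipartite graphs).

## Survival modelling

The unit of analysis is the patient-quarter. A network ending at quarter
$q$ predicts the event indicator of quarter $q+1$ (one-quarter lag), so
each panel row is the counting-process interval $(q, q+1]$. Patients
contribute rows only while enrolled and only until their first event;
disenrollment censors by simply ending the row stream.

* **Centrality transform.** Scores are divided by the mean score of their
  network component (same mode), log-transformed, then z-scored over the
  pooled panel. Component-mean normalization puts disconnected components
  on a comparable scale before pooling; the log tames the right-skew; the
  z-score makes hazard ratios "per one standard deviation". Robustness
  variants: raw scores and an indicator of exceeding the pooled 99th
  percentile. Scores that are exactly zero (possible only for undamped
  HITS on disconnected graphs, where off-component mass underflows) are
  floored at the smallest positive score times $10^{-6}$, guarded by the
  smallest representable positive double.
* **Standardization of controls.** Age is z-scored; degree and transitive
  ties are z-scored on the log1p scale (right-skewed counts); binary flags
  stay 0/1. Z-scoring is pooled over all patient-quarters, not per
  quarter.
* **Ties.** Quarter-grained stop times produce heavy ties, so the Efron
  approximation is the default; Breslow is available by flag. The
  numerical maximization of the partial likelihood is delegated to
  `survival::coxph()`; the package owns the panel contract, the tie
  policy, and the AIC identity $\mathrm{AIC} = -2\log PL + 2k$, which the
  tests verify against a hand-written partial likelihood on tie-free toy
  data.
* **Comparison.** Models differ only by which single centrality column
  they add to the fixed control set (the measures are far too collinear to
  enter jointly). `delta_aic` is baseline minus model, and
  `exp(-delta/2)` is the relative likelihood of the baseline; a 25-unit
  gap maps to $e^{-12.5} < 0.001$. No multiplicity correction is applied —
  the comparison is by AIC, not by p-values.

## The synthetic claims generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is demonstrated.

**What it emulates.** A cohort (default 20,000 patients, 2,000 providers,
12 quarters) in which: (i) a small latent subpopulation (2%) seeks opioids
from many prescribers; (ii) mainstream patients hold 1–2 "home" providers
drawn by heavy-tailed provider volume (log-normal, $\sigma = 1.5$), which
concentrates single-provider patients on a few high-volume clinics; (iii)
seekers draw most prescriptions (95%) from a large pool (30% of the
roster) of *low-volume* lenient prescribers, clustering on shared ones by
preferential attachment (weight = 1 + visits so far, deliberately
decoupled from mainstream volume); (iv) per-prescription MME is
log-normal and right-skewed, inflated for lenient prescribers and for
seekers; (v) overdose hazard per patient-quarter is
$h \exp(\gamma\,\mathrm{seeker} + \beta^{\mathsf T}x)$ truncated at 1
(discrete-time approximation; truncation warns), with first event ending
follow-up; (vi) independent per-quarter disenrollment. The comorbidity
log-hazards default to the magnitudes familiar from claims studies of
overdose (e.g. psychiatric disorder $\approx e^{2}$, palliative care
$\approx e^{1.6}$), and the baseline hazard defaults to $2\times10^{-4}$
per patient-quarter, the rare-event rate typical of commercial claims.

**Why the lenient pool is low-volume.** This is the single most
consequential design choice. Reinforcement-style indices deliver per-edge
teleport mass proportional to the inverse of the provider's degree, so a
patient whose providers are *poorly connected* scores high for their
degree — precisely the reported signature of high-bipartite-centrality,
low-PageRank patients attached to multiple small prescribers, and also the
driver of the slightly negative patient-provider degree assortativity
(defaults give $r \approx -0.1$ at study scale; the generator exposes
knobs rather than targeting a specific value). The opposite geometry —
few high-throughput "pill mills" shared by all seekers — makes the seeker
cluster edge-rich and node-poor, *inverts* the conditional association
(centrality hazard ratios below 1 given degree), and is therefore not the
default, although the knobs (`lax_provider_fraction`, `lax_popularity`,
`seeker_lax_prob`) can produce it for sensitivity analyses.

**Effect sizes.** The latent seeker log-hazard defaults to
$\gamma = 4$: latent drug-seeking is modelled as the dominant overdose
risk factor, well above any single comorbidity, so that cohorts of
desk-testable size carry a detectable signal. The seeker prescription rate
(1 per quarter vs 0.5 for others) keeps seeker degree overlapping the
mainstream range — if seekers were extreme-degree outliers, raw degree
would already classify them and centrality could not add information.

**Scenarios used by the tests.**

* *Recovery*: defaults except the hazard scale is raised to
  $2\times10^{-3}$, giving the desk-scale cohort roughly the absolute
  event count (~500) of a full-size claims study; at the rare-event
  default the cohort would see ~45 events, too few to identify any
  covariate. Under this scenario the CoHITS and BiRank models beat the
  covariates-only baseline on AIC with hazard ratios above 1.
* *Null calibration*: $\gamma = 0$ with independent covariates on 100
  smaller cohorts (3,000 patients, 8 quarters, hazard $5\times10^{-3}$ so
  Wald intervals exist); the 95% CI for the centrality hazard ratio must
  cover 1 at its nominal rate within three binomial standard deviations.
* *Potency coupling*: MME weighting can only help where the weights carry
  information the binary structure lacks. The coupling scenario gives
  lenient prescribers a mixed clientele (`lax_popularity = 0.2`), seekers
  a six-fold MME extraction (`seeker_mme_multiplier = 6`) and moderate
  prescription-size dispersion (`mme_log_sd = 0.25`); the weighted CoHITS
  and BiRank models then beat their unweighted counterparts (assessed by
  a one-sided sign test over 20 seeded replicates).

**What the generator does not emulate, and what that means.** Covariates
are independent of seeker status by default (a confounding knob exists but
is off); there is no geography, no provider turnover, no dose titration
over time, no coding noise in diagnoses, and the MME multipliers apply
uniformly to a patient's edges. Passing tests therefore demonstrate that
the algorithms and models behave as specified under a *favourable, known*
data-generating process — not that any index will dominate on real claims.
Two honest limitations found during design are worth stating: (a) under
the *default* cohort (exclusive lenient pool, full log-normal MME
dispersion), MME weighting does not improve CoHITS/BiRank fit — the
unweighted structure is already a near-saturated classifier and the weight
dispersion only adds noise; the weighted advantage is a property of the
coupling scenario. (b) Multiplying all of a patient's edge weights by a
constant cancels in source-normalized transitions, so "seekers get more
MME everywhere" is only visible to the ranking where seekers and
mainstream patients share providers.

## Numerical and degenerate-input policy

* Empty windows return a valid empty network with a message; empty panels
  are an error.
* Duplicate edge-list rows are summed with a warning on read; duplicate
  prescriptions collapse at build time (binary OR / MME sum) without
  mutating the record stream.
* Zero-variance covariates are rejected before fitting; models with zero
  events refuse to fit; all-equal centrality scores z-transform to a zero
  column with a warning.
* Ranking problem sizes in the tests are chosen so the whole suite runs in
  minutes on one CPU: oracle checks use graphs up to $10\times10$,
  structural and survival checks use cohorts of 1,200–20,000 patients.
* Determinism: every stage derives its randomness from the configured
  seed (population, prescriptions and outcomes use consecutive derived
  seeds), so identical configurations reproduce byte-identical claims,
  networks, panels and reports. The outcome stage draws its uniforms
  indexed by patient and quarter before any parameter-dependent branching,
  so runs sharing a seed are coupled across values of $\gamma$ (common
  random numbers: raising $\gamma$ can only add events).

## Interfaces

Claims, edge lists, score tables, component reports and comparison tables
are tab-delimited with headers; the adjacency matrix can be exported in
MatrixMarket form with an identifier sidecar; fit reports and the run
manifest (seed, configuration hash, package version) are JSON. The
command-line front end (`inst/cli/claimsrank.R`) wraps the same functions
with `simulate | build-net | rank | project | panel | fit | run-all`
subcommands and structured stage logging.
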