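# claimsrank

Bipartite network centrality and survival models for prescription-claims
networks.

## The problem

Patients who obtain opioids for nonmedical use ("doctor shoppers") leave a
characteristic trace in insurance claims: they receive prescriptions from
several providers at once, cluster around the same lenient prescribers, and
favour providers who dispense large quantities of potent opioids. A common
way to quantify this behaviour is network centrality on the patient-provider
prescription network. The standard recipe — project the bipartite network
onto patients and run PageRank — distorts the two-mode structure: a patient
tied to one busy clinic can outrank a patient tied to many small
prescribers, the opposite of the drug-seeking signature.

`claimsrank` implements the family of **bipartite centrality indices** that
rank both modes directly — HITS, CoHITS, BGRM and BiRank — next to
PageRank-on-projection, and evaluates all of them the way an epidemiologist
would: as covariates in Cox proportional-hazards models of subsequent
overdose, compared by AIC. Because real claims databases are proprietary,
the package ships a synthetic claims generator that reproduces the
statistical structure this analysis depends on (a small latent drug-seeker
subpopulation spread over low-volume lenient prescribers, heavy-tailed
provider volumes, slightly negative patient-provider degree assortativity,
right-skewed MME edge weights, rare overdose events, censoring by
disenrollment), so every stage is testable end to end.

## The model

All four bipartite indices are damped fixed points of one two-mode
iteration. With `W` the provider-by-patient weight matrix, patient scores
`p`, provider scores `d`, priors `p0`, `d0` and damping `alpha`, `beta`:

    p = alpha * S_p d + (1 - alpha) * p0
    d = beta  * S_d p + (1 - beta)  * d0

The indices differ only in how `W` is normalized into the transition pair,
with `K_d = diag(rowSums(W))`, `K_p = diag(colSums(W))`:

| algorithm | `S_p`                      | `S_d`                      |
|-----------|----------------------------|----------------------------|
| HITS      | `W'`                       | `W`                        |
| CoHITS    | `W' K_d^-1`                | `W K_p^-1`                 |
| BGRM      | `K_p^-1 W' K_d^-1`         | `K_d^-1 W K_p^-1`          |
| BiRank    | `K_p^-1/2 W' K_d^-1/2`     | `K_d^-1/2 W K_p^-1/2`      |

HITS runs undamped with per-iteration sum normalization; the others damp at
0.85 by default. Edges are either binary ties ("at least one prescription
in the window") or the total morphine milligram equivalents (MME) a
provider prescribed to a patient in the window. Models are fit on
patient-quarters with the outcome lagged one quarter, and compared by AIC;
`exp(-delta_AIC / 2)` is the relative likelihood that the worse model is as
good as the better one.

## Worked example

```r
library(claimsrank)

cfg <- experiment_config(
  sim = sim_config(n_patients = 20000, baseline_hazard = 2e-3, seed = 1),
  algorithms = c("pagerank", "cohits", "birank"), variants = "unweighted",
  second_period = FALSE)
ex <- run_experiment(cfg)
ex$comparison
```

```
Model comparison (baseline: baseline)
     model n_parameters log_partial_likelihood     aic delta_aic
1 baseline           10               -4795.20 9610.39      0.00
2 pagerank           11               -4793.44 9608.88      1.51
3   cohits           11               -4778.22 9578.43     31.96
4   birank           11               -4790.58 9603.15      7.24
  relative_likelihood
1            1.00e+00
2            4.70e-01
3            1.15e-07
4            2.68e-02
```

On this cohort the CoHITS model improves on the covariates-only baseline by
about 32 AIC units and BiRank by about 7, while PageRank on the projection
adds little (delta 1.5, relative likelihood 0.47) — the bipartite indices
recover the latent drug-seeker signal that degree, transitive ties and the
projection miss. The centrality hazard ratios (per one standard deviation
of log-normalized score) are read off the fits:

```r
ex$fits$cohits$hazard_ratios[["cohits"]]   # 1.59
ex$fits$birank$hazard_ratios[["birank"]]   # 1.32
```

Individual stages are available as plain functions: `simulate_claims()`,
`build_window_network()`, `project_patients()`, `birank()`,
`pagerank_projection()`, `build_panel()`, `fit_cox()`, `compare_models()`.
A thin command-line front end with `simulate | build-net | rank | project |
panel | fit | run-all` subcommands lives at `inst/cli/claimsrank.R`.

## Vignette

`vignettes/claimsrank-methods.Rmd` documents the model assumptions, what
the synthetic generator does and does not emulate, the numerical choices
(floors, tie handling, convergence), and known limitations.
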