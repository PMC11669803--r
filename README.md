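# clpnet

Cross-lagged panel networks (CLPNs) for two-wave symptom cohorts.

## What this is for

Psychotic-like experiences (PLEs) in young adults co-evolve with depressive
symptoms, anxiety symptoms and adverse life events. A cross-sectional
symptom network cannot orient these relationships in time; with two
measurement waves, a CLPN can: the directed edge *i → j* is the
L1-regularized regression coefficient of wave-1 variable *i* predicting
wave-2 variable *j*, controlling for all other wave-1 variables and for
socio-demographic covariates,

```
z2_j = sum_i W[i, j] * z1_i + gamma' x + eps_j ,
```

fitted node-wise by LASSO (glmnet) over the canonical 24-node layout:
3 CAPE-P15 factors (PI, BEs, PAs), 9 PHQ-9 items, 7 GAD-7 items, and
5 ASLEC adverse-life-event factors. The diagonal `W[i, i]` holds
autoregressive effects and is excluded from every centrality.

The package covers the whole workflow for epidemiologists and
network-psychometrics researchers:

* instrument scoring — CAPE-P15 weighted score (valid-item mean) with the
  1.57 screening cut-off, PHQ-9/GAD-7 item nodes, ASLEC factor scores,
  Cronbach's alpha;
* administrative exclusions (duplicates, speeders, history flags,
  refusals) with an exact cohort-flow report, and persistence/incidence
  transition rates;
* node-wise LASSO CLPN estimation with unpenalized covariate adjustment
  and seeded, reproducible cross-validation;
* expected influence (in-EI, out-EI) and bridge expected influence
  centralities;
* nonparametric bootstrap edge CIs and case-drop bootstrap
  correlation-stability (CS) coefficients;
* between-network comparison: edge-matrix correlation, same-sign edge
  replication, centrality correlations;
* a seeded synthetic two-wave cohort generator with known ground-truth
  cross-lagged structure, used throughout the tests.

## Worked example

```r
library(clpnet)

# a seeded synthetic cohort at study scale, with administrative artifacts
cfg    <- sim_config(seed = 1)          # 3,755 unique respondents
cohort <- generate_cohort(cfg)
raw    <- inject_admin_artifacts(cohort$data, cfg)

res <- run_pipeline(raw, pipeline_config(out_dir = "out", seed = 1))
res
```

which prints (numbers from this exact seed):

```
<clpn_pipeline> analyzed 3358 participants (positive 460 / negative 2898)
<clpn_comparison> edge-matrix r = 0.263 (p = 3.5e-10); replication 54.0% (54/100)
  in_ei          r = 0.674 (p = 0.000307)
  out_ei         r = 0.007 (p = 0.975)
  bridge_in_ei   r = 0.850 (p = 1.46e-07)
  bridge_out_ei  r = 0.226 (p = 0.287)
```

Read: after the exclusion ledger (111 duplicates, 2 speeders, 14
psychotic-history, 11 refusals) and follow-up loss, 3,358 participants are
analyzed; 460 screen positive at the 1.57 weighted-score cut-off. The two
groups' networks are estimated independently. Even though this synthetic
cohort shares one ground-truth dynamics across groups, the small positive
group (n = 460) estimates its outgoing edges noisily: the edge matrices
correlate modestly (r = 0.26), 54% of the positive group's 100 edges
replicate with the same sign in the negative group's network, and the
in-EI / bridge in-EI centralities agree across groups while out-EI does
not — incoming influence concentrates on a few well-determined nodes, while
outgoing influence spreads over many small, unstable edges.

Individual stages are plain functions:

```r
w1  <- node_scores(res_data <- complete_followup(apply_exclusions(raw)$data), 1)
w2  <- node_scores(res_data, 2)
net <- fit_clpn(w1, w2, config = fit_config(seed = 1))
head(centrality_table(net))
boot <- bootstrap_edge_cis(w1, w2, iterations = 1000, seed = 1)
stab <- case_drop_bootstrap(w1, w2, iterations = 250, seed = 1)
cs_coefficient(stab, "in_ei")
```

A thin command-line wrapper over the same functions is at
`inst/scripts/clpnet-cli.R` (subcommands `simulate` and `run`).

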