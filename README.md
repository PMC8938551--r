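# t1dtraj

Disease-progression trajectories from longitudinal islet-autoantibody
panels, modeled with continuous-time hidden Markov models (CT-HMMs).

## What this package is for

Children at increased risk of type 1 diabetes are followed from infancy
with repeated measurements of three islet autoantibodies — GADA, IAA and
IA-2A. Progression from first autoimmunity to clinical diabetes is
heterogeneous: children differ in which antibody appears first, how fast
they accumulate further antibodies, and how quickly they progress to
diagnosis. `t1dtraj` is for biostatisticians and epidemiologists who
want to model such irregularly sampled binary panels:

* **Model.** A latent continuous-time Markov jump process with rate
  matrix $Q$; transition probabilities over a visit gap $\Delta$ are
  $e^{Q\Delta}$, and each visit emits three independent Bernoulli
  antibody observations with state-specific positivity probabilities.
  Parameters are learned by EM (`cthmm()`): the E-step accumulates
  endpoint-conditioned expected dwell times and jump counts in closed
  form from the spectral decomposition of $Q$, and the M-step updates
  rates, emissions and the initial distribution. Diagnosis is never an
  emission — models are learned unsupervised from the antibody panels.
* **Model order.** `run_state_search()` / `select_model()` choose the
  number of latent states by repeated 70/30 participant splits scored
  with BIC ($-2\ell + k\log n_{\text{visits}}$,
  $k = (S-1) + S(S-1) + 3S$) and held-out per-visit predictive
  log-likelihood.
* **Trajectories.** `decompose_trajectories()` splits the fitted state
  space into disjoint forward chains (TR1 = multiple-antibody-first,
  TR2 = IAA-first, TR3 = GADA-first on paper-like fits);
  `assign_participants()` assigns each participant to one chain or
  flags them ambiguous.
* **Statistics.** Seroconversion ages, Pearson chi-square association
  tests, one-way ANOVA with Tukey HSD, Kaplan-Meier curves with
  log-log confidence intervals, and overall/pairwise log-rank tests.
* **Synthetic cohorts.** `simulate_cohort()` generates cohorts from a
  ground-truth 11-state, three-trajectory model calibrated to published
  emission probabilities and entry ages, with state-dependent diagnosis
  hazards, irregular visit schedules, missingness, and sex/HLA-DR
  covariates — the real study data are protected, so all tests run on
  synthetic data.

## A worked example

```r
library(t1dtraj)

config <- ground_truth_config(n_participants = 500, seed = 1)
cohort <- simulate_cohort(config)
nv <- table(cohort$visits$participant_id)
cohort <- subset_cohort(cohort, names(nv)[nv >= 2])
cohort
#> Longitudinal islet-autoantibody cohort
#>   participants: 488 (322 diagnosed)
#>   visits: 7503, ages 0.25-14.99 years

fit <- cthmm(cohort, n_states = 11, n_restarts = 5, seed = 1)
fit
#> CT-HMM fit: 11 states, 488 participants, 7503 visits
#>   log-likelihood -6963.274 (BIC 15291.8), 89 EM iterations

# canonical matching of fitted states to the generator: the recovered
# multiple-antibody state and IAA-first state sit close to the published
# probabilities (0.93/0.62/0.94 and 0.58/0.86/-)
truth <- make_ground_truth_model(config)
matching <- match_states(truth$emissions, fit$params$emissions)
round(fit$params$emissions[matching, ][c(2, 5), ], 3)
#>       [,1]  [,2]  [,3]
#> [1,] 0.909 0.578 0.946
#> [2,] 0.604 0.814 0.058

# trajectory semantics and survival, on decodings under the generating
# model (desk-scale fits may entangle the interchangeable start states;
# see the vignette's identifiability section)
labelings <- decode_states(truth, cohort)
trajectories <- decompose_trajectories(truth, labelings)
trajectories
#> Trajectory decomposition: 3 chain(s), sizes {3, 5, 3}
#>   TR1: TR1-0 -> TR1-1 -> TR1-2
#>   TR2: TR2-0 -> TR2-1 -> TR2-2 -> TR2-3 -> TR2-4
#>   TR3: TR3-0 -> TR3-1 -> TR3-2

assignments <- assign_participants(labelings, trajectories, cohort = cohort)
surv <- build_survival_dataset(assignments, labelings, cohort,
                               trajectories, strata = "chain")
survival_at(km_estimate(surv), 5)[, c("stratum", "estimate")]
#>   stratum  estimate
#> 1     TR1 0.4605542
#> 2     TR2 0.5810811
#> 3     TR3 0.8770810
log_rank(surv)$overall
#> Log-rank test
#>   statistic = 170.8, df = 2, p = 8.048e-38, n = 404
```

The three survival values are 5-year diabetes-free probabilities from
first entry into each trajectory's first antibody-positive state: the
multiple-antibody-first trajectory progresses fastest, the GADA-first
trajectory slowest — the ordering the generator is calibrated to
(approximately 40%/62%/88%).

`chi_square(t1di_table1()$sex)` reproduces the published
trajectory-by-sex association from the printed contingency table:

```r
chi_square(t1di_table1()$sex)
#> Pearson chi-square (no continuity correction)
#>   statistic = 10.59, df = 5, p = 0.06021, n = 2145
```

## Layout

* `R/`, `src/` — implementation (R interface, RcppArmadillo kernels)
* `tests/testthat/` — unit, property and acceptance tests
* `vignettes/trajectory-modeling.Rmd` — the methods vignette: model,
  estimation choices, generator calibration, identifiability limits
* `inst/scripts/t1dtraj-cli.R` — thin command-line front end
  (`simulate`, `fit`, `select`, `label`, `analyze`, `report`)
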