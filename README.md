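# recovmix

Mixture latent Markov models (MLMM) for joint longitudinal analysis of
clinical, societal and personal recovery in schizophrenia spectrum
disorders.

Recovery from psychotic disorders is multidimensional. In naturalistic
cohorts with yearly assessments, twelve indicators describe it per
patient-year: the eight remission items of the Positive and Negative
Syndrome Scale (PANSS-R, rated 1–7 and modelled in three severity
categories), the three Functional Recovery Tool items (independent /
partially independent / dependent functioning in daily living, work and
social contact), and the Single-Item Happiness Question (SIQ, 0–10) as a
proxy for personal recovery. `recovmix` models all twelve jointly: each
patient occupies one of K latent **recovery states** per year, with annual
transition probabilities

a<sub>jk</sub><sup>(c)</sup> = P(S<sub>t</sub> = k | S<sub>t−1</sub> = j, C = c),

optionally stratified by M latent **classes** C with class-specific
dynamics (shared emissions). Conditional on the state, the categorical
indicators are multinomial and the SIQ is Gaussian with state-specific mean
and shared SD; the marginal likelihood is a mixture over classes of scaled
forward recursions, and item-level missingness is handled by dropping
missing items from the emission term.

The package is for biostatisticians and psychiatric-epidemiology
researchers who want to:

* estimate MLMMs by EM with multiple random starts (`em_fit`), with exact
  smoothed posteriors (`forward_backward`);
* select the number of states/classes by BIC under a >10% minimum
  state/class size rule, with an explicit interpretability override
  (`fit_grid`, `select_model`);
* characterize states: canonical worst-to-best ordering, occupancy shares,
  annual transition tables, per-state indicator profiles and happiness
  means (`order_states`, `occupancy`, `transition_table`,
  `state_profiles`);
* apply the dichotomous recovery classifiers of the remission literature
  (all PANSS-R ≤ 3; all ≤ 2; all FRT items independent; SIQ > 7)
  (`classify_panel`, `recovery_rates`);
* relate states to patient characteristics with a three-step
  classification-error correction and Bonferroni-adjusted chi-squared
  tests (`associate_covariates`);
* generate fully synthetic cohorts emulating a yearly naturalistic
  registry — 2327 patients, 1–11 visits (realized mean 4.4, SD 2.4),
  instrument-block observation rates 91.1% / 54.9% / 63.0%, and a
  documented 4-state ground truth — so the entire pipeline is testable
  without access to restricted patient data (`simulate_panel`,
  `ground_truth_defaults`).

## Worked example

Simulate a cohort of 2000 patients from the default ground truth, refit the
4-state model, and summarize:

```r
library(recovmix)

pan <- simulate_panel(generator_config(n_patients = 2000, seed = 1))
pan
#> <recov_panel> 2000 patients, 8777 measurements (mean 4.4 per patient)
#>   observation rates: PANSS 0.911, FRT 0.539, SIQ 0.631
#>   covariates: gender, age_band, diagnosis, illness_duration, antipsychotics
#>   hidden truth attached (strip before fitting)

fit <- em_fit(strip_truth(pan), mlmm_spec(4, 1), fit_config(seed = 1))
fit <- canonicalize_fit(fit)   # relabel states worst -> best

round(occupancy(fit$posterior), 3)
#> [1] 0.175 0.242 0.204 0.379

transition_table(fit$params)
#> annual transition probabilities (row = state at t-1, col = state at t)
#>         to
#> from     state1 state2 state3 state4
#>   state1 0.8511 0.0969 0.0495 0.0026
#>   state2 0.0566 0.8104 0.0433 0.0897
#>   state3 0.0548 0.0543 0.7798 0.1110
#>   state4 0.0035 0.0482 0.0639 0.8844

round(fit$params$mu, 2)
#> [1] 5.69 6.72 5.85 7.08
```

The fit recovers the generating structure: about 17% of measurements in the
least recovered state and 38% in the most recovered; self-transition
probabilities between 0.78 and 0.88 (patients tend to stay in their state
from one year to the next); transitions between the extreme states are
rare (0.26% and 0.35% here); and per-state happiness means near
(5.7, 6.7, 5.9, 7.1) — the negative-symptom intermediate state (state 2)
reports higher happiness than the positive-symptom state (state 3) despite
worse societal functioning.

Dichotomous recovery rates for literature comparison (per measurement,
among determined measurements):

```r
recovery_rates(strip_truth(pan))
#>           classifier n_determined n_recovered       rate
#> 1 clinical_andreasen         7996        2111 0.26400700
#> 2    clinical_leucht         7996        1290 0.16133067
#> 3  societal_swildens         4734         469 0.09907055
#> 4       personal_siq         5539        2123 0.38328218
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/recovmix-cli.R` (subcommands `simulate`, `fit`, `select`,
`profile`, `classify`, `associate`, `reproduce`).

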