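---
title: "Modelling recovery states in psychotic disorders with mixture latent Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling recovery states in psychotic disorders with mixture latent Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Recovery from schizophrenia spectrum disorders is multidimensional: clinical
recovery (symptom remission), societal recovery (independent functioning in
daily life, work and social contact) and personal recovery (the patient's own
sense of well-being) evolve together but are usually analysed separately, or
flattened into a single dichotomy. `recovmix` models all three domains
jointly in yearly panel data. Twelve indicators are analysed per
patient-year:

* eight remission items of the Positive and Negative Syndrome Scale
  (PANSS-R: P1 delusions, P2 conceptual disorganization, P3 hallucinatory
  behaviour, N1 blunted affect, N4 social withdrawal, N6 lack of
  spontaneity, G5 mannerisms/posturing, G9 unusual thought content), each
  rated 1–7 and entered into the model collapsed to three severity
  categories (1–2 absent/unclear, 3–4 mild/moderate, 5–7 severe);
* three Functional Recovery Tool (FRT) items (daily living and self-care;
  work, study and housekeeping; social contacts), each 0 = independent,
  1 = partially independent, 2 = dependent;
* the Single-Item Happiness Question (SIQ, 0–10), a proxy for personal
  recovery.

## The model

The mixture latent Markov model (MLMM) assumes that patient $i$ occupies a
latent *state* $S_{it} \in \{1,\dots,K\}$ at measurement occasion $t$, and
belongs to a time-constant latent *class* $C_i \in \{1,\dots,M\}$ with
weights $\omega_c$. Given the class, states follow a first-order Markov
chain with class-specific initial probabilities $\pi^{(c)}_k$ and annual
transition probabilities $a^{(c)}_{jk} = P(S_t = k \mid S_{t-1} = j, C = c)$.
Conditional on the state, the twelve indicators are independent: each
categorical indicator $v$ has a state-specific distribution $B_{k v}$ over
its three categories, and the SIQ is Gaussian with state-specific mean
$\mu_k$ and a shared standard deviation $\sigma$. The marginal likelihood of
one patient's series $y_{i,1:T}$ is

$$
P(y_{i,1:T}) \;=\; \sum_{c=1}^{M} \omega_c \sum_{s_{1:T}} \pi^{(c)}_{s_1}
\prod_{t=2}^{T} a^{(c)}_{s_{t-1} s_t} \prod_{t=1}^{T} P(y_{it} \mid s_t),
$$

evaluated by a scaled forward recursion rather than the exponential sum.

Design choices that were genuinely open:

* **Classes condition dynamics only.** Classes enter through
  $\pi^{(c)}$ and $A^{(c)}$; emissions are state-specific and shared across
  classes. Classes are thus subpopulations with different transition
  regimes, not different symptom profiles, which keeps states comparable
  across classes.
* **Shared Gaussian variance.** Only per-state happiness means are
  scientifically interpreted; a shared $\sigma$ is the most parsimonious
  emission consistent with that, and avoids variance collapse in small
  states. The SIQ is treated as continuous Gaussian; it is bounded in
  reality, which matters only at the margins (see Limitations).
* **Missing data.** Items missing at a visit are dropped from the emission
  term (missing-at-random), so all available data contribute; a visit with
  nothing observed still contributes structure through the chain.
* **Calendar gaps.** Consecutive *recorded* assessments are treated as
  adjacent annual steps. Gap-aware (continuous-time) transitions are out of
  scope; with yearly target visits the approximation is mild and keeps the
  transition matrix interpretable as an annual rate table.

## Estimation

`em_fit()` maximizes the likelihood by EM. The E-step runs a scaled
forward–backward pass per patient (compiled code), returning smoothed state
posteriors, class posteriors and expected transition counts; the M-step has
closed forms. Numerical choices:

* **Multiple random starts.** The likelihood is multimodal. By default 20
  starts are drawn (probability vectors from Dirichlet(1); SIQ means from
  random observed quantiles; $\sigma$ from the pooled SD). Each start runs
  a 50-iteration burn-in, and the best is continued until the relative
  log-likelihood change falls below `tol = 1e-8` (`max_iter = 1000`). This
  short-run/long-run scheme is standard for mixture likelihoods and cuts
  the cost of poor starts.
* **Floors.** Transition and categorical emission probabilities are floored
  at `1e-6` (renormalized) at every M-step, and $\sigma$ at `1e-3`,
  preventing degenerate zero-probability cells from freezing the chain.
  On non-degenerate data the floors never bind, so the EM ascent property
  holds to numerical precision; the per-iteration log-likelihood trace is
  stored on the fit for inspection.
* **Determinism.** All randomness flows from `fit_config(seed=)`; identical
  seed and configuration reproduce a fit bit-for-bit.
* **Label switching.** State labels are arbitrary. `order_states()` imposes
  a canonical worst-to-best order using a fixed recovery score: the
  happiness mean rescaled to [0, 1] plus the mean probability of the best
  category (absent/independent) across the 11 categorical indicators,
  equal weights. With the default ground truth this reproduces the
  substantive ordering (least recovered, negative-symptom, positive-symptom,
  most recovered): the rescaling makes the two components commensurate, and
  the societal/negative-symptom profile separates the two intermediate
  states that happiness alone would order differently. For comparisons
  against generating parameters, `align_states()` instead matches states by
  emission affinity, which is robust to estimation noise in the score.

## Model selection

`fit_grid()` fits all combinations of $K$ (default 1–6) and $M$ (default
1–3) and `select_model()` returns the admissible model with the lowest
BIC, where

$$\mathrm{BIC} = -2\,\ell + p \log n,$$

$p$ from `n_parameters()` and $n$ = the number of patients (the case-level
convention of latent-class software; configurable). *Admissible* means every
state occupies strictly more than 10% of all measurements (summed
posteriors) and every class strictly more than 10% of patients — small
states are rarely interpretable and often artefacts. Ties break to smaller
$K$, then smaller $M$. An interpretability-based choice of a different
admissible model is supported through an explicit, logged `override`
argument, never automatically: such judgments must be declared to be
reproducible. If the BIC minimizer lies on the grid boundary the grid can
be extended upward (`max_extend`).

## The synthetic cohort generator

No public data accompany this class of naturalistic cohort (the source
registry is access-restricted), so `simulate_panel()` generates panels whose
structure mirrors the published cohort description, and every downstream
claim in the test suite is a parameter-recovery claim on these panels:

* 2327 patients by default; series lengths are a rounded truncated normal
  clipped to 1–11 visits. The latent normal is N(4.272, 2.632), calibrated
  once so that the *realized* length distribution has mean 4.4 and SD 2.4
  (naively rounding/clipping N(4.4, 2.4) inflates the mean to ≈ 4.48).
  The calibrated share of single-visit series is 14.6%, close to but not
  exactly the published 12.8%; it is logged as a diagnostic, not enforced.
* per-visit instrument-block observation rates: PANSS 91.1%, FRT 54.9%,
  SIQ 63.0%; a patient left with no observed indicator anywhere has their
  masks redrawn (the inclusion-criterion analogue).
* the default ground truth (`ground_truth_defaults()`) is a 4-state,
  1-class model: initial distribution (0.16, 0.25, 0.21, 0.38); a
  transition matrix satisfying the published constraints (self-transitions
  77–89%, extreme-state exchanges 0.31% and 0.49%, intermediate-to-best
  10%, worsening moves 4–6%) and approximately stationary at the initial
  distribution (one-step L1 residual 0.0094; over four steps the exact
  drift reaches 0.014 in one state, which the stationarity test accounts
  for); happiness means (5.7, 6.7, 5.9, 7.1) with SD 1.5 (the SD is not
  published; 1.5 gives realistic overlap between adjacent states).
* categorical emissions are *documented qualitative approximations* of the
  published per-state profiles (state 1 impaired everywhere; state 2
  negative-symptom dominant with poor societal functioning; state 3
  positive-symptom dominant, societally better except work; state 4 best
  except work/study/housekeeping). The exact published percentages are not
  available as text, so these defaults are never used as numeric targets.
* raw PANSS scores are drawn uniformly within the band of the sampled
  category (0 → 1–2, 1 → 3–4, 2 → 5–7), because the model emits categories
  while the dichotomous classifiers need raw scores.
* SIQ draws are clipped to [0, 10]. The clip moves the realized state-4
  mean by ≈ −0.03 and adds a small upward bias (≈ +0.05 percentage points)
  to the rarest fitted transition rates; both are absorbed by the
  Monte-Carlo tolerances used in testing.
* covariates (gender, age band, diagnosis, illness-duration band,
  antipsychotic prescription) are drawn per patient from category tables
  keyed to the true state at the first visit, with directions matching the
  published associations (male gender, schizophrenia diagnosis and long
  illness duration more prevalent in worse states; age and antipsychotics
  flat). This supports testing the association machinery without claiming
  the published proportions.

What the generator deliberately does **not** emulate: informative dropout
or drop-in, informative missingness, diagnosis recoding over time, and
calendar-time effects. Passing recovery tests on these panels therefore
shows that the estimator recovers a correctly specified MLMM under
realistic sample sizes, lengths and missingness — not that real cohort data
satisfy the model.

## Worked pipeline

```{r}
library(recovmix)

pan <- simulate_panel(generator_config(n_patients = 2000, seed = 1))
obs <- strip_truth(pan)

grid <- fit_grid(obs, K_range = 1:5, M_range = 1:2,
                 config = fit_config(n_starts = 4, seed = 1))
as.data.frame(grid)
sel <- select_model(grid)          # lowest admissible BIC
fit <- canonicalize_fit(sel$fit)   # worst-to-best state labels

occupancy(fit$posterior)
transition_table(fit$params, fit$posterior$class_post)
state_profiles(obs, fit$posterior, fit$params)

recovery_rates(obs)
assoc <- associate_covariates(pan, fit$posterior)
assoc$tests
```

## Dichotomous recovery classifiers

For comparability with the remission literature, `classify_panel()` applies
four per-measurement rules to the *raw* items: all PANSS-R items ≤ 3
(symptomatic recovery, consensus criterion), all ≤ 2 (the stricter
criterion under which mild symptoms do not count as recovery), all three
FRT domains independent (societal recovery), and SIQ strictly greater
than 7 (personal recovery). Two caveats are intentional: the consensus
six-month persistence requirement is not enforced, because yearly visits
cannot resolve it — classification is per measurement; and the classifiers
consume raw 1–7 scores because the ≤2 versus ≤3 cut-offs are
indistinguishable after the model's three-level coding.

## Covariate association with classification-error correction

Relating states to patient characteristics post hoc ("three-step" analysis)
must account for the fact that modal state assignments are imperfect.
`classification_error_matrix()` estimates
$D_{jk} = P(\text{modal } k \mid \text{true } j)$ from the smoothed
posteriors, and `corrected_crosstab()` premultiplies the modal-by-covariate
count table by $(D^\top)^{-1}$, which undoes the misclassification in
expectation; negative cells (possible in small tables) are floored and
renormalized with a warning. The corrected proportions are the effect
estimates (the per-state covariate distributions).

For the *test* of independence, `chisq_bonferroni()` evaluates the Pearson
statistic on the **observed** modal counts when given a corrected table.
This is deliberate: the correction is an invertible linear map on the state
margin, so "corrected proportions do not vary with the covariate" and
"modal counts are independent of the covariate" are the same hypothesis;
testing the observed multinomial counts propagates the correction's
sampling variability exactly, whereas a Pearson statistic applied naively
to the corrected cells treats them as multinomial counts, understates their
variance, and over-rejects (empirically ~4× the nominal rate at realistic
misclassification levels). The suite verifies the nominal type-I error by
null simulation. Tests use $\alpha = 0.01$ (large samples) with Bonferroni
division by the number of characteristics tested (default family: the five
generated covariates). Descriptive two-group comparisons use unpooled Wald
95% intervals (`group_difference_ci()`).

## Problem sizes used in testing

The suite exercises: exact oracle equivalence against brute-force path
enumeration for all $K \le 3$, $M \le 2$, $T \le 4$; parameter recovery on
five cohorts of 2000 patients (20 EM starts each) with occupancies within
±0.02, self-transitions within the published band ±0.02 and happiness means
within ±0.2; rare-transition recovery on one cohort of 20 000 patients;
selection consistency (the 4-state/1-class truth chosen by BIC plus the
size rule in at least 9 of 10 cohorts of 2000 patients, with reduced starts
over a $K \le 5$, $M \le 2$ grid); exhaustive classifier truth tables over
all $3^8$ categorical patterns; and a 500-replicate null calibration of the
corrected association test. These sizes were chosen so each statistical
tolerance sits near three standard errors of the quantity under test.

## Known limitations

* The SIQ emission is an unbounded Gaussian while the instrument (and the
  generator) is bounded at 0 and 10; near the bounds the model is mildly
  misspecified. The induced biases are small (see above) but a censored
  Gaussian emission would be the principled refinement.
* Empirical (posterior-weighted) state profiles are slightly shrunk toward
  the population mixture relative to the model's emission parameters,
  because posteriors are never exactly one-hot; the model-based profiles
  are the ones to interpret.
* Maximum-likelihood estimates of very rare transition probabilities
  (a few per thousand) are imprecise even at large n: the likelihood is
  nearly flat along these directions and estimates carry an upward finite-
  sample tendency on the order of one per thousand.
* State-by-covariate tables are built at the measurement level (states are
  measurement-level quantities) while covariates are patient-level, so a
  patient's measurements are not independent draws; with sticky states this
  pseudo-replication inflates chi-squared statistics relative to a
  patient-level analysis. The strict family-wise $\alpha = 0.01$ partially
  compensates, but borderline associations should be read cautiously.
* No standard errors are computed for the MLMM parameters; uncertainty is
  carried through posteriors only.
* Covariates are related to states post hoc; they do not enter the
  structural model.
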