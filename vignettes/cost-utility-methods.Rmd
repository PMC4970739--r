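---
title: "Methods: cost-utility modelling of test-and-treat strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-utility modelling of test-and-treat strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceadx)
```

# The decision problem

`ceadx` evaluates whether genotyping advanced lung adenocarcinoma patients
for *EGFR* mutations before first-line therapy — and giving
mutation-positive patients an oral tyrosine-kinase inhibitor (erlotinib)
instead of a platinum doublet — is cost-effective relative to treating
everyone with conventional chemotherapy from a healthcare payer's
perspective. The model couples:

1. a **decision tree** that splits the tested cohort by test result, and
2. a **semi-Markov cohort model** that simulates disease progression
   through first-line treatment, second-line treatment and best supportive
   care (BSC) to death, on monthly cycles over a five-year horizon
   (60 cycles).

Each cohort fraction accrues discounted costs (USD) and quality-adjusted
life-years (QALYs); strategies are compared by incremental
cost-effectiveness ratio (ICER) with explicit dominance labelling.

# Decision tree

With mutation prevalence $p$, test sensitivity $se$, specificity $sp$ and a
proportion $u$ of specimens too inadequate to genotype:

$$
\begin{aligned}
p_{TP} &= p \cdot se \cdot (1-u), &
p_{FP} &= (1-p)(1-sp)(1-u),\\
p_{TN} &= (1-p) \cdot sp \cdot (1-u), &
p_{FN} &= p (1-se)(1-u),
\end{aligned}
$$

and the five proportions (with $u$ itself) sum to one. Test-positive
patients — true and false positives alike, since treatment follows the test
result rather than the unobservable truth — receive the TKI-first pathway.
Test-negative **and unknown-result** patients receive the chemotherapy
pathway; rebiopsy cascades are not modelled, and every tested patient
(including unknowns) incurs the test fee once. At the base-case inputs
(prevalence 39%, sensitivity 98.4%, specificity 89.2%, unknown 11%) this
gives $p_{Test+} \approx 0.4002$ and $p_{Test-} \approx 0.4898$.

# Survival inputs: pooling, fitting, extrapolating

Each model branch (e.g. "first-line TKI PFS in mutation-positive patients")
is informed by one or more digitized Kaplan-Meier curves. The package:

* **Pools** curves across trials as a sample-size-weighted average on the
  union time grid, $\bar S(t) = \sum_i n_i S_i(t) / \sum_i n_i$, with
  right-continuous step interpolation of each input — the natural
  semantics for Kaplan-Meier step functions.
* **Fits** a Weibull survival model $S(t) = \exp(-(t/\lambda)^k)$ two ways:
  - *log-log regression*: OLS of $\ln(-\ln S)$ on $\ln t$, which is linear
    exactly when $S$ is Weibull; the slope is the shape $k$ and
    $\lambda = \exp(-\text{intercept}/k)$. Points with $S = 1$ or $t = 0$
    are excluded (the transform is undefined there) but retained for the
    least-squares objective.
  - *least squares on the survival scale*: minimize
    $\sum_i (s_i - S(t_i; k, \lambda))^2$ with uniformly weighted points.
* **Averages** the two fits pointwise for the base case:
  $S(t) = (S_{\text{reg}}(t) + S_{\text{ls}}(t))/2$. Averaging the
  *parameters* instead would not give the mean survival curve (the model is
  nonlinear in them); the pointwise average is always bounded by the two
  component curves, so single-method scenario runs bracket the base case.

The Weibull family is fixed: the log-log linearization presupposes it, and
the exponential model is recovered as the $k = 1$ special case. Alternative
families (log-logistic, splines) and likelihood-based fitting from
pseudo-individual-patient data are out of scope.

**Numerical choices.** The least-squares optimizer is deterministic without
any seed: L-BFGS-B within shape $\in [0.05, 20]$, scale $\in [0.1, 600]$
from six fixed starts (the regression fit when it exists, plus the lattice
$(0.5,3), (1,6), (1.5,12), (2,24), (3,48)$), each polished by Nelder-Mead
at `reltol = 1e-14`. A curve whose usable points are constant (log-log
slope $\le 0$) is rejected as non-Weibull-compatible rather than silently
fitted.

# Transition probabilities

A monthly-cycle cohort model needs conditional per-cycle event
probabilities, not survival curves. For any fitted (or averaged) model,

$$p_t = 1 - \frac{S(t+1)}{S(t)}, \qquad t = 0, \dots, H-1,$$

so that $\prod_{u<t}(1-p_u) = S(t)$ at every cycle boundary — an identity
the tests verify to $10^{-10}$ over the whole 60-cycle horizon. If $S$
underflows to zero before the horizon the remaining probabilities are set
to one (the state becomes absorbing) and a message is logged.

# The semi-Markov cohort engine

States are *clock-expanded*: a cohort fraction in treatment line $L$ is
indexed by the number of cycles since it entered $L$. The line's PFS and OS
schedules are indexed by that clock, not by model time — trial curves
start at treatment initiation, which is only coherent if the clock resets
on line entry. Each cycle, a fraction with clock $\tau$:

* dies with probability $p^{OS}_\tau$ (death takes priority);
* progresses with probability $\max(0,\; p^{PFS}_\tau - p^{OS}_\tau)$ —
  the PFS event probability includes deaths, and the model gives death
  first claim; negative differences are clamped to zero and counted in a
  logged diagnostic;
* otherwise stays with clock $\tau + 1$.

Progression from the last treatment line enters BSC (clock reset); BSC
fractions die per the BSC survival schedule; death is absorbing.
Progression is impossible from BSC. Transitions are evaluated at cycle
boundaries: a fraction dead at the start of a cycle accrues nothing for
that cycle.

**Accrual.** Occupied line-cycles accrue the line's administration-phase
cost while the clock is below `admin_cycles` (4 for chemotherapy doublets;
the whole duration for oral erlotinib and for BSC) and the cheaper
non-administration cost afterwards. QALYs accrue as occupancy × effective
utility / 12 per cycle: pre-progression utility 0.6532 on first-line
treatment, 0.4734 after progression and in BSC, +0.02 for oral regimens
(the utility source valued intravenous therapy). Adverse-event disutility
is subtracted in the line-entry cycle only (a scenario switch extends it to
the whole administration phase). Both streams are discounted at
$(1+r)^{-t/12}$ with $r = 0.03$ per year; the diagnostic test fee is
charged once, undiscounted, at cycle 0. A half-cycle correction (averaging
start- and end-of-cycle occupancy) is available but off by default.

**Design choices made where the design was open.**

* *Competing risks split*: no decomposition rule for PFS events into
  progression vs death is published for this model class at the cycle
  level; death-takes-priority with clamping is transparent and keeps the
  alive fraction consistent with the OS curve when progression is disabled
  (a tested invariant).
* *OS curve substitutions*: where no trial reports OS for a branch
  (first-line TKI in mutation-positive patients; first-line chemotherapy in
  mutation-negative patients), the configuration binds those lines to the
  pooled OS of unselected first-line chemotherapy cohorts. These are
  ordinary curve bindings, not hard-coded rules, and one shipped scenario
  rebinds them.
* *IV-injection disutility* (scenario switch, −0.043): applied only while a
  non-oral line is in its administration phase, when injections actually
  occur; the source does not state the window.
* *Adverse-event burden*: per-event disutilities are published but
  incidence rates are not. The per-regimen `ae_burden` scalars in
  `default_config()` (erlotinib 0.010, cisplatin+pemetrexed 0.028,
  cisplatin+gemcitabine 0.033, docetaxel 0.042, pemetrexed 0.016) are
  package assumptions built as plausible grade-3/4 incidences times the
  published disutilities (e.g. docetaxel: ~40% neutropenia × 0.0897 + ~7%
  febrile neutropenia × 0.090); they are configuration values a user can
  replace, and their one-cycle application makes results insensitive to
  them.
* *Model construction*: a state-transition (not partitioned-survival)
  formulation, which is what time-variant transition probabilities imply.

# Economics

`compare_strategies()` labels the intervention **dominant** (cheaper and
more effective), **dominated** (costlier and less effective), or reports
the ICER; a zero incremental effect yields the explicit label
`"undefined ICER"` rather than an exception. The comparison is
anti-symmetric in its incrementals and the ICER is invariant to scaling
both incrementals — both tested properties.

`cea_tornado()` perturbs one parameter at a time (costs ±25% by default;
epidemiological parameters and the horizon over explicit ranges) and sorts
bars by swing. The summary statistic is the ICER when the base case and
every endpoint have one; otherwise it switches to the incremental net
monetary benefit $\text{iNMB} = \text{WTP} \times \Delta E - \Delta C$ at a
configurable willingness-to-pay threshold (default \$30,000/QALY, of the
order of per-capita GDP for the setting), because dominance makes the ICER
undefined or sign-ambiguous. The output records which statistic was used.

Seven scenario analyses ship in `scenario_registry()`: each extrapolation
method alone, the OS-substitution rebinding, two alternative chemotherapy
regimens (second-line pemetrexed for mutation-positive patients;
cisplatin+gemcitabine first line with second-line pemetrexed), whole-period
adverse-event disutility, and the IV-injection disutility.

# The synthetic study

Nothing in the pipeline can run without survival curves, and the published
curves exist only as figure images. `synthetic_curves()` therefore
generates a complete, seeded study with known ground truth:

* per-trial event times are Weibull; censoring is the minimum of an
  exponential dropout time (2%/month) and an administrative follow-up
  cutoff (24–36 months by branch);
* the product-limit estimate of each simulated trial is digitized onto a
  monthly grid, mirroring what figure digitization yields;
* the trial-count structure matches the pooled evidence base the pipeline
  must handle (3 trials behind first-line TKI PFS, 12 behind second-line
  TKI in unselected patients, 9 behind first-line cisplatin+gemcitabine
  OS, and so on);
* trial sample sizes are drawn between 80 and 400.

The generating parameters are package inventions chosen once so that the
medians sit where a practitioner would expect them: first-line TKI PFS
median ≈ 13 months versus ≈ 5 months for chemotherapy (the
regime in which biomarker-guided therapy is clearly more effective), OS
medians 8–12.5 months, BSC ≈ 4.5 months. Because the substituted
chemotherapy OS (median ≈ 11 months) has higher early hazard than the long
TKI PFS curve, part of the TKI line's progression probabilities clamp to
zero — the engine's documented competing-risk path, which real digitized
curve sets with OS substitutions also trigger.

What the generator does **not** emulate: digitization error from reading
published figures, non-proportional or non-Weibull hazards (cure fractions,
crossing curves), informative censoring, and between-trial heterogeneity in
the true curves within a branch. Passing tests on synthetic data therefore
demonstrate that the machinery is correct under its own assumptions, not
that any published cost-effectiveness number is reproduced; reproducing
published results additionally requires digitized curves supplied in the
documented CSV format.

# Problem sizes and runtime

The shipped configuration runs 60 monthly cycles with clock-expanded
occupancy matrices (61 × 61 per line), 15 curve sets totalling ~55 trials,
and two Weibull fits per branch; a full base-case evaluation takes well
under a second, and the complete test suite — including ~50-replicate
parameter-recovery studies at n = 500 and 200 × 200 grid-search oracles —
runs in a few seconds. These sizes were chosen as comfortably sufficient
for the statistical checks involved.

# Known limitations

* Deterministic cohort model only: no probabilistic sensitivity analysis,
  CEACs or EVPI, and no individual-level microsimulation.
* The Weibull family is fixed; branches with strongly non-Weibull shapes
  will fit poorly (the per-branch SSE report makes this visible).
* Costs are a single flat currency (USD, 2014 prices) with no indexing
  logic; inputs must arrive pre-adjusted.
* Utility inputs are treated as fixed values; their published confidence
  intervals are not propagated.
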