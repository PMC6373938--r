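---
title: "Methods: partial credit calibration, item purification and CAT simulation"
author: "premcal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial credit calibration, item purification and CAT simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

premcal implements the psychometric workflow used to develop brief
patient-reported experience measures (PREMs) from a large pool of Likert
items: non-parametric screening, partial credit Rasch calibration, an
iterative purification of the item set, test–retest agreement, and
simulation of computerized adaptive testing (CAT) on the calibrated bank.
This vignette records the models, the conventions we chose where several
are defensible, and what the bundled synthetic data generator does and does
not emulate.

## The measurement model

Responses are ordered categories $k = 0, \dots, m_i$ of item $i$.  The
partial credit model (PCM) places persons and item category thresholds on a
common latent metric $\theta$:

$$P(X_i = k \mid \theta) =
  \frac{\exp \sum_{h \le k} (\theta - \delta_{ih})}
       {\sum_{l=0}^{m_i} \exp \sum_{h \le l} (\theta - \delta_{ih})},$$

with the empty sum defined as zero.  The $\delta_{ih}$ are adjacent-category
thresholds: the $\theta$ at which categories $h-1$ and $h$ are equally
likely.  The slope is fixed at one (the Rasch constraint), so the total
score is sufficient for $\theta$ and item information equals the
conditional category variance $\mathrm{Var}(X_i \mid \theta)$.

**Calibration** (`fit_pcm()`) maximises the marginal likelihood by EM with a
fixed standard normal latent prior — the identification convention that
pins the metric.  The prior is integrated on 61 equally spaced nodes on
$[-6, 6]$; convergence is declared when no threshold moves by more than
$10^{-4}$ between iterations (cap 500).  Missing responses simply
contribute nothing to the likelihood.  Raw categories never observed in
the data cannot be estimated and are merged into their lower neighbour,
with the action recorded on the model object.

**Scoring** (`eap_score()`) is Bayesian expected a posteriori: the
posterior mean over the quadrature grid, with the posterior SD as the
standard error.  An empty response pattern returns the (grid-discretised)
prior mean and SD.

**Item fit** (`fit_statistics()`) stratifies persons on the EAP estimate
computed *without* the item under test and compares observed category
counts per stratum with their posterior-predictive expectation.  The
leave-one-out matching criterion matters: conditioning on an estimate that
contains the tested response inflates the statistic severely (in our null
calibrations, to an 87% rejection rate at the nominal 5% level), while the
leave-one-out version is approximately calibrated.  Ten strata are formed
by deciles and merged until every expected cell reaches 5; the item
degrees of freedom are $(G-1) \, m_i$ for $G$ strata.  The scale-level
statistic aggregates the item chi-squares — a first-order
limited-information discrepancy, chosen because the full response-pattern
table is hopelessly sparse at a few hundred respondents — and RMSEA is
$\sqrt{\max(0, \chi^2 - df) / (df \cdot n)}$.  Fit software differs
substantially in these conventions, so printed fit values from other
programs should only be compared loosely.

**Marginal reliability** is $(V - E[\mathrm{SE}^2])/V$ over a latent
population with variance $V$.  Two conventions are implemented: averaging
EAP posterior variances over simulated respondents (default; the
reliability of the scores a user actually gets) and averaging
$1/I(\theta)$ by quadrature (the asymptotic, prior-free version, slightly
lower for short scales — 0.85 versus 0.87 for the bundled 19-item bank
under a standard normal population).

## Non-parametric screening

`mokken_screen()` applies two checks before any parametric modelling.
Loevinger's scalability coefficient for an item pair is the ratio of the
observed covariance to the maximum attainable under the marginals; we
compute the maximum by the rearrangement bound (covariance of the two
sorted columns), which is exact for empirical distributions.  Items are
kept when item $H \ge .30$, reading the usual practice threshold as a
keep-rule.  Manifest monotonicity is checked against rest-score groups:
the rest score is the mean over the person's other observed items (robust
to missingness), grouped into quantile bins of at least
$\max(50, n/10)$ persons; each item-step probability is compared across
all ordered group pairs, a decrease beyond .03 counts as a violation, and
its one-sided two-proportion $z$-test at $\alpha = .05$ decides
significance.  An item is flagged on any significant violation.

Dimensionality is screened by parallel principal component analysis of the
polychoric correlation matrix (two-step estimator: thresholds from the
marginal normal quantiles, then the latent correlation by maximising the
bivariate-normal table likelihood, integrated with 32-node Gauss–Legendre
quadrature).  Reference eigenvalues are means over Monte-Carlo datasets of
identical dimensions whose items are resampled from the observed marginal
frequencies; components are retained while the observed eigenvalue exceeds
the reference at the same rank.  Non-positive-definite matrices are
eigenvalue-clipped and rescaled to unit diagonal.  Pearson correlations are
available as a fallback, but on 5-category data at modest $n$ they can
inflate the second component (in our emulation runs they falsely retained
two components where polychorics correctly retained one), so polychoric is
the default despite its cost.

## The purification pipeline

`run_purification_pipeline()` executes the stages in the order used in
instrument development, recording every action in a JSON-lines ledger:

1. **Mokken screening** — items failing scalability or monotonicity are
   removed.
2. **Dimensionality gate** — the pipeline refuses to continue if parallel
   analysis retains more than one component.
3. **Threshold ordering** — after an initial calibration, an item is
   disordered when some category is never the modal response anywhere on
   $\theta$; for the PCM this coincides with non-ascending thresholds, and
   both checks are run.  If any item is disordered, one uniform collapsing
   map (default 0-1-1-2-2) is applied to *all* items, mirroring the
   practice of choosing a single rescoring solution so that scores remain
   comparable across items; the map may only merge adjacent categories.
4. **Local dependency** — Yen's Q3: residuals $x_{pi} - E[X_i \mid
   \hat\theta_p]$ (after modal imputation so residual columns are
   complete) are correlated over item pairs, and the flagging threshold is
   .2 above the mean off-diagonal value.  Items dependent on two or more
   partners are removed first (highest partner count first, ties to the
   item with less prior-integrated information, counts recomputed after
   each removal); each surviving isolated pair then loses its less
   informative member.
5. **Differential item functioning** — see below; flagged items are
   removed.
6. **Misfit** — worst-fitting item removed while its Bonferroni-adjusted
   $p$ falls under $\alpha = .05$, refitting between removals.

The model is refit after every stage that changes the item set or scoring.

**DIF** (`detect_dif()`) uses the hybrid ordinal-regression/IRT approach:
per item, nested proportional-odds models $y \sim \hat\theta$,
$+\,\mathrm{group}$, $+\,\hat\theta\times\mathrm{group}$ (fitted with
`MASS::polr`).  The 2-df likelihood-ratio test of the full model against
the baseline, Bonferroni-corrected across items, establishes significance;
McFadden's $\Delta R^2 = R^2(M_2) - R^2(M_0)$ with $R^2 = 1 -
\ell/\ell_0$ measures magnitude; an item is flagged only when both the
corrected test *and* $\Delta R^2 > .035$ agree.  Because $\Delta R^2$ is
an effect size, no sample size makes a small shift "meaningful": in our
calibrations a threshold shift of 0.8 yields $\Delta R^2 \approx .02$
(never flagged), 1.2 yields $\approx .05$, and 1.6 — the study-emulation
default — $\approx .05$–$.09$ depending on group balance.  Purification
iterates: items flagged in one round are dropped from the matching
criterion for the next, until the flagged set stabilises.  The service
user/carer contrast excludes persons labelled as both or unreported.
Separation or non-convergence in any nested fit marks the item unstable
rather than flagged.

**Test–retest** (`test_retest()`) pairs occasions on person id and reports
the Pearson correlation and Bland–Altman limits of agreement
$\bar d \pm 1.96\, s_d$ of the baseline-minus-followup differences, both
occasions scored with the same final calibration (the retest is scored,
never recalibrated).

## CAT simulation

`simulate_cat_study()` draws simulees from a normal trait distribution,
generates complete PCM response vectors, and administers fixed-length
adaptive tests: at each step the maximum posterior weighted information
(MPWI) criterion picks the unadministered item whose information curve,
integrated against the current $\theta$ posterior, is largest; the
posterior is then updated and the final EAP and posterior SD recorded.
The first item therefore maximises prior-weighted information.  All test
lengths reuse the same response vectors, so correlations between CAT and
full-bank scores are directly comparable, and a full-length session is by
construction identical to full-bank scoring (its correlation with the full
scale is exactly 1).

Three conventions deserve notice, because published CAT tables rarely
state them:

* *Population parameters.*  A reported trait distribution
  "N(−0.08, 1.90)" is read as mean and **variance** (SD $\approx 1.38$) —
  the convention in which Rasch software reports an estimated latent
  variance.  We prototyped both readings against the bundled bank's
  published precision table: the variance reading with a matched prior
  reproduces the printed SE means and ranges closely, while the SD reading
  overshoots every row (e.g. mean SE .45 instead of .36 at full length).
  `var_is_sd = TRUE` restores the SD reading.
* *Scoring prior.*  Default `"matched"`: the EAP prior equals the simulee
  distribution, as in the Firestar simulation script this module emulates;
  `"standard"` uses N(0, 1).
* *Grid.*  81 nodes on $[-4, 4]$, Firestar's grid; calibration keeps
  61 nodes on $[-6, 6]$.  The truncation matters only for extreme
  simulees, where it bounds the reported SE.

Under these defaults the bundled 19-item bank yields mean final SEs of
about .39/.42/.49/.64 at 19/15/10/5 items with full-scale correlations of
1/.99/.97/.92 (1000 simulees; exact values are computed by
`scripts/acceptance.R` and the test suite, never asserted from memory).
One observation from reproducing published precision tables: SE-versus-
length curves implied by information additivity are smooth, so a table
whose 15- and 5-item rows fit such a curve but whose 10-item row sits far
below it cannot be matched at all lengths simultaneously by any convention
we tried; our reproduction favours the rows consistent with the smooth
curve.

## The synthetic data generator

`study_design()` emulates the development survey that produced the bundled
bank: 67 five-category items (thresholds uniform on $[-2.5, 2.5]$, sorted),
267 respondents with $\theta \sim N(-0.08, \sigma^2 = 1.90)$, 16%
missingness completely at random, a 67-person retest with latent
correlation .75, a 66/15/12/7% service-user/carer/both/unreported mix, and
one pathology of each kind the pipeline must catch:

* **Disordered thresholds** — responses regenerated from reversed
  thresholds, so middle categories are never modal.
* **Local dependency** — a partner item copies the source item's response
  with probability .7 (a triplet, so the multi-partner removal rule is
  exercised).
* **DIF** — carer thresholds shifted by 1.6, sized to give McFadden
  $\Delta R^2$ near the .06 reported in the development study.
* **Low scalability** — 80% of responses replaced by uniform noise.
* **Non-monotone item** — an unfolding-style item whose operating curve
  reverses past its centre (magnitude = fraction of slope reflected).  We
  first tried a localised probability dip, but rest-score group averaging
  makes dips of any plausible depth statistically invisible even at
  $n = 1000$; unfolding is both the classic empirical violator and
  detectable, so it is the implemented pathology.

All magnitudes were calibrated once by Monte-Carlo so that each pathology
is detectable by its stage at the study's sample size, then frozen.

The generator is deliberately idealised: missingness is MCAR (no
informative skipping), persons respond exactly per the PCM (no
carelessness, acquiescence or response styles), groups differ only through
injected DIF, and the retest involves no item memory or true change beyond
the latent autocorrelation.  Pipeline tests passing on these data
therefore demonstrate that the machinery detects what it claims to detect,
not that real survey data are this well behaved.

## Numerical choices and degenerate inputs

Category probabilities are computed with max-subtraction, so extreme
$\theta$ or thresholds cannot overflow.  M-step maximisation is BFGS with
the analytic expected-score gradient.  Zero-variance items make Loevinger
H undefined for that item (reported, not dropped silently); identical
response rows make all Q3 residual columns constant and every pair is
reported uncomputable.  Ties in MPWI break by bank order, making sessions
reproducible.  Threshold-disorder verdicts use the analytic check when two
thresholds are closer than twice the scan resolution.  Degenerate
Bland–Altman limits (zero variance of differences) report 100% of pairs
within limits.

## Problem sizes in the test suite

Unit tests run at the smallest sizes that make their statistics stable:
recovery and power checks use 19 or 10 items at $n$ = 400–2000 with 5–50
replicates (50 for the pathology power properties), and the end-to-end
emulation runs once at the full 267 x 67 study scale.  The acceptance
script simulates 1000 adaptive-testing respondents and 20,000 simulees for
the reliability integral.

## Known limitations

Slopes are fixed at one; no graded-response or multidimensional
alternatives are fitted, so slope misfit can only surface as item misfit.
RMSEA conventions differ across programs, and ours is intentionally
simple.  Parallel analysis retains components sequentially from rank 1.
DIF handles one two-level contrast at a time.  The CAT simulator has no
content balancing or exposure control, matching the simulated design it
reproduces.
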