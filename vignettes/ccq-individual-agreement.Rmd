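---
title: "Individual-level agreement analysis for the CCQ: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-level agreement analysis for the CCQ: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccqagree)
```

## The problem

Health-status questionnaires are usually validated at the group level:
internal consistency, test--retest reliability, responsiveness.  Whether a
*single patient's* score can be trusted in routine care is a different
question, and one way to answer it is to treat independent raters -- the
treating clinician, and a pool of reviewing clinicians who only read a
transcript of an in-depth interview -- as proxy measurements of the same
patient, and then quantify how closely their questionnaire scores agree
with the patient's own.

`ccqagree` implements that design for the Clinical COPD Questionnaire
(CCQ): a 10-item instrument on a 0--6 Likert scale with three domains --
symptoms (4 items), mental state (2 items), functional state (4 items) --
whose total score is the plain mean of the ten items.  The minimal
clinically important difference (MCID) of the CCQ is 0.4 points, and that
value anchors the absolute agreement indices below.

The package covers four stages:

1. **Instrument** -- form validation and scoring (`score_ccq()`,
   `score_forms()`).
2. **Review design** -- a balanced randomized assignment of patient
   interviews to reviewer sets (`build_review_design()`), and per-patient
   reviewer means (`aggregate_reviewers()`).
3. **Agreement suite** -- Lin's concordance correlation coefficient with
   its precision/accuracy decomposition, the Total Deviation Index, the
   Coverage Probability at the MCID, the absolute-agreement intraclass
   correlation, Bland--Altman quantities, and a Shapiro--Wilk gate.
4. **Pipeline and simulator** -- the three-comparison study report
   (`run_study()`) and a synthetic-study generator with analytically known
   population agreement (`simulate_study()`, `population_agreement()`).

## The agreement model

All indices derive from the first two joint moments of paired scores
$(x_i, y_i)$, $i = 1 \dots n$.  Writing $\bar x, \bar y$ for the means,
$s_x^2, s_y^2$ for the variances, $s_{xy}$ for the covariance, the
concordance correlation coefficient is

$$\rho_c \;=\; \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

the expected squared distance from the identity line, normalized.  It
factorizes exactly as $\rho_c = \rho \cdot C_b$ where $\rho$ is the Pearson
correlation (*precision*) and

$$C_b = \frac{2}{v + 1/v + u^2}, \qquad
  v = s_x / s_y, \quad u = \frac{\bar x - \bar y}{\sqrt{s_x s_y}}$$

is the bias-correction factor (*accuracy*), penalizing scale ($v \ne 1$)
and location ($u \ne 0$) shifts.  The decomposition separates "the raters
disagree randomly" from "the raters disagree systematically".

Two absolute indices complement the scale-free coefficients.  With
$\mu_d = \bar x - \bar y$, $\sigma_d^2 = s_x^2 + s_y^2 - 2 s_{xy}$ and the
mean squared difference $\varepsilon^2 = \mu_d^2 + \sigma_d^2$:

* **TDI$_p$** is the boundary capturing a proportion $p$ of absolute
  differences.  The default estimator is the normal approximation
  $z_{(1+p)/2}\,\varepsilon$; an exact mode solves the folded-normal
  quantile of $|D|$, $D \sim N(\mu_d, \sigma_d^2)$, instead.  The two
  agree when $\mu_d = 0$ and diverge when $|\mu_d|$ dominates $\sigma_d$
  (the approximation is then conservative); both are exposed, and the
  approximation is the default because it is the conventional reported
  form.
* **CP$_\delta$** is the model-based probability that a difference lies in
  $\pm\delta$: $\Phi((\delta-\mu_d)/\sigma_d) -
  \Phi((-\delta-\mu_d)/\sigma_d)$, with $\delta$ defaulting to the MCID
  (0.4) so the index reads directly as "the chance that a proxy rating is
  clinically indistinguishable from the patient's own".

The ICC variant is the two-way absolute-agreement single-rater ICC(A,1) --
the variance-components construct closest to the CCC; the two coincide
asymptotically and the package tests their proximity by simulation.
Coefficients are categorized with the conventional cutoffs
($\le 0.4$ poor to fair, 0.41--0.6 moderate, 0.61--0.8 good, 0.81--1.0
excellent).  Both the CCC and ICC can be negative in principle; the
implementation keeps the full $[-1, 1]$ range and treats $[0, 1]$ merely
as the interpretable region rather than clamping.

### Moment denominator

The moments default to the $1/n$ denominator, which is the convention of
Lin's estimator (on the triple $x = (0,1,2)$, $y = (1,2,3)$ it gives
$\rho_c = 4/7$, where $1/(n-1)$ moments would give $2/3$).  The choice is
configurable (`denominator = "n_minus_1"`) but pinned by default, since
the estimate itself depends on it.

### Confidence limits

Reports carry a *single* 95% confidence limit per estimate, one-sided in
the unfavourable direction: lower for CCC, precision, accuracy, CP and
ICC, upper for TDI.  This matches the convention of concordance reporting
(a TDI limit above the estimate, all other limits below), and two-sided
intervals are available via `ci = "two-sided"`.

The variance machinery, all on transformed scales and back-transformed:

* **CCC**: Fisher $z = \tanh^{-1}\rho_c$, with Lin's asymptotic variance
  (erratum-corrected form), divisor $n - 2$.
* **Precision**: classical Fisher $z$ with variance $1/(n-3)$.
* **Accuracy**: a normal-theory delta method.  $C_b$ is a smooth function
  of the five moment estimators, whose joint asymptotic covariance under
  bivariate normality is known in closed form; the gradient is taken
  numerically and the limit is formed on the logit scale.  Because the
  logit standard error degenerates as $C_b \to 1$ (an interior maximum:
  the gradient vanishes while the logit Jacobian explodes), the limit is
  taken as the larger of the logit-scale and the untransformed
  delta-method bounds -- asymptotically equivalent, and the untransformed
  bound takes over smoothly near the boundary.
* **CP**: logit-transform delta method from the moments of the
  differences ($\mathrm{Var}(\hat\mu_d) = \sigma_d^2/m$,
  $\mathrm{Var}(\hat\sigma_d) = \sigma_d^2/2m$, $m = n-2$).
* **TDI**: log transform of the MSD with variance
  $2(1 - \mu_d^4/\varepsilon^4)/(n-2)$.

The $n-2$ divisor is used consistently across the suite (the CCC variance
fixes it; the delta methods adopt it as the small-sample convention).
One-sided lower-limit coverage of the CCC is verified by simulation at the
package's validation scale (100 replicates of $n = 2000$; observed
coverage within a few points of 95%).

### Degenerate inputs

Zero-variance score series make the scale-free coefficients undefined and
raise explicit errors rather than returning 0/0 artifacts.  Constant
differences (detected up to a $10^{-12}$ relative floating-point residue)
make CP an indicator $\mathbf 1(|\mu_d| < \delta)$ with a degenerate limit,
flagged in the output; a zero MSD gives TDI 0 with a zero-width limit.
Estimates at $|\rho_c| = 1$ report zero-width limits.  The folded-normal
quantile is solved by bisection (`uniroot`, tolerance $10^{-10}$) on a
bracket $[0, |\mu_d| + \sigma_d(z_{(1+p)/2} + 8)]$ that always contains
the root.

### Bland--Altman conventions

Differences are `x - y` (first-named series minus second), limits of
agreement use the sample ($n-1$) SD as is standard, and the within-MCID
fraction counts differences *strictly* smaller than $\delta$.  The
Shapiro--Wilk gate annotates each total-score series at $\alpha = 0.05$;
it is an annotation of confidence-limit validity, not a hard stop.

## The review design

The study structure assigns each of $P$ patients to $k$ of $R$ reviewers
with every reviewer receiving exactly $Pk/R$ interviews (44, 20 and 5 give
11 per reviewer set).  The generator uses a cyclic balanced template --
patient $i$ takes reviewer residues $ik, \dots, ik+k-1 \pmod R$, which is
exactly balanced whenever $R \mid Pk$ -- randomized by uniform relabeling
of patients and reviewers, plus a random presentation order inside each
reviewer's packet.  Relabeling preserves exact balance with no retries and
makes each (patient, reviewer) pair's marginal assignment probability
exactly $k/R$ by permutation symmetry; both properties are tested by
enumeration over all small feasible designs and by Monte-Carlo frequency.
Infeasible requests ($R \nmid Pk$, or $k > R$) fail with the violated
condition named.

## The synthetic-data generator

Each patient carries a latent severity $\theta_i \sim N(\mu_\theta,
\sigma_\theta^2)$ on the CCQ scale (defaults 2.2 and 0.9, the cohort
marginals of the study population, alongside age 66.1 (7.4), FEV$_1$
%predicted 44.8 (13.8), GOLD II/III/IV at 13/26/5 and 32/44 male).  A rater
$r$ perceives $a_r + b_r \theta_i + N(0, \sigma_r^2)$ and answers each
item as that perceived value plus item-level noise with a per-domain SD;
items are rounded and clipped to the 0..6 grid.  Reviewer location biases
are drawn once per study from $N(0, \sigma_a^2)$, so the "mean of five
reviewers" averages genuinely heterogeneous raters.

On the continuous scale (no rounding, no clipping) the paired total scores
are exactly bivariate normal, and `population_agreement()` gives the whole
suite in closed form from $X = \theta + e_1$, $Y = a + b\theta + e_2$:
$\mathrm{cov} = b\sigma_\theta^2$, error variances collecting perception
noise plus the item-average term $\sum_j n_j \sigma_j^2 / 100$, and for
the $k$-reviewer mean the between-reviewer term $\sigma_a^2/k$ plus the
within-reviewer variance over $k$.  These closed forms anchor every
estimator to known truth.

Choices worth stating explicitly:

* **All noise is Gaussian on the latent scale** -- this is the same
  distributional assumption the CP/TDI formulas and the Shapiro--Wilk gate
  make, so the simulator tests the estimators under their own model.
* **Continuous mode skips clipping as well as rounding.**  Clipping at
  $[0,6]$ is a boundary effect exactly like rounding; keeping either would
  shift the population moments away from the closed forms.  Estimator
  recovery runs therefore use continuous mode; Likert-mode runs are
  checked only for attenuation (rounding plus clipping should not *raise*
  concordance beyond sampling noise -- a documented property, not a sharp
  bound).  Continuous items may leave $[0,6]$, so form validation has a
  `likert` switch and score ranges are guaranteed only for Likert data.
* **Default rater-error magnitudes are calibration choices**, not data:
  no published error magnitudes exist.  They were fixed once so the
  population patient-vs-treating CCC is about 0.87 and
  patient-vs-reviewer-mean about 0.86 at the study's severity spread
  (perception SD 0.2 for patient and treating clinician, item-noise SDs
  0.8/1.0/0.9, reviewer bias SD 0.5 and perception SD 0.63).
* **Limitation**: with independent rater errors the model cannot
  simultaneously reproduce a *lower* treating-vs-reviewer concordance
  (as published tables of this design show) than either comparison with
  the patient -- that pattern requires error correlation between the
  patient and each clinician rater, which the generator does not model.
  The pipeline is validated on what the generator knows: comparisons
  against constructed population values.

What passing tests show -- and do not.  The simulator demonstrates that
the estimators recover known population agreement from data satisfying
the model's assumptions, that the design generator is exactly balanced,
and that the pipeline is deterministic end-to-end.  It does not
demonstrate anything about real interview-based ratings: ordinal item
behaviour beyond Gaussian-plus-rounding, floor effects in mild disease,
rater error correlated with severity, or non-normal score distributions
are all outside the generated world.

## The pipeline

`run_study()` reports the three comparisons of the study design -- patient
vs treating clinician, patient vs reviewer mean, treating clinician vs
reviewer mean -- on **total scores**, with domain-level output as
Bland--Altman datasets (total, symptoms, mental, functional) for the
patient-vs-reviewer comparison; a config switch (`domain_tables = TRUE`)
adds domain-level agreement tables.  The reviewer mean is computed on
total scores; for complete forms this equals scoring the item-wise mean
form (the scoring rule is linear), and the pipeline asserts that identity
at run time rather than assuming it.  Reconciliation is strict: one
patient and one treating form per subject, reviewer forms matching the
design pair-for-pair, violations named with their rows or
(patient, reviewer) pairs.  Exports (`export_report()`) are
byte-deterministic CSVs plus JSON, and the manifest records the config,
design seed and input digests.

Missing items are refused by default; an opt-in pro-rating policy scores
forms with $\ge 8$ answers when every domain keeps at least half its
items, with the total defined as the 4/2/4-weighted mean of pro-rated
domain means so the weighted-mean identity stays exact.  The item-to-domain
mapping defaults to the published CCQ convention (symptoms $\{1,2,5,6\}$,
mental $\{3,4\}$, functional $\{7,8,9,10\}$) but any 4/2/4 partition can
be supplied -- the agreement analysis is invariant to the labels, so
nothing downstream depends on the default being right.

## Validation scale

The shipped checks run at sizes chosen to keep Monte-Carlo error an order
of magnitude below the tolerances they assert: moment/identity properties
on 1000 random pairs; Monte-Carlo oracles for CP and exact TDI at $10^6$
draws (tolerances 0.005 and 0.01); estimator recovery at $n = 2000$ over
100 seeds against a constructed population CCC of 0.85; ICC--CCC proximity
at $n = 500$; generator-moment convergence at $n = 10^5$ (1%).  A
44-patient probe with equal-variance errors calibrated to a population CCC
of 0.87 is reported by `scripts/acceptance.R` (median one-sided lower
limit across seeds, landing near 0.79); it is assumption-dependent by
construction and is reported rather than asserted.
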