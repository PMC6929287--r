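---
title: "Latent-class patterns of children's mental-health service use: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class patterns of children's mental-health service use: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careclass)
```

## The problem

Administrative records from children's mental-health agencies hold one row
per face-to-face contact. A person-centered question — *what distinct
patterns of service use do children follow over several years?* — cannot be
answered from totals alone. This package implements a pipeline that

1. filters raw visit records into an analysis cohort with explicit
   inclusion/exclusion rules and an attrition log;
2. codes each child's four years after intake as 48 monthly binary
   indicators and segments visits into *episodes of care* (EoC);
3. discovers latent service-use classes with a binary latent class model
   fitted by EM, selecting the number of classes by an explicit
   multi-criterion rule;
4. handles the non-random missingness of intake interview scores
   (Little's MCAR test, single EM imputation); and
5. asks how well intake characteristics *predict* the discovered classes
   (canonical discriminant function analysis with jackknife
   cross-validation).

Because agency records of this kind are restricted, the package ships a
seeded synthetic-cohort generator whose defaults encode the published
descriptive structure of a large real cohort (five classes, their
prevalences, monthly visit-probability shapes, visit volumes, intake
T-score distributions and missingness rates). Every downstream stage is
exercised, tested and benchmarked against that generator.

## Cohort construction

A child's **index visit** is the earliest face-to-face visit inside the
intake window (default 2004–2006) with no face-to-face visit in the
previous 548 days (18 months at 365.25 d/y, rounded). Filters are applied
in a fixed, logged order: face-to-face restriction; index rule; age at
index at least 5 and under 14 completed years (ages "5 to 13" inclusive);
exclusion of pervasive-developmental-disorder flags; and exclusion of
children with a complete prior episode of care ending within 548 days
before the index.

The last rule deserves a note. Episodes detected on *face-to-face* visits
can never end inside the 548-day pre-index window — the index rule already
guarantees that window is free of face-to-face visits. A recent prior
episode can therefore only consist of other contact modes (telephone,
indirect), and that is how the rule is implemented here: episode screening
for this rule runs over pre-index visits of any mode. This is the only
reading under which "no face-to-face visit in 18 months" and "had an
episode of care in the previous 18 months" can both select children, and
it matches the fact that the raw records do contain non-face-to-face
contacts.

Ages are computed as completed years by day count (`floor(days/365.25)`),
which is deterministic and agrees with the generator's date construction.

## Trajectory coding and episodes of care

Month *m* covers day offsets `[round((m-1)·365.25/12), round(m·365.25/12))`
from the index date — fixed-width bins rather than calendar months, so
coding is reproducible and timezone-free. Entry *m* of a child's
48-vector is 1 if any visit falls in bin *m*; month 1 is always 1 by
construction.

An **episode of care** is a chronological cluster of at least 3 visits;
clusters are separated wherever the gap since the previous visit reaches
180 days (the conventional 6 months; a deliberate constant, not a quoted
figure). Smaller clusters are kept as non-episode contacts so that
scattered pre- and post-episode visits remain reportable. The greedy
split-at-gaps rule yields the unique partition in which all within-cluster
gaps are below the threshold and all between-cluster gaps at or above it;
the test suite verifies this against an exhaustive partition enumerator on
instances of up to 12 visits. Derived metrics per child: episode count and
category (0/1/2+), total visits, duration of involvement (first to last
visit, in years, with "more than 2 years" strict), pre-episode visits and
the first inter-episode gap.

## The latent class model

For child $i$ with indicators $x_{i1},\dots,x_{i48}$,
$$P(x_i) = \sum_{k=1}^{K} \pi_k \prod_{j=1}^{48}
  \theta_{kj}^{x_{ij}} (1-\theta_{kj})^{1-x_{ij}},$$
the standard binary LCA with conditional independence within class. EM
runs in log space; $\theta$ is floored at $10^{-6}$ to keep the
log-likelihood finite at the boundary. Each of 10 random starts runs up to
250 EM iterations (relative log-likelihood tolerance $10^{-7}$), and the
winning start is polished by up to 50 further EM iterations at tolerance
$10^{-8}$. The polish phase plays the role of the Newton-type final
optimization used by commercial LCA software; since both seek the same
maximizer, the optimizer's identity is immaterial to the result, and
continued EM cannot decrease the likelihood. Classes are reported in
canonical order of descending $\pi_k$ (ties broken by descending mean
profile), and the reported log-likelihood is recomputed from the returned
parameters so that fit indices always correspond exactly to the model
reported.

**Model selection.** For $K = 2..7$ (the upper end of the published
$2..10$ scan is uninformative on cohorts of the size simulated here and
triples the run time), the average relative improvement over $K-1$ across
AIC, BIC and CAIC is computed; scanning upward, the chosen $K$ is the last
one whose improvement is at least 2% before the first failure. A
non-converged fit counts as a failure at that $K$. A guard errors if any
index is non-positive, where relative improvement would be meaningless.

**Entropy.** $1 - \sum_{ik}(-p_{ik}\ln p_{ik})/(n \ln K)$, defined as 1
when $K=1$; 1 means perfectly separated classes.

**Goodness of fit.** A parametric bootstrap of
$G^2 = 2(\ell_{\text{sat}} - \ell_{\text{model}})$, with the saturated
term computed over observed response patterns. The commercial variant of
this bootstrap is not documented publicly; the $G^2$ version implemented
here is the standard choice and is validated for calibration (p-values
spread over $(0,1)$ under the true model, collapse to 0 under gross
misfit) rather than against a printed value.

**Grouped weights.** The published analysis checked whether intake-year
cohorts or agencies improved the model. The multilevel parameterization
used there is not fully specified, so this package implements a documented
proxy: class weights $\pi_{gk}$ varying by group with shared $\theta$,
adding $(G-1)(K-1)$ parameters. Comparing BIC of grouped vs plain fits on
data simulated without group structure reproduces the published "no
substantive improvement" conclusion; a simulated group effect is detected.

## Missing data

Only the four intake scales enter the missing-data analysis — age and sex
come from administrative records and are complete by construction. The
published test had many more variables (its df implies interview
subscales, which are out of scope here), so its printed statistic is not a
benchmark; what is reproduced is the *conclusion* (non-random
missingness), which holds for the generator's missing-at-random mechanism
at the default sample sizes.

Little's test estimates the grand mean and covariance by EM under
multivariate normality and compares each missingness pattern's observed
means with the grand mean,
$\chi^2 = \sum_j n_j(\bar y_j - \hat\mu_j)^\top \hat\Sigma_j^{-1}(\bar y_j - \hat\mu_j)$,
$df = \sum_j p_j - p$. A ridge of $10^{-8}$ stabilizes pattern-level
inversions. Type-I error calibration is verified by simulation (rejection
rate within (0.03, 0.07) at $n=2000$ under MCAR). Imputation fills each
missing cell with its conditional mean under the final EM estimates;
observed cells are never altered. Single imputation is used deliberately,
matching the analysis being reproduced, and its RMSE advantage over
column-mean imputation is asserted in the tests.

## Discriminant function analysis

Predictors are sex (0/1, male = 1), age at index, and the four imputed
scales. The canonical directions are eigenvectors of $W^{-1}B$ (within-
and between-group scatter), scaled so canonical scores have pooled
within-group variance 1 with divisor $n-g$; standardized coefficients
multiply by pooled within-group SDs, and structure coefficients are pooled
within-group correlations between predictors and scores. Sequential Wilks
tests use Bartlett's $\chi^2 = -(n-1-(p+g)/2)\ln\Lambda_m$ with
$df=(p-m)(g-1-m)$; with 6 predictors and 5 groups this gives the published
24 and 15. Classification uses all $s=\min(p,g-1)$ functions with
proportional priors (equivalently, smallest squared canonical distance to
a centroid minus $2\ln\text{prior}$); whether the original analysis
classified on 2 or 4 functions is unstated, and using all functions is the
conventional default. Eigenvector signs are fixed so each function's
largest-magnitude standardized coefficient is positive. Leave-one-out
refits the model $n$ times. On synthetic intake covariates the
cross-validated accuracy lands in the mid-50s per cent against a 55%
largest-class base rate — bracketing the published ~51% without
reproducing it, as real-data accuracy depends on the real covariate
structure.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions.

* **Class weights** (0.532, 0.201, 0.079, 0.130, 0.058) for Minimal,
  Acute, Brief Episodic, Intensive, Ongoing/Intensive-Episodic.
* **Monthly profiles** are explicit 48-vectors of piecewise-constant
  segments — transparent to calibrate and exactly reproducible — pinned to
  the three published anchors (Ongoing month 11 = 0.63, Intensive month 21
  = 0.22, Brief Episodic month 21 = 0.08), with month 1 equal to 1 for
  every class. The Brief Episodic profile has an early bump and a second
  bump after a 14-month near-zero span, so segmentation yields two
  episodes for most of that class; the Ongoing profile stays at 0.63 for
  two years. Segment levels between the anchors are the package's own
  choices, shaped to the published episode narratives.
* **Visit volume.** Visits in an active month are $1 + \min(\text{Poisson}
  (\lambda_k), 20)$; $\lambda_k$ is solved so the expected 4-year total
  per class equals the published means (3.1, 15.6, 28.6, 32.6, 86.7). The
  truncation caps pathological months and keeps the active indicator
  honest.
* **Demographics.** Integer age-year from the published distribution
  (8, 10, 9, 11, 12, 12, 12, 13, 14 per cent for ages 5–13, renormalized)
  plus a uniform within-year day offset; per-class male proportions from
  the published pattern table.
* **Covariates.** Class-conditional multivariate normal with the published
  per-class means and SDs and an exchangeable correlation of 0.4 — the
  source reports no inter-scale correlations, so a single moderate value
  typical of these interview scales is used, chosen once.
* **Missingness.** Per-scale rates (0.003, 0.03, 0.08, 0.124); the two
  extreme values are published, the middle two are placeholders chosen
  once on that interval. The default mechanism makes the missingness
  probability of the other three scales rise with the child's
  Externalizing score through a logistic link (slope 0.06 per T-point,
  centered at T = 68), so Little's test rejects at the default sample
  sizes, mirroring the original conclusion.

What the generator does **not** emulate: agency- or intake-year-level
heterogeneity (none was found in the original analysis), non-face-to-face
contact streams beyond what the filter tests construct, within-child
autocorrelation of monthly activity beyond the class profile (months are
conditionally independent given class — exactly the LCA assumption), and
any real covariate-trajectory dependence beyond class membership. Passing
tests therefore demonstrate that the *methods* recover known structure
under the model's own assumptions — not that real service data satisfy
those assumptions.

## Numerical and design choices

* 18 months = 548 days; 6 months = 180 days; month bins of 365.25/12
  days. All date arithmetic is integer-day.
* EM convergence: relative log-likelihood change below $10^{-7}$ (plain)
  and $10^{-8}$ (polish); $\theta \in [10^{-6}, 1-10^{-6}]$.
* Modal assignment breaks posterior ties toward the lower (larger-weight)
  class index.
* Pattern *names* are assigned from descriptives, not class indices:
  lowest mean visits = Minimal, highest = Ongoing/Intensive-Episodic, a
  modal-"2+" middle class = Brief Episodic, the remaining two are Acute
  and Intensive by visit volume.
* The within-groups scatter must be numerically non-singular
  (`rcond >= 1e-12`); degenerate inputs are signaled, not silently
  regularized.
* Problem sizes in the scripts and tests — 3000 children for class
  discovery, 5000 for generator calibration checks, 1500 replications for
  the type-I simulation — were chosen once as the smallest sizes at which
  the quantities of interest are stable relative to their Monte-Carlo
  error.

## Known limitations

* The prior-episode exclusion interplay discussed above is an
  interpretation; anchoring that rule at the intake-window start instead
  would change which children it removes.
* The multilevel proxy varies class weights only; random-effect
  formulations could detect group structure in $\theta$ that this proxy
  cannot.
* Little's test and the imputation assume multivariate normality of the
  four scales; T-scores are approximately normal within class but the
  mixture across classes is not, and the test is applied to the pooled
  table as in the original analysis.
* Episode categories use three levels (0/1/2+); the underlying published
  test of episode counts appears to have used a finer categorization in
  supplementary material that is not reproduced here.

## A worked example

```{r example, eval = FALSE}
cfg <- default_config(n_children = 1500)
cohort <- sample_cohort(cfg, seed = 1)
res <- apply_filters(cohort$children, cohort$visits,
                     as.Date(c("2004-01-01", "2006-12-31")))
X <- trajectory_matrix(res$visits, res$index_dates)
sel <- select_num_classes(X, k_range = 2:7, n_starts = 10, seed = 1)
sel$chosen_k
fit <- sel$fits[[as.character(sel$chosen_k)]]
round(fit$model$pi, 3)
```

The numbered scripts under `analysis/` run the same stages end-to-end on a
3000-child cohort and write all tables under `results/`.
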