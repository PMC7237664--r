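---
title: "Nonlinear metabolite selection and kernel prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear metabolite selection and kernel prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Plasma metabolome profiles are a promising intermediate phenotype for
depressive symptoms, but two statistical obstacles stand between a table of
several hundred metabolite intensities and a usable prediction of a
depressive-symptom score: most features are useless or redundant
(mutually dependent metabolites add no information), and the informative
associations need not be linear — in particular, a feature whose effect on
the outcome is an even function of its level is invisible to every screen
built on correlation.

`hsiclasso` implements a pipeline built around nonlinear feature selection:
the Hilbert–Schmidt independence criterion (HSIC) Lasso screen, followed by
kernel ridge regression (KR) for quantitative scores or an RBF
support-vector machine (SVM) for binary traits, evaluated against a
registry of linear and nonlinear baselines under one shared three-level
nested cross-validation. Companion modules provide the cohort-comparison
statistics (pooled t tests, exact r×2 Fisher tests by hypergeometric
enumeration), selection-frequency marker summaries with covariate-adjusted
per-metabolite regressions, pairwise HSIC dependency tables, and a
synthetic cohort generator, since the motivating cohort data are not
publicly distributable.

# The HSIC Lasso screen

For one variable $u$ observed on $n$ subjects, let $K$ be its Gram matrix
under a kernel chosen by type: Gaussian
$K_{ij} = \exp(-(u_i-u_j)^2/2\sigma^2)$ on standardized values with
$\sigma = 1$ for continuous variables, and the class-frequency normalized
delta kernel $K_{ij} = 1/n_c$ (shared class $c$) for categorical ones. With
$\Gamma = I - n^{-1}\mathbf{1}\mathbf{1}^\top$, the empirical HSIC between
$u$ and $v$ is

$$\widehat{\mathrm{HSIC}}(u,v) = (n-1)^{-2}\,
  \mathrm{tr}(\Gamma K \Gamma \cdot \Gamma L \Gamma),$$

nonnegative, and zero in population exactly under independence. The screen
solves, over candidate features $k = 1,\dots,p$ (metabolites *and*
covariates),

$$\min_{\alpha \ge 0}\; \tfrac12 \Big\| \bar L - \sum_k \alpha_k \bar K^{(k)}
 \Big\|_F^2 + \lambda \sum_k \alpha_k ,$$

where $\bar K^{(k)}$ and $\bar L$ are centered and Frobenius-normalized
feature and outcome Gram matrices. Expanding the norm gives a nonnegative
lasso with $Q_{kl} = \langle \bar K^{(k)}, \bar K^{(l)}\rangle_F$ and
$c_k = \langle \bar K^{(k)}, \bar L\rangle_F$: features are rewarded for
dependency on the outcome ($c_k$) and penalized for dependency on each
other ($Q_{kl}$), so of a block of mutually redundant metabolites typically
only the strongest is selected.

Design choices worth stating:

* **Bandwidth convention.** Continuous variables are standardized and the
  bandwidth fixed at 1, the original convention for this screen; it is
  exposed as an argument but not tuned.
* **Normalization.** Centered Grams are Frobenius-normalized, which makes
  every non-degenerate feature's self-term $Q_{kk} = 1$ and the penalty
  scale comparable across features. The entries of $c$ are then
  normalized HSIC scores.
* **Solver.** Cyclic coordinate descent with the closed-form update
  $\alpha_k \leftarrow \max\{0, (c_k - \sum_{l\ne k} Q_{kl}\alpha_l -
  \lambda)/Q_{kk}\}$, run to a KKT residual below $10^{-8}$ (at most
  $10^4$ sweeps; non-convergence is flagged, not hidden). Coordinates
  whose converged weight is below $10^{-8}$ relative to the largest weight
  are cleared: the losing copy of an exactly duplicated feature otherwise
  survives as $10^{-17}$-scale round-off. The solver is checked in the
  test suite against an independent projected-gradient solve of the same
  quadratic program.
* **Requested feature count.** The tuned hyperparameter is the number of
  retained features $k$ (grid $\{5, 10, 15, 20, 30, 50\}$ by default), found
  by geometric bisection on $\lambda \in (0, \max_k c_k]$ with warm starts.
  If a count is skipped on the path (active sets need not hit every size),
  the largest active set not exceeding the request is returned with a
  warning. Ties in the reported ranking are broken by larger $c_k$, then
  column order. Note that even as $\lambda \to 0^+$ the nonnegativity
  constraint can pin coordinates at zero, so large requests may be
  unreachable on degenerate problems — this is reported, not silently
  padded.
* **Memory.** Gram matrices are built in feature blocks (64 by default) and
  reduced to $Q$ and $c$ blockwise, so the full set of $p$ matrices of size
  $n \times n$ is never held at once; at the design scale ($n \approx 900$,
  $p \approx 314$) peak use stays well under typical desktop memory.
* **Zero-variance features** are excluded with a warning rather than
  aborting the screen, since single degenerate columns are routine in
  split-sample workflows.

# Predictors

KR solves $(K + \lambda m I)\beta = y - \bar y$ on the RBF Gram of
training-standardized features and predicts
$f(x) = \bar y + \sum_i \beta_i k(x, x_i)$. The $\lambda m$ scaling makes
the penalty per-observation: replicating the whole training set leaves the
prediction function unchanged. Centering $y$ means a constant outcome is
reproduced exactly and predictions decay to the training mean far from the
data. The SVM is delegated to `kernlab::ksvm` (soft-margin C-classification,
RBF kernel), wrapped so real decision values — required for AUC — are
exposed, with orientation fixed on training data only.

Hyperparameter grids: $\sigma \in \{0.25, 0.5, 1, 2, 4\} \times$ the median
pairwise distance of the standardized training features;
$\lambda \in [10^{-4}, 10]$ and $C \in [10^{-2}, 10^3]$, log-spaced.
Standardization statistics and the median heuristic are computed on each
training fold only.

# The nested cross-validation

All subjects are randomly split into 5 roughly equal outer groups (sizes
differ by at most one; 897 subjects give 180/180/179/179/179). Each outer
training set is split again into 5 first-inner folds, and each first-inner
training set into 5 second-inner folds. For a two-stage model the
selector's grid is tuned in the first inner loop — each candidate count is
scored by selecting on the inner training set, tuning the predictor on the
second-inner folds, and evaluating on the held-out inner fold — and the
grid point with the best mean inner score wins. Features are then
re-selected on the full outer training set, the predictor grid re-tuned on
the first-inner folds, and the final model scored once on the untouched
outer test fold. Single-stage models tune everything in the first inner
loop; with all grids singleton the machinery reduces *exactly* to flat
5-fold cross-validation, and the test suite asserts that equality.

Every index touched by selection, standardization or tuning is recorded
per outer fold and checked to be disjoint from the test fold; the audit
result is part of the returned object. Binary traits use stratified folds
(per-class counts within one subject per fold) so no training fold loses a
class. Folds whose metric is undefined (constant predictions, or a class
absent) are recorded as `NA`, never as zero, to avoid biasing fold
summaries. Metrics are the Pearson correlation between predicted and
observed scores (PCC) and the Mann–Whitney AUC with ties counted half.

The baseline registry mirrors the standard lineup for this problem: lasso
(glmnet; $\lambda$ tuned in the first inner loop), KR/SVM without
selection, KR/SVM on features passing a covariate-adjusted $p<0.05$ screen,
KR/SVM on lasso-selected features, PLS and sparse PLS (native NIPALS; the
sparse variant soft-thresholds each direction vector by a fraction $\eta$
of its largest loading), random forest (500 trees, `mtry` by out-of-bag
error), and all-variable and covariates-only linear/logistic regressions.
Whether the $p<0.05$ screen adjusts for covariates is a switch
(`adjusted`, default `TRUE`).

# Exact Fisher tests

For an $r \times 2$ table the two-sided p-value follows the
probability-mass rule: the sum of point probabilities of every table with
the observed margins whose probability is at most $(1 + 10^{-7})$ times the
observed table's — the dominant convention in statistical software. The
enumerator (C++) walks the $r-1$ free cells of the first column with
feasibility pruning, accumulates per-table log-probabilities as sums of
row log-binomials minus the margin log-binomial, and asserts that the
enumerated probabilities sum to 1 within $10^{-9}$. A 5×2 table on ~900
subjects enumerates in seconds; a seeded Monte-Carlo fallback
(`fisher_rx2_mc`, built on `r2dtable`) with a Clopper–Pearson interval is
provided for tables beyond the enumeration budget. Note that some software
substitutes a chi-square approximation for large well-conditioned tables;
an exact enumerator deliberately does not, so its p-values can differ from
such output (e.g. 1.38×10⁻⁴ exact versus 8.8×10⁻⁵ approximate on one of
the reference tables) — the exact value is the one reported.
Summary-statistic t tests (pooled variance) are provided for continuous
rows; recomputing them from rounded group means/SDs drifts, so only
count-based rows anchor cross-checks.

# The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
not the biology: feature values are abstract intensities, never simulated
spectra.

* **Metabolites** are standard normal; redundancy blocks (10 blocks of 4 by
  default) share a latent factor so within-block pairwise correlation
  equals `block_correlation` (0.7 by default).
* **Covariates** mimic the target population's marginals: sex ~
  Bernoulli(0.57); age ~ N(57.7, 11.6); BMI ~ N(23.5, 3.6); marital status
  in {0..3}; house-damage category in {0..4} at the observed frequencies;
  antidepressant use ~ Bernoulli(0.01); two social-engagement scores.
  Categorical covariates are integer codes and use the delta kernel.
* **Outcome.** A latent score = intercept + covariate effects + Σ
  effect·g(z) + N(0, `noise_sd`), rounded and clipped to [0, 60]. Links g
  are drawn from {quadratic, sine, threshold, linear}, each standardized
  to zero mean and unit variance under N(0,1) inputs so that an effect
  size is the latent-SD contribution per causal feature regardless of link
  shape; the default cycle always includes the purely even quadratic link,
  which correlation-based screens provably miss. With the defaults
  (5 causal features, effect 3, noise SD 5) the latent outcome SD is ≈ 8.4,
  matching the real score scale. When `intercept` is `NA` it is set so the
  empirical prevalence of scores ≥ 16 matches 298/897.
* **Exclusions.** Missing-outcome and unreliable-answer flags are
  independent Bernoulli draws (only marginal counts are known for the
  motivating cohort; the actual unreliability criteria are not public, so
  unreliability is modeled as a random flag only). `apply_exclusions`
  removes the union, listwise; no imputation.

What passing tests on these cohorts shows — and what it does not: the
machinery recovers planted sparse nonlinear signal, suppresses redundant
copies, and respects the cross-validation protocol. It does not show that
real metabolome data carry comparable signal; the synthetic
signal-to-noise regime is deliberately strong enough for recovery to be
assessable at desk scale, which is far more predictable than real cohorts.
Published predictive correlations on real data are therefore not
reproduced here and no such claim is made.

# Fixed simulation studies

Two study designs are frozen in the package so every consumer measures the
same thing:

* **Recovery study** (`recovery_config`): n = 400, p = 100, five causal
  features with links quadratic/sine/threshold/linear/linear (exactly one
  pure x² and one sine), no covariate effects. Measured over 20 seeds: how
  often the 10-feature screen recovers ≥ 4 of 5 planted features, and how
  often it captures the x² feature versus a 10-feature lasso screen. The
  sine link is deliberately retained although it sits near the HSIC
  detection boundary at this sample size (its fast oscillation is at the
  edge of what a bandwidth-1 Gaussian kernel resolves); the ≥ 4-of-5
  criterion tolerates missing it.
* **Prediction study** (`prediction_study`): the full default cohort
  structure at n = 300, p = 60 with compact grids (k ∈ {5, 10}; σ
  multiplier ∈ {0.5, 1, 2}; λ ∈ {0.01, 1}), comparing HSIC Lasso + KR
  against the lasso on identical fold plans, paired over 20 seeds. The
  reduced scale keeps a 20-seed replication within minutes while
  preserving the qualitative design; grids were fixed before measurement
  and are deliberately small rather than exhaustive.

# Numerical and degenerate-input policy

* Coordinate-descent KKT tolerance 10⁻⁸, max 10⁴ sweeps, warm starts along
  the penalty path; sub-tolerance weights cleared (see above).
* HSIC of any constant variable is exactly 0 (its centered Gram is the
  zero matrix); constant variables never error out of `hsic_statistic`,
  but do error out of Gram construction when standardization is requested.
* `pcc`/`auc` return `NA` with a warning on undefined inputs (constant
  vector; single class); the harness propagates the `NA`.
* Fisher tests on tables with an empty margin return p = 1 (single
  possible table), with a message.
* Collinear covariate-adjusted regressions are flagged (`ok = FALSE`)
  rather than reporting an arbitrary coefficient.
* All randomness flows from explicit seeds: the fold plan from its `seed`
  argument, cohorts from `config$seed`, random-forest fits from a seed
  derived from the plan.

# Known limitations

* The SVM stage exposes decision values, not calibrated probabilities.
* The HSIC estimator is the biased V-statistic form; no permutation
  p-values are attached to dependency tables (raw statistics only, scaled
  by a readability constant, 10³ by default).
* The selection-frequency consistency threshold defaults to ≥ 4 of 5
  outer folds in both outcome branches; it is exposed because reasonable
  conventions differ on whether "more than four" includes four.
* Neural-network baselines are out of scope; random forest is the
  delegated nonlinear no-selection baseline.
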