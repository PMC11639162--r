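---
title: "Selecting microbiome balances for censored survival outcomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting microbiome balances for censored survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survbalance)
```

## The problem

Microbiome profiling yields *compositional* data: sequencing depth is
arbitrary, so a sample's counts carry only relative information. Any
statistic used as a regression feature should therefore be invariant to
per-sample rescaling. Log-contrasts — linear combinations of log relative
abundances whose coefficients sum to zero — are the canonical such
statistics, and a *balance* is the special log-contrast that summarizes
the antagonism between two disjoint groups of taxa:

$$
B_i \;=\; \sqrt{\frac{k_+ k_-}{k_+ + k_-}}\;
\log\frac{\big(\prod_{j\in I_+} X_{ij}\big)^{1/k_+}}
         {\big(\prod_{j\in I_-} X_{ij}\big)^{1/k_-}}
\;=\; \sqrt{\frac{k_+ k_-}{k_+ + k_-}}
\Big(\tfrac{1}{k_+}\sum_{j\in I_+}\log X_{ij}
  - \tfrac{1}{k_-}\sum_{j\in I_-}\log X_{ij}\Big),
$$

the normalized log-ratio of the geometric means of the plus set $I_+$
($k_+$ taxa) and the minus set $I_-$ ($k_-$ taxa). Natural logarithms are
used throughout. `compute_balance()` evaluates the mean-log form — never
the product form, which underflows — and accepts un-closed positive
matrices precisely because the statistic is scale-invariant.

This package selects the pair $(I_+, I_-)$ whose balance is most
associated with a right-censored time-to-event outcome, under one of two
survival models:

* **Cox proportional hazards**:
  $h(t \mid B_i, Z_i) = h_0(t)\exp\{\gamma B_i + Z_i^\top\beta\}$,
  estimated by partial likelihood (Efron ties by default, Breslow
  selectable). The plus set is oriented to be *hazard-increasing*
  ($\hat\gamma \ge 0$).
* **Weibull AFT** (and optionally log-normal / log-logistic):
  $\log T_i = \mu + \gamma' B_i + Z_i^\top\beta' + \sigma\epsilon_i$ with
  extreme-value errors. The plus set is oriented to be
  *survival-time-increasing* ($\hat\gamma' \ge 0$).

In both cases the selection-facing p-value is the 1-df likelihood-ratio
test of the balance effect against the covariates-only null; the Wald
standard error is reported alongside.

## Greedy search

The space of balances is exponential in the number of taxa, so the search
is greedy:

1. **Initialization** (`initialize_pair()`): every unordered pair of taxa
   is fitted as a 1-vs-1 balance and the pair with the largest model
   log-likelihood wins. Swapping the two sides negates the balance and
   the effect estimate but leaves the likelihood unchanged, so only
   unordered pairs need fitting; the reported orientation is restored
   afterwards.
2. **Growth** (`greedy_grow()`): at each step every unused taxon is tried
   on each side; the single best addition is accepted if it improves the
   log-likelihood by more than `tol`. Ties break to the plus side first
   and then to the lowest taxon index. Candidate fits that fail to
   converge (including monotone-likelihood separations) are skipped.
3. **Stopping**: no addition clears `tol`, the balance reaches
   `max_taxa`, or taxa are exhausted.

The defaults `tol = 2` (about the AIC penalty for one
parameter-equivalent, preventing unbounded growth) and `max_taxa = 15`
were fixed a priori; the exact stopping rule of comparable balance
selectors varies, and both knobs are exposed. An optional k-fold
cross-validation (`cv_folds`, default off, 5 folds when on) picks the
balance size instead: the selection is re-run on the training folds, the
trained balance spec is re-fitted on each held-out fold, and the smallest
size whose mean held-out log-likelihood is within one standard error of
the best is kept — the usual 1-SE parsimony rule. Randomness enters only
through fold assignment and the permutation test, controlled by a single
seed.

Greedy search has no optimality guarantee. The acceptance suite checks it
against exhaustive enumeration over all balances with at most two taxa a
side on strong-signal simulations, requiring the greedy criterion within
2% of the enumerated optimum in at least 95% of replicates. (A note on
that band: the criterion is a negative log-likelihood, so the comparison
is implemented as a relative gap $|\ell^* - \ell_{greedy}| \le
0.02\,|\ell^*|$ — a literal "$\ge 0.98\,\ell^*$" is unsatisfiable for
negative $\ell^*$.)

## The community-level gate

A greedy selector always returns *some* balance, even from pure noise.
Before selecting, the package therefore runs a community-level kernel
association test in the MiRKAT-S style:

* **Distances**: Bray-Curtis on the composition closed *without*
  pseudocount (true zeros preserved — pseudocount inflation distorts
  ecological distances) and Jaccard on raw presence/absence
  (count > 0). The composition used for balances, which needs strict
  positivity, is a separate object.
* **Kernels**: Gower centering $K = -\tfrac12 J D^{\circ 2} J$, negative
  eigenvalues clipped to zero.
* **Statistic**: $Q = r^\top K r$, with $r$ the martingale residuals of
  the covariates-only Cox null model (with no covariates this is the
  Nelson-Aalen reduction).
* **P-values**: residual permutation with the $(b+1)/(B+1)$ estimator,
  $B = 999$ by default; the same permutations are reused across kernels
  so their dependence is preserved. Permutation replaces the original
  analytic small-sample approximations deliberately: it is exact under
  exchangeability and has no numerical edge cases.
* **Omnibus**: the Cauchy combination (ACAT) of the per-kernel p-values;
  identical inputs are a fixed point, and the combination is invariant
  to kernel order.

If the omnibus p-value is at or above `alpha` (default 0.05), a
**caution flag** is set and a warning is emitted; selection still
proceeds. The two analyses answer different questions — the kernel test
detects concerted shifts across many taxa, balance selection targets an
imbalance in a few — so an insignificant global test does not invalidate
a selected balance, it only cautions against over-interpreting it.

## Preprocessing conventions

* Taxa are filtered on **mean relative abundance** (mean over samples of
  count/sample total, computed on raw counts): `remove_rare` drops taxa
  strictly below the threshold (e.g. 0.01%), `keep_common` keeps taxa
  strictly above it (e.g. 1%). Strict inequalities match the
  conventional "<"/">" phrasing; at least two taxa must survive.
* Zeros are replaced by an **additive pseudocount** (default 0.5) on all
  counts before closure — deterministic, rank-preserving, and
  dependency-free, unlike Bayesian-multiplicative replacement. The value
  is configurable; `pseudocount = 0` is allowed for already-positive
  input, where closure is exactly scale-invariant.
* Taxonomic aggregation (e.g. to genus) is the user's responsibility
  upstream.

## The synthetic-data generator

`simulate_dataset()` powers every test. It draws a latent per-sample
composition from a Dirichlet distribution, counts from a multinomial at
fixed depth (the standard Dirichlet-multinomial microbiome family), and
survival times driven by the *latent* balance, so the planted truth is
exact while the pipeline sees only counts — exercising the full
pseudocount-and-closure path. Event times come from a Weibull baseline
hazard scaled by $e^{\gamma B}$ (Cox mode, inverse-transform) or from
the log-linear AFT equation with extreme-value noise (Weibull mode);
censoring times are uniform on $(0, c)$ with $c$ solved numerically so
the expected censored fraction matches the target.

Defaults describe a modest 16S study chosen once and kept: $n = 100$
samples, $K = 20$ taxa, depth 10000, symmetric Dirichlet concentration
0.5 (sparse, overdispersed profiles), a planted 1-vs-1 balance with
$\gamma = 1.5$ (a strong, detectable effect), 20% censoring. What the
generator does **not** emulate: phylogenetic correlation between taxa,
zero-inflation beyond multinomial sampling, batch effects, longitudinal
sampling, or covariate-microbiome confounding. A green simulation-based
test therefore establishes internal correctness of the estimator and
search under the stated generative family, not performance on any
particular real cohort.

## Numerical choices

* Model fitting is delegated to the `survival` package (`coxph`,
  `survreg`); the test suite checks it against independent oracles — a
  brute-force grid maximization of the written-out Breslow partial
  likelihood and a direct two-parameter Weibull MLE.
* The LRT statistic is floored at 0 before the $\chi^2_1$ tail call
  (round-off can make it marginally negative).
* Kernel PSD-ness is enforced by eigenvalue clipping at 0; the test
  tolerance for the minimum eigenvalue is $-10^{-10}$.
* Quartiles for stratified survival curves use the linear-interpolation
  convention (`quantile` type 7), so the balance vector $(1,2,3,4)$
  yields $Q_1 = 1.75$, $Q_3 = 3.25$.
* Curves are evaluated at the covariate means by default; for a binary
  covariate of interest (`by_covariate`) one curve set per level is
  rendered instead.
* Pipeline reports are JSON with fixed numeric formatting, so identical
  configuration and seed reproduce the report byte-for-byte.

## Known limitations

* Greedy search can miss jointly-optimal sets that no single-taxon
  addition reaches; the exhaustive-oracle acceptance check quantifies
  this on small problems only.
* The community test's permutation null assumes exchangeable residuals;
  heavy covariate-driven censoring patterns are only partially absorbed
  by the null Cox model.
* Competing risks, time-varying covariates, stratified baselines,
  regularized (lasso-type) log-contrast selection and phylogeny-aware
  kernels (UniFrac) are out of scope.
* With small cohorts the selected taxa lists are unstable; the caution
  flag and the step trace (`trace_table()`) should be read together
  before interpreting individual taxa.
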