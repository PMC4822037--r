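---
title: "An integrative screen for angiogenesis-regulating miRNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrative screen for angiogenesis-regulating miRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiomir)
```

## The problem

Tumour angiogenesis — the recruitment of new blood vessels — is a hallmark of
aggressive disease in high-grade serous ovarian carcinoma and clear-cell renal
carcinoma, and microRNAs that suppress it paracrinely are candidate
therapeutics. Identifying such miRNAs from patient data requires combining
several weak, noisy signals: vessel counts in stained tumour sections
(microvessel density, MVD), tumour expression of pro-angiogenic factors,
miRNA abundance, and overall survival. `angiomir` implements that integration
as a tested pipeline: a per-sample pro-angiogenic signature score, a
median-decrease differential filter between MVD extremes, Spearman
association layers, an optimal-percentile Kaplan–Meier cutpoint scan, a
transcription-factor/target intersection cascade, and a random-walk network
relevance scorer — together with a seeded synthetic cohort generator so that
every stage can be validated against planted ground truth.

## The signature score

For a panel of $N$ pro-angiogenic genes, each sample $s$ receives

$$\mathrm{score}_s \;=\; \frac{1}{N} \sum_{n=1}^{N} g_{n,s},
\qquad
g_{n,s} = \begin{cases} +1 & x_{n,s} > \mathrm{median}_s(x_{n,\cdot}) \\
-1 & \text{otherwise,} \end{cases}$$

where the median is taken across **all** samples in the matrix passed in, and
is recomputed whenever the sample set changes. Scores lie in $[-1, +1]$ and
$N\cdot\mathrm{score}$ is an integer with the parity of $N$. Two conventions
are deliberate:

* **Ties map to $-1$**: "otherwise" includes equality with the median, so a
  constant gene contributes $-1$ everywhere rather than a coin flip.
* **Even-sample medians** are the mean of the two central order statistics
  (the conventional sample median).

Because the score depends on the data only through within-gene ranks, it is
invariant under any strictly increasing per-gene transform — normalization
choices that preserve ranks cannot change it. The panel is treated as
uniformly pro-angiogenic (+ orientation); `select_consistent_genes()`
restricts it to genes present in the matrix and above an expression floor in
at least 80% of samples by default, because "consistently expressed" needs a
quantitative rule and that threshold is configurable and logged.

## The MVD median-decrease screen

Tumours are grouped by vessel counts per high-power field with **strict**
inequalities (high: $>36$, low: $<16$; boundary samples excluded), and a
miRNA passes when its median expression in the high-MVD group is less than
$1 - 0.8 = 0.2$ times its low-group median — a strictly-more-than-80%
decrease of group medians. We read the decrease on the ratio of group
medians rather than as a median of per-pair decreases because the groups are
unpaired. The screen is scale-invariant (multiplying all counts by a
positive constant changes no flag), is deliberately normalization-agnostic,
and also offers a total-count scaling mode for callers who want medians
reported on a library-size-adjusted scale. A miRNA whose low-group median is
zero has an undefined decrease and never passes; it is reported, not
dropped.

## Association layers

All correlation layers use Spearman's rank correlation with mid-ranks on
ties and a two-sided p-value from the $t$ approximation on $n-2$ degrees of
freedom (an exact permutation p is available for $n \le 9$). Constant
vectors yield a flagged-undefined result rather than a silent `NaN`.
`correlate_with_score()` ranks miRNAs by most-negative rho with
lexicographic tie-breaks and carries a nominal $p < 10^{-4}$ shortlist flag;
Benjamini–Hochberg q-values are reported alongside nominal p-values.
Methylation and copy-number layers share one per-track routine: probes with
fewer than three complete pairs are reported as skipped.

## Survival: Kaplan–Meier, log-rank, and the cutpoint scan

`km_estimate()` wraps the product-limit estimator (censored records tied
with an event time remain at risk for that event). The log-rank statistic is
computed by a vectorized observed/expected/variance engine over distinct
event times — written in-package so that the cutpoint scan and its
permutation adjustment stay tractable — and is cross-checked in the test
suite against both `survival::survdiff` and an explicit-loop oracle.

`cutpoint_scan()` dichotomizes the marker at every percentile from 0.25 to
0.75 in steps of 0.01 (51 splits), using linear-interpolation quantiles
(R's type 7) with samples at the quantile going to the low group, and
returns the split with the smallest nominal log-rank p (ties broken toward
the smaller percentile). Minimum-p selection over 51 correlated tests is
anti-conservative: under the null the nominal optimum falls below 0.05 far
more than 5% of the time. The scan therefore reports the nominal minimum p
as primary — matching how such scans are conventionally reported — and
optionally a permutation-adjusted p (marker values permuted against the
survival records, the whole scan re-run, default 1,000 permutations), which
is calibrated under the null. The two are never silently substituted for
one another.

## The transcription-factor cascade

Starting from tables of predicted TF–promoter bindings (position-weight-
matrix matrix-similarity scores in $[0,1]$) and of miRNA–target predictions
by named algorithms, the cascade keeps TFs predicted to bind **strictly more
than** `min_genes` (default 5) panel-gene promoters at score $\ge$
`min_score` (default 0.9), then keeps those predicted as direct targets of
the miRNA by **at least** `min_algorithms` (default 4) distinct algorithms.
Both boundaries are exactly as stated and unit-tested; duplicate (TF, gene)
rows collapse to their maximum score. Raising any threshold can only remove
candidates, and row order never matters. A single-promoter scan (e.g. TFs
binding one miRNA's promoter at cutoff 0.95) is the same operation with
`min_genes = 0` and a one-gene panel. The upstream prediction engines are
consumed as plain tables: their counts are database-version-dependent, so
this module's guarantees are stated on planted synthetic truth, where the
cascade attains sensitivity and specificity 1 by construction.

## Random-walk network relevance

Node data values (strictly positive weights) define the walk: from node $i$
the walk steps to neighbour $j$ with probability
$v_j / \sum_{k \in N(i)} v_k$. A node's relevance is its stationary
visitation frequency, computed by power iteration to an L1 residual below
`tol` (default $10^{-10}$); an edge's relevance is the stationary flux
$\pi_i P_{ij} + \pi_j P_{ji}$ on the neighbour-following kernel, normalized
to sum to one. Numerical choices:

* **Periodicity guard**: with no restart, a lazy-walk stay probability of
  0.01 is mixed in so bipartite graphs converge; laziness leaves the
  stationary distribution unchanged and is reported in the metadata.
* **Restart distribution** (when `restart > 0`) is data-value-proportional,
  consistent with values acting as transition probabilities; this also
  covers disconnected graphs.
* **Non-positive data values** are floored to $10^{-6}$ of the positive
  median with a warning.

This is a faithful-in-spirit implementation of visitation-frequency scoring
as commonly described for network-analysis tools; exact numeric parity with
any specific third-party implementation is not claimed. How node values
should be derived from expression data (fold change, signed log-ratio, ...)
is left to the caller: any positive value column is accepted.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the
package's reference study conditions. A standard-normal latent angiogenic
activity $A_s$ drives every layer:

| layer | model | default |
|---|---|---|
| panel gene $g$ | $\mu_g + \beta_g A_s + \mathcal N(0,\sigma)$ | 20 genes, $\beta=1$, $\mu=8$, $\sigma=1$ |
| planted miRNA | counts: $\mathrm{NB}(\mathrm{mean}=e^{\nu - \gamma A_s},\ \mathrm{disp})$ | $\gamma=0.8$, $\nu=\log 500$, disp 0.2 |
| null miRNAs | same with $\gamma = 0$ | 50 |
| vessel count | $\mathrm{Poisson}(e^{\alpha_0 + \alpha_1 A_s})$ | $\alpha_0=\log 24$, $\alpha_1=0.5$ |
| event time | $\mathrm{Exp}(h_0 e^{\theta A_s})$ | $h_0=0.1$, $\theta=0.8$ |
| censoring | $\min(\mathrm{Exp}(c),\ T_{\max})$ | $c=0.01$, $T_{\max}=15$ |
| methylation | $\mathrm{logit}^{-1}(\delta_0+\delta_1 A_s)$ + bounded noise, clipped to $[0,1]$ | 4 planted probes, $\delta_1=1$ |

Rationale for the forms: linear-Gaussian for expression, log-linear Poisson
for vessel counts and proportional-hazards exponential survival are the
simplest models consistent with the monotone relationships the screen
assumes (activity ↔ MVD ↔ survival), are identifiable at small $n$, and
admit closed-form expectations for tests. Specific defaults: $\alpha_0 =
\log 24$ and $\alpha_1 = 0.5$ centre vessel counts near 24/HPF with enough
spread that a 400-sample cohort yields substantial groups beyond both the
36 and 16 vessels/HPF cutoffs; the censoring rate was calibrated by
simulation to approximately 30% censored records, a typical fraction for
mature survival cohorts; the negative-binomial dispersion 0.2 gives
counts overdispersed at roughly the level of replicate digital-counting
data. miRNAs default to count mode because the screen consumes counts;
a Gaussian mode is also provided since expression may equally arrive from
array platforms, and the rank-based stages are indifferent to the choice.

Every component (latent activity, mRNA, miRNA, MVD, survival, methylation)
draws from its own sub-stream, seeded deterministically from the base seed
and the component name — so adding or resizing one component never perturbs
another's draws, and identical configs give bit-identical cohorts.

What the generator does **not** emulate: probe chemistry and platform
normalization, batch effects, tumour purity/stromal contamination,
copy-number structure, and any dependence structure beyond the single
latent factor. Passing tests on these cohorts therefore demonstrate the
correctness and calibration of the pipeline's statistics under the assumed
monotone single-factor structure — not robustness to the full messiness of
clinical multi-omic data.

A separate two-group count generator (`generate_nanostring_counts()`)
produces digital-counting-style fixtures for the screen, with planted
decrease fractions; `synthetic_supplementary_counts()` is one fixed,
documented instance — 24 samples, 250 probes, 13 planted strong (95%)
decreases — used as the package's reference screen fixture. It is a
constructed synthetic object, not measured data.

## The orchestrated pipeline

`run_screen()` composes: median-decrease screen → score correlation on the
screen survivors (direction of interest configurable: `down` by default,
since the screen targets miRNAs lost in highly angiogenic tumours) →
cutpoint scan on the correlation survivors, with an optional TF cascade.
Stage thresholds default to the printed conventions above and are all
overridable. An optional `require_protective` flag additionally demands
that the flagged split's high-expression arm have the better
restricted-mean survival — off by default, since a direction-of-effect rule
is an analysis choice, not part of the scan. The report records every
threshold beside the count it produced, and serializes byte-identically for
identical inputs (no timestamps), so report counts can always be reconciled
against the per-stage TSVs.

## Problem sizes used by the test suite

The suite validates: the score against a brute-force oracle on 1,000 random
matrices (up to 20×50); the log-rank engine against `survdiff`, an explicit
O/E/V loop, and 4,000-permutation oracles on 20 datasets of 16–24 subjects
(sizes at which the $\chi^2_1$ reference is expected to be adequate); scan
null calibration on 200 replicate 60-sample cohorts with 200 permutations
each; planted-miRNA recovery on 100 replicate 400-sample cohorts; the
random-walk scorer against dense eigen-decompositions on 20 random 8-node
graphs; and quantile normalization idempotence on 500 random matrices.
These sizes are the package's chosen trade-off between statistical
resolution and a test suite that runs in a couple of minutes.

## Known limitations

* The screen's discovery guarantees are stated on the synthetic
  single-latent-factor model; real cohorts violate it in ways the tests do
  not probe (see above).
* The nominal minimum-p of the cutpoint scan is intentionally reported as
  primary despite its anti-conservatism; users who need calibrated error
  rates must use the permutation-adjusted p and pay its computational cost.
* Multivariate survival adjustment (Cox regression over clinical
  covariates) is out of scope; the clinical table carries covariates so
  standard tools can consume it.
* The TF cascade inherits whatever biases its input prediction tables
  carry; it guarantees only the set algebra applied to them.
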