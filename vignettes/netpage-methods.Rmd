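---
title: "Network propagation-based association testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network propagation-based association testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpage)
```

## The problem

Rare deleterious variants carry large per-allele effects but are, by
definition, observed in few subjects, so the subject × gene matrix of
rare-variant carriers is extremely sparse and single-gene burden tests are
underpowered at realistic cohort sizes. At the same time, a deleterious
coding variant does not act in isolation: its impact spreads through the
protein's functional interactions, so variants in *different* genes across
*different* subjects can converge on the same neighbourhood of an
interaction network. This package implements a gene-based association test
built on that observation: the rare-variant signal is smoothed over a
tissue-specific gene-interaction network before being tested, so a gene's
score reflects rare variation in its whole functional neighbourhood.

## The diffusion model

Let $G^0 \in \mathbb{R}^{S \times M}$ be the subject × gene burden matrix
and $N \in [0,1]^{M \times M}$ the symmetric weight matrix of the gene
network. With $D$ the diagonal matrix of inverse node strengths, the
smoothing operator is the row-stochastic product $DN$, and the smoothed
scores are the limit of

$$G^{t+1} = \alpha\, G^t (D N) + (1-\alpha)\, G^0 ,$$

iterated from $G^0$ until $\lVert G^{t+1} - G^t \rVert_2 < \text{tol}$.
The diffusion length $\alpha \in [0,1]$ mixes network-smoothed signal with
the original burden: $\alpha = 0$ performs no propagation (the package
returns $G^0$ bit-identically), and larger values let signal travel
further. For $\alpha < 1$ the update is a contraction (the operator is
row-stochastic), so the iteration converges geometrically to the unique
fixed point

$$G^{*} = (1-\alpha)\, G^0 (I - \alpha D N)^{-1},$$

which `closedFormPropagate()` computes by a direct solve and which serves
as the package's internal oracle: the test suite checks the two routes
against each other on hundreds of random problems.

Numerical choices worth stating explicitly:

* **Norm.** Convergence is declared on the Frobenius norm of the whole
  $S \times M$ iterate difference — a global criterion, stricter than any
  per-row test.
* **Multiplication side.** The update *right*-multiplies by $DN$: the mass
  a subject holds in gene $j$ is pushed along row $j$ of the operator.
  Since $DN$ is not symmetric, the side matters; the worked example in
  `?propagateBurden` pins the convention down.
* **Isolated genes.** Genes with strength zero keep all-zero operator
  rows. They neither receive nor emit signal, but their columns stay in
  place so the burden and the operator always share one gene order (the
  functions refuse to run otherwise).
* **Iteration cap.** `maxIters` defaults to 1000; if it is hit (only
  realistically possible at $\alpha = 1$) the result is flagged
  non-converged and a warning raised — an unconverged matrix is never
  returned silently.
* **Dense vs sparse.** The same update runs on dense or sparse
  representations depending on burden density; the two paths are tested to
  agree to $10^{-10}$.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | diffusion length; mid-range, since hub-score separation is largely insensitive to it (see below) |
| `tol` | 1e-6 | Frobenius-norm convergence threshold |
| `topPct` | 1 | percentage of highest-weight edges kept by binarization |
| `quantileNormalize` | off | equalize per-subject score distributions after convergence |

Binarization keeps exactly $\lceil P/100 \cdot E \rceil$ of the $E$
nonzero undirected edges — a percentage of *existing* edges, not of all
$M(M-1)/2$ pairs, which would retain far more than the name suggests. The
ceiling guarantees a nonempty graph for any $P > 0$, and ties at the cut
weight break lexicographically so the result is reproducible. After
binarization node strength equals degree, so the operator built from the
binarized matrix is the degree-normalized adjacency.

Row-wise quantile normalization (each subject's row mapped onto the mean
order statistics across subjects, ties sharing the mean of their target
values) is provided because some propagation pipelines equalize patient
score distributions this way, but it is **off by default**: in the
simulation study below it erodes exactly the case/control difference in
the hub score that the method is designed to detect.

## Effect orientation

A deleteriousness score such as CADD is phenotype-agnostic: a gene's rare
variants can raise or lower disease risk. Because propagation is linear,
mixing unsigned risk and protective signals in one neighbourhood blends
them away. `orientEffects()` therefore calls a direction per gene from the
odds ratio of the carrier × case 2×2 table (OR > 1 risk, OR < 1
protective) and, in `signed` mode, stores risk carriers as $+1$ and
protective carriers as $-1$. Conventions: zero cells get the
Haldane–Anscombe 0.5 correction (for direction calling only, never for a
reported effect size); an OR of exactly 1, an all-carrier or a no-carrier
gene leaves the column unchanged and flagged `undetermined`; the direction
uses the OR only, not the Fisher p-value. Orientation is computed on the
phenotyped subjects but applied to every row, since propagation typically
runs on the full cohort while selection uses the case/control subset. The
operation assigns signs to magnitudes (protective $\to -|v|$) rather than
multiplying by $-1$, so applying it twice is a no-op.

## Sparse selection with stability selection

Smoothed scores are related to case/control status by L1-penalized
logistic regression (fitted by glmnet; intercept unpenalized, columns
standardized) over a 50-point penalty grid log-spaced from the data-driven
$\lambda_{\max}$ down to $0.01\,\lambda_{\max}$. Stability selection runs
100 class-stratified split-half resamples; a gene's selection probability
at $\lambda$ is the fraction of resamples giving it a nonzero coefficient,
and genes whose maximum along the path reaches 0.80 are selected.
Split-half subsampling *without* replacement is used (that is what the
stability-selection estimator is defined on), stratified by class so every
fit sees both outcomes. Covariates stay out of the sparse model; they
enter only in the downstream model comparison.

One design point deserves emphasis. Selections are counted only while a
fit's active set has at most $q$ = `maxSupport` genes. Restricting the
regularization region this way is the standard device that gives the
0.80 threshold its error control: the expected number of falsely
selected genes is bounded by $q^2/((2\pi_{thr}-1)M)$. The default
inverts that bound at a per-family error target of 0.5 expected false
selections, $q = \lfloor\sqrt{(2\pi_{thr}-1)\,M\cdot 0.5}\rfloor$
($q = 12$ at $M = 500$), so that spurious selections are expected well
under once per analysis — the calibration the selection stage is
designed around. The cap is not optional in practice: on pure-noise data
the greedy end of an unrestricted path selects large supports whose
strongest fixed-sample noise correlations recur across half-samples,
pushing noise genes above 0.80. With the cap in place, the package's
calibration tests show zero selections on null data (400 subjects × 500
genes) while a single gene shifted by one pooled standard deviation in
cases is selected with probability ≈ 1; power is unaffected because a
genuinely associated gene enters the path among the first few
coefficients.

Two probability-counting modes exist because a 0.80 threshold can be
crossed at granularity $1/n$ (plain; default) or $1/(2n)$ (complementary
pairs, both halves of each split). Plotted trajectories
(`stabilityPaths()`) are running maxima over decreasing $\lambda$, the
usual stability-path display convention; raw per-$\lambda$ values are
retained in the result object.

## The simulation framework

`simulateCohort()` plants the statistical structure the method is meant to
exploit: an **unmutated** hub gene whose first (`n1 = 10`) and/or second
(`n2 = 50`) network neighbours carry variants with frequency `fCase` in
cases and `fControl` in controls, independently per subject and per gene
(three scenarios: first ring, second ring, both). The default desk-scale
cohort is 200 cases and 200 controls with 20 replicates per parameter
cell — sizes chosen so a full frequency × $\alpha$ sweep runs in about a
minute while keeping the per-cell Monte-Carlo error of the median p-value
small. `parameterSweep()` then measures, per cell, the separation of the
hub's smoothed score between cases and controls with a two-sided
Wilcoxon rank test (rank-based because smoothed-score distributions are
strongly non-normal mixtures; a t-test is available behind a flag),
Bonferroni-corrected by the number of cells in the sweep.

The qualitative pattern this reproduces: equal neighbourhood frequencies
give no detectable hub difference; differential frequencies (e.g. 0.5 vs
0.05) always flow into the unmutated hub and separate the classes; and the
result is insensitive to $\alpha$ over a sizable mid-range — the package's
acceptance checks verify the median $-\log_{10} p$ varies by less than an
order of magnitude across $\alpha \in \{0.25, 0.5, 0.75\}$.

What the generator deliberately does **not** emulate: linkage
disequilibrium and haplotype structure, relatedness, per-gene variant
counts beyond presence/absence, covariate confounding, and the heavy-tailed
degree distribution of real interactomes (the fixture is a clean two-tier
star; `random_weighted` graphs are Erdős–Rényi). Passing tests therefore
demonstrate correctness of the machinery and calibration under the planted
model, not performance on real cohorts.

## Downstream characterization

* `compareModels()` — likelihood-ratio $\chi^2$ (1 df) of a baseline
  covariate model against the same model plus one smoothed gene score,
  with McFadden pseudo-$R^2$ for both; Bonferroni-multiplied by the number
  of genes compared (default: the selected set, configurable — the
  multiplier choice is a user decision, not derivable from the data).
* `neighbourOverlapTest()` — is a selected gene set overrepresented within
  radius 2 of a seed gene? Null: uniform random sets of the same size from
  the tested-gene universe; 10,000 draws by default.
* `enrichmentTest()` / `enrichmentRandomization()` — one-sided Fisher
  exact overrepresentation per annotation set (GMT input), BH-adjusted at
  FDR 5%, with a 1,000-draw randomization control that re-tests random
  query sets of the same size.

All empirical p-values use the $+1$ correction,
$p = (1 + \#\{null \ge obs\})/(n_{draws}+1)$: they are floored at
$1/(n_{draws}+1)$ and can never be zero, which is why extreme results are
reported as "$p < 1/(n+1)$" rather than 0.

## Degenerate inputs and tie-breaks, collected

* Duplicate edges in an edge list: maximum weight wins, with a warning
  (conservative for probabilistically weighted evidence).
* Self-loops: dropped by default; kept on request and then excluded from
  the top-edge ranking's symmetrization concerns.
* Binarization ties: lexicographic (geneA, geneB) order at the cut.
* Edge-swap randomization: swaps creating self-loops or duplicate edges
  are rejected, so the degree sequence is preserved *exactly*; the default
  attempt count is $10E$, a common mixing heuristic.
* Constant hub scores in the rank test: p = 1 by convention.
* Perfect separation in the logistic comparison: flagged, p reported as a
  machine-precision bound with a warning.

## Problem sizes used by the test suite

The oracle-equivalence checks use 100 random networks with up to 50
genes; the calibration study uses 20 independent runs of 400 subjects ×
500 genes with 100 resamples each; sweeps use the default 200 + 200
cohort with 20 replicates per cell. These sizes make the full suite and
the reproduction script comfortable on a single CPU while leaving the
Monte-Carlo margins of every assertion wide.

## Limitations

The package consumes pre-annotated variants (gene, consequence, MAF,
CADD); it does not annotate, infer ancestry, or prune relatedness.
Continuous phenotypes, elastic-net penalties, directed networks and
heat-kernel diffusion variants are out of scope. The selection threshold
of 0.80 controls family-wise error only through the support-size cap
described above; users wanting a formal per-family error target should
set `pfer` (or `maxSupport` directly) from the bound rather than relying
on the default.
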