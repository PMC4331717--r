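---
title: "Methods: phenotype-genotype similarity regression and dependence-corrected fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-genotype similarity regression and dependence-corrected fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofuse)
```

## The model

phenofuse scores the association between a query disease $d$ and a candidate
gene $g$ without requiring seed genes for $d$. The premise is
guilt-by-association read through phenotype space: if $g$ causes $d$, then
$g$ should be functionally similar to the known genes of diseases that are
phenotypically similar to $d$.

Two similarity currencies are used, both symmetric matrices with entries in
$[0,1]$:

* **Phenotype similarity** $Y_{de}$ between diseases, supplied by the user
  (typically cosine similarity of clinical-concept frequency vectors).
* **Gene similarity** $\varphi_{gh}$ per genomic data source, built by this
  package from profile vectors (cosine or absolute Pearson) or from
  networks (rescaled shortest-path distance), then passed through the
  exponential transformation below.

For a fixed source, the **genotype similarity** of the candidate $g$ to the
$i$-th reference disease (any other disease with at least one annotated
gene) is the sum over that disease's gene set $I_i$:

$$x_i = \sum_{k \in I_i} \varphi_{gk}.$$

The association strength is the one-sided significance of the slope in

$$Y = \alpha + \beta x + \varepsilon, \qquad
T = \frac{\hat\beta}{\sqrt{S^2 / \sum_i (x_i - \bar x)^2}}, \qquad
S^2 = \frac{\sum_i (Y_i - \hat\alpha - \hat\beta x_i)^2}{n - 2},$$

testing $H_0\!: \beta = 0$ against $H_1\!: \beta > 0$ with
$p = P(T_{n-2} \ge t)$. In validation mode every annotation of the query
disease is removed first, so its genetic basis contributes nothing to its
own score.

### Empirical calibration

The $t$ reference distribution assumes Gaussian errors; real phenotype
similarities are bounded, skewed and module-structured, and the genotype
sums are strongly leverage-prone (a single highly similar gene set can
dominate $x$). Raw p-values are therefore re-ranked within a null sample of
raw p-values computed, with the identical protocol, for disease-gene pairs
that are *not* annotated:

$$p_{\text{cal}} = \frac{\#\{p_{\text{null}} \le p_{\text{raw}}\} + 1}{M + 1}.$$

The add-one smoothing deviates from a plain proportion on purpose: it keeps
calibrated p-values strictly positive, so the downstream $\log$ in Fisher's
statistic stays finite. The default $M$ is 10{,}000 sampled pairs (seeded);
exhaustive enumeration (`m_pairs = NULL`) is practical on small instances.
When a query is scored, null pairs involving that query are excluded, which
keeps leave-one-out experiments honest.

### Dependence-corrected fusion

Per-source calibrated p-values $p_1,\dots,p_k$ are combined with Fisher's
statistic $X = \sum_i V_i$, $V_i = -2\log p_i$. The sources are *not*
independent — they describe overlapping biology — so $X$ is modelled as a
scaled chi-squared variable $X \sim r\chi^2_v$ with moments matched through
the pairwise covariances:

$$\hat r = \frac{1}{4k}\sum_{i}\sum_{j} \widehat{\operatorname{cov}}(V_i, V_j),
\qquad \hat v = 2k/\hat r,$$

with diagonal terms $\operatorname{cov}(V_i,V_i) = 4$. Off-diagonal
covariances come from a quartic polynomial in the corrected correlation
$\tilde\rho_{ij}$ of the probit scores $Z_i = \Phi^{-1}(1 - p_i)$:

$$\operatorname{cov}(V_i,V_j) \approx a_1\tilde\rho + a_2\tilde\rho^2 +
a_3\tilde\rho^3 + a_4\tilde\rho^4,$$

with $a_1 = 3.263119$, $a_2 = 0.709866$, $a_3 = 0.026589$,
$a_4 = -0.709866/n$, and the small-sample correction
$\tilde\rho = \hat\rho\,(1 + (1-\hat\rho^2)/(2(n-1)))$. Correlations are
estimated once, from the same background of non-associated pairs used for
calibration, with pairwise-complete observations; $n$ is the smallest
pairwise-complete count. Two limits anchor the construction: with
$\hat\rho \equiv 0$ the procedure is exactly textbook Fisher
($\chi^2_{2k}$), and two perfectly correlated tests collapse to effectively
one ($\hat r \to 2$, $\hat v \to 2$, up to the polynomial's own precision —
its value at $\tilde\rho = 1$ is 3.999574, not exactly 4). Sources missing
for a gene are dropped and $k$ reduced; a gene covered by no source is
excluded and counted.

Combined p-values across a candidate list are converted to q-values
controlling the positive false discovery rate, with the null proportion
estimated at a fixed $\lambda$:
$\hat\pi_0 = \#\{p > \lambda\}/((1-\lambda)m)$ at $\lambda = 0.5$, clipped
into $[1/m, 1]$. The fixed-$\lambda$ estimator was chosen over spline
smoothing for determinism; with $\hat\pi_0 = 1$ the q-values equal
Benjamini-Hochberg adjusted p-values exactly, which the test suite asserts.
Ranked output is ordered by (q-value, combined p, gene identifier), so ties
break identically on every platform.

## The exponential similarity transformation

Raw similarity scores $\omega \in [0,1]$ are mapped to final scores

$$\varphi = \exp\!\left[-\left(\frac{1-\omega}{\sigma}\right)^2\right],$$

which fixes $\varphi(1) = 1$ and drives low, noise-dominated raw scores
towards zero ($\varphi(0) = e^{-\sigma^{-2}}$, tiny when the dispersion
$\sigma$ is small). By default $\sigma$ is the *population* standard
deviation of the observed strictly-off-diagonal raw scores: self-pairs are
not pairs and are excluded, as are missing entries. Both choices are
overridable via the `sigma` argument.

Other numerical conventions:

* **Disconnected network pairs** have no shortest-path distance; they get
  $\omega = 0$ (maximal dissimilarity) and are counted in a `disconnected`
  attribute. $\delta_{\max}$ uses finite distances only, computed globally
  over the network rather than per component.
* **Undefined profile pairs** (zero-norm or zero-variance vectors) become
  `NA`, not 0 — a zero would assert confident dissimilarity the data cannot
  support. `NA` entries are excluded from $\sigma$ estimation and skipped
  (with a count) in genotype sums.
* **Edge threshold** for alignment e-value networks is a strict `<`
  (default `1e-4`).
* **p-value clipping** to $[10^{-300},\, 1 - 10^{-16}]$ before every log
  and probit transform.
* **Symmetry tolerance** for matrix validation is $10^{-10}$ relative;
  validated matrices are symmetrized exactly by averaging.

## Validation machinery

Leave-one-out cross-validation treats each annotated disease-gene pair in
turn as (query, test gene), masks all annotations of the query, and ranks
the test gene against $m = 99$ controls — either the $m$ same-chromosome
genes nearest to the test gene (a simulated linkage interval; distance ties
break by smaller coordinate then identifier) or a uniform random genome
sample. Controls never include genes annotated to the query. Per-run rank
ratios (rank divided by list size) aggregate into the mean rank ratio
(MRR), the rank-ROC AUC (sensitivity = fraction of test genes at or above a
rank-ratio threshold, specificity = fraction of control positions below
it), and top-$k$ counts; a uniform random ranker yields MRR
$\approx 50.5\%$ and AUC $\approx 0.5$, which the suite verifies.

The binned correlation analysis takes every unordered pair of annotated
diseases, bins phenotype similarity into ten equal-width bins on $[0,1]$
(last bin closed), averages the genotype similarity
$x_{de} = \sum_{g\in D}\sum_{h\in E}\varphi_{gh}$ within bins, and reports
the Pearson correlation of the ten bin means. Equal-width (not
equal-count) bins were chosen to match the natural reading of a $[0,1]$
similarity axis. The hypergeometric enrichment helper is the one-sided
Fisher's exact test used to ask whether top-ranked candidates are enriched
for independently validated genes.

## The synthetic world

`generate_world()` emulates the data this method consumes, with planted
truth for power and calibration experiments:

* Genes are partitioned into functional modules (defaults: 30 modules of 3
  genes among 200 genes; the remainder are unassigned background genes).
  Each module anchors 2 diseases, and each disease is annotated with all of
  its module's genes — so a held-out gene still has annotated same-module
  diseases to learn from, while control pools exclude the query's annotated
  genes.
* Phenotype similarity of a disease pair is a 0.2 baseline, plus
  `effect_b` (default 0.3) when the diseases share a module, plus
  $N(0, 0.05^2)$ noise, clipped to $[0,1]$. `effect_b = 0` gives a null
  world.
* Raw gene similarity per source is a 0.3 baseline plus a 0.6 within-module
  boost scaled by the source's reliability, plus pair-level noise
  (SD 0.1) split into a shared component across sources (variance share
  `cross_source_rho`, default 0.3) and an independent remainder, clipped
  and passed through the exponential transformation. Reliability 0 turns a
  source into pure noise.
* Locations are uniform over 5 synthetic chromosomes; all randomness flows
  from one root seed through fixed per-component offsets, so the same seed
  reproduces the world byte for byte.

Clipping after noise (rather than resampling) slightly biases boundary
values; with the default baselines the clipped mass is negligible. What the
generator does *not* emulate: text-mined phenotype vectors, scale-free
interaction networks, annotation sparsity correlated with study bias, and
gene-set sizes beyond a fixed module size. Passing tests therefore
demonstrate correctness of the machinery and calibration under the stated
generative assumptions, not performance on real corpora.

## Problem sizes and known limitations

The shipped experiments use worlds of 60-100 diseases, 200 genes and 3
sources, null samples of 2,000 pairs per source for the cross-validation
harness (10,000 is the production default), 2,000 scores for uniformity
checks and 5,000 replicates for the copula size check; a full LOOCV on the
default planted world takes seconds on one core.

Two caveats are worth stating. First, the scaled chi-squared correction is
a moment approximation: its size at $\alpha = 0.05$ under strongly
correlated sources is accurate to within Monte-Carlo error, but extreme
tails inherit the polynomial's approximation error. Second, combined
p-values for pairs sharing a disease share the same response vector, so
they are uniform marginally but not mutually independent; goodness-of-fit
statistics computed over such a grid fluctuate somewhat more than iid
theory suggests. Null calibration absorbs the per-source effect; the
combined-level effect is visible only in aggregate uniformity diagnostics,
not in per-query inference.

```{r example, eval = FALSE}
w <- generate_world(synthetic_config(seed = 1))
vs <- loocv(w$assoc, w$phenotype, w$sources, control_mode = "random",
            m = 99, seed = 1, null_size = 2000)
print(vs)
```
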