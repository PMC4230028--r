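---
title: "Dominance-aware genomic evaluation and mate allocation with gblupd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance-aware genomic evaluation and mate allocation with gblupd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`gblupd` implements genomic evaluation of a single-generation cohort of
genotyped cows with additive *and* dominance gene action.  At a biallelic
locus with alleles $A_1$, $A_2$ at frequencies $p$, $q = 1 - p$, the
genotypic values of $A_1A_1$, $A_1A_2$, $A_2A_2$ are $+a$, $d$, $-a$.  The
breeding values of the three genotypes are $2q\alpha$, $(q-p)\alpha$,
$-2p\alpha$ with the substitution effect $\alpha = a + d(q-p)$, and the
dominance deviations are $-2q^2d$, $2pqd$, $-2p^2d$.  Summed over loci this
gives the classical orthogonal partition of the genetic variance,
$\sigma^2_A = \sum_k 2p_kq_k\alpha_k^2$ and
$\sigma^2_D = \sum_k (2p_kq_kd_k)^2$.

The animal-level mixed models are

* **MA** — $y = \mu + u + e$, $V(u) = A\sigma^2_A$ (pedigree relationships),
* **MG** — $y = \mu + u + e$, $V(u) = G\sigma^2_A$ (genomic relationships),
* **MGD** — $y = \mu + u + v + e$, $V(u) = G\sigma^2_A$,
  $V(v) = D\sigma^2_D$,

with one yield deviation (YD) per cow and heteroscedastic residuals
$V(e) = F\sigma^2_E$, where $F$ is diagonal with the reciprocal of the
effective number of own performances (EOP) of each cow.  $G$ is the VanRaden
genomic relationship matrix
$G^* = W_aW_a'/2\sum_k p_kq_k$ built from the frequency-centred allele
counts, rescaled so that the means of its diagonal and off-diagonal match
those of $A$, and blended as $G = 0.95\,G^* + 0.05\,A$; the dominance
matrix uses the heterozygosity coding
($-2q_k^2$, $2p_kq_k$, $-2p_k^2$) and is blended with the identity,
$D = 0.95\,D^* + 0.05\,I$.  Blending bounds the smallest eigenvalue away
from zero, which both samplers and REML rely on.

The equivalent marker-effect formulation (MGD-SNP) is
$y = \mathbf{1}\mu + Ta + Xd + e$ with $T$ coded $\{-1, 0, 1\}$ and $X$
coded $\{0, 1, 0\}$, $V(a) = I\sigma^2_a$, $V(d) = I\sigma^2_d$.  The
marker- and animal-level variances are linked by
$\sigma^2_A = \sum 2pq\,\sigma^2_a + \sum 2pq(q-p)^2\sigma^2_d$ and
$\sigma^2_D = \sum 4p^2q^2\sigma^2_d$
(`marker_to_animal_variance()` / `animal_to_marker_variance()`).  The two
levels are *exactly* equivalent only when the marker model uses the
frequency-centred designs $W_a$, $W_d$ (option `design = "centered"` of
`snp_blup_effects()`); with the genotypic $T$/$X$ coding the equivalence is
approximate, because the induced substitution-effect variance is
locus-specific.

## Estimation

`reml_fit()` maximizes the restricted likelihood with average-information
updates.  The reported $-2\log L$ carries all terms
($(n-1)\log 2\pi + \log|V| + \log|X'V^{-1}X| + y'Py$) with the same fixed
mean across models, so MA/MG/MGD differences are valid LRT statistics.
Numerical choices:

* convergence when the relative change of every parameter falls below
  `tol = 1e-8`;
* variance estimates are floored at $10^{-10}\,\mathrm{var}(y)$ and flagged
  when they end there;
* a negative AI proposal is clamped at the floor and accepted if the
  likelihood improves, otherwise an expectation-maximization step (which is
  provably monotone) is taken.  Clamping matters: near a zero boundary the
  EM map alone contracts only geometrically, and a boundary optimum (e.g.
  $\hat\sigma^2_A \to 0$ in a tiny example) would otherwise not be reached
  in hundreds of iterations.

Because $\hat\sigma^2_D = 0$ lies on the boundary of the parameter space,
the LRT of MGD against MG uses an equal mixture of $\chi^2_0$ and
$\chi^2_1$: `mixture_lrt()` returns
$P = \tfrac12\Pr(\chi^2_1 \ge \lambda)$ for $\lambda > 0$ and $P = 1$
otherwise; small negative statistics arise from finite optimizer tolerance
in two separate maximizations and count as evidence for the null.

`gibbs_animal()` and `gibbs_snp()` are single-site Gibbs samplers written
against the mixed-model equations (the scheme of the classical animal
breeding samplers): location effects are drawn one at a time from scalar
normal full conditionals, variances from scaled inverse-$\chi^2$
conditionals under flat (improper) priors.  Default desk-scale chain
lengths are 20&nbsp;000 iterations, 2&nbsp;000 burn-in, thinning 10;
convergence is *checked*, never assumed, with `geweke_diagnostic()`
(first 10% vs last 50% of the retained chain, variances from the AR-fitted
spectral density at frequency zero).  Variance proposals below
$10^{-10}\,\mathrm{var}(y)$ are pinned and counted.  In the marker-level
sampler a constant shift between $\mu$ and the summed marker effects is
weakly identified under the $T$ coding and mixes slowly — posterior
summaries of *centred* genetic values are reliable long before the
intercept direction converges.

## Prediction and cross-validation

`blup_solve()` solves the mixed-model equations at fixed variance
components on the training records and predicts any individual covered by
the relationship matrices through the joint covariance,
$\hat u_{\mathrm{pred}} = \sigma^2_A G_{\mathrm{pred,train}}
V^{-1}(y - \hat\mu)$; total genetic values are $\hat g = \hat u + \hat v$.
`cross_validate()` partitions the cohort into $K = 10$ folds of
near-equal size and reports, per fold, the accuracy $r(YD, \hat u)$ and the
regression slope $b$ of YD on $\hat u$ (1 = unbiased), likewise for
$\hat g$ under MGD.  Design choices made where the design was open: the
statistics are unweighted by default (an EOP-weighted variant sits behind
`weighted = TRUE`); $\mu$ is re-estimated inside every training set; fold
statistics are averaged arithmetically with the standard error taken as the
SD over folds divided by $\sqrt{K}$.

## Planned matings

For each sire $\times$ dam pair, `offspring_genotype_probs()` gives the
Mendelian genotype distribution of the offspring per locus, and
`predict_mating()` evaluates its expected total genetic value
$\hat g_{ij} = \sum_k \Pr_{ijk}(A_1A_1)\hat a_k + \Pr_{ijk}(A_1A_2)\hat d_k
- \Pr_{ijk}(A_2A_2)\hat a_k$ and expected breeding value (which reduces
exactly to the parent average $\tfrac12(\hat u_i + \hat u_j)$).  Marker
effects come from `snp_blup_effects()`, the BLUP-SNP model: the marker
model at *fixed* variances obtained from the REML animal-level estimates
via `animal_to_marker_variance()`.

`allocate_matings()` assigns one bull per cow under a per-bull capacity cap
(default 200 cows).  The selection sentence underdetermines the algorithm
once the cap binds; we use a globally sorted greedy pass (all pairs by
score, ties broken by bull then cow position), which is deterministic,
matches brute-force enumeration on small instances, and reproduces the
qualitative usage pattern of a few saturated bulls plus a tail.  An optimal
transport formulation would be the natural extension but is not the
default.  `gain_summary()` reports the expected total genetic superiority
$\Delta G$ and additive gain $\Delta U$ of a plan against the mean over
*all* possible matings, in trait units and relative to the SD of the
respective scores over all matings; `compare_mating_criteria()` turns the
SD-relative values of two plans into the percentage gain/loss of selecting
on $\hat g$ instead of $\hat u$.  The percentage convention operates on the
SD-relative values — the absolute-value convention gives slightly different
numbers and is deliberately not used.

## The synthetic cohort generator

No public data accompany the method, so `simulate_population()` generates
the study conditions: a single phenotyped generation (validation animals
can have sibs, never descendants, in training — matching the
cross-validation structure of a one-generation cow cohort), many paternal
half-sib families from a small number of sires, and a configurable fraction
of full sibs (default 3% of cows in full-sib pairs, created by repeated
sire$\times$dam matings).  Founder genotypes are drawn in Hardy-Weinberg
proportions at MAF uniform on (0.05, 0.5) — a post-QC spectrum that avoids
near-monomorphic QTL — and offspring are produced by gene dropping with
unlinked loci.  `assign_effects()` draws QTL effects from standard normals
and rescales each vector by a single factor so that the implied animal-level
variances hit the configured targets *exactly*; the additive factor solves a
quadratic because $\alpha$ mixes $a$ and $d$, and targets for which the
dominance-induced substitution variance alone exceeds $\sigma^2_A$ are
rejected.  Phenotypes add $N(0, \sigma^2_E/\mathrm{EOP}_i)$ noise with EOP
uniform on (1, 3); for conformation-like traits with single records set
`eop_range = c(1, 1)`.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: linkage and LD between markers (the relationship-matrix
formulas nowhere require it, but LD changes the *dispersion* of genomic
relationships: with unlinked loci the off-diagonal spread of $D^*$ is
slightly *larger* than that of $G^*$ in an unrelated cohort, whereas on real
genomes it is several-fold smaller; in a family-structured cohort $G$ is
more dispersed either way), selection and assortative mating in the
ancestors, genotyping error, and the construction of yield deviations from
test-day records (YD enter as given).

Problem sizes used in the shipped tests and acceptance script (n = 120 to
2000 cows, m = 120 to 10&nbsp;000 markers, chains of a few thousand
iterations) were chosen so the whole suite runs on a laptop in minutes while
keeping Monte-Carlo error well inside the asserted tolerances; all sizes are
arguments, and the defaults of `sim_config()` reproduce the cohort scale of
a realistic application (1996 cows).

## Known limitations

* Dense matrices throughout; $n \approx 2000$ is the intended scale.
* Independence of $u$ and $v$ is assumed (no inbreeding depression /
  directional dominance; dependent-prior Bayesian regressions are out of
  scope).
* The marker-level Gibbs sampler mixes slowly in the intercept direction
  (see above); compare centred quantities or use the animal-level sampler
  for variance components.
* Mate allocation is single-generation: dominance-specific superiority is
  not transmitted, so the optimization has to be repeated each generation.
* `hwe_filter()` uses the 1-df goodness-of-fit $\chi^2$; an exact test is a
  possible refinement for very small samples.

## A worked session

```{r, eval = FALSE}
library(gblupd)

cfg <- sim_config(n_sires = 20, n_dams = 500, n_offspring = 800,
                  m_loci = 2000, n_qtl = 300,
                  target_sigmaA2 = 200, target_sigmaD2 = 100, sigmaE2 = 150,
                  seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")

res$reml$MGD          # variance components, -2 log L
res$lrt               # mixture chi-square test of sigmaD2 = 0
res$cv$MGD            # 10-fold accuracies and slopes
res$mate$gain_g       # expected gains of selection on g-hat
res$mate$comparison   # % change vs selection on u-hat
```
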