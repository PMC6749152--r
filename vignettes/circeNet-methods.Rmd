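---
title: "circeNet: models and methods behind the ceRNA network pipeline"
author: "circeNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circeNet: models and methods behind the ceRNA network pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circeNet)
```

## The scientific problem

Circular RNAs (circRNAs) are covalently closed, exonuclease-resistant
non-coding RNAs enriched in brain tissue. Under the competing endogenous
RNA (ceRNA) hypothesis, a circRNA can act as a miRNA sponge: by sequestering
a miRNA through its response elements it de-represses the miRNA's mRNA
targets. A circRNA and an mRNA that share many miRNA regulators are
therefore candidates for indirect, miRNA-mediated competitive regulation.

circeNet implements an integrated workflow to dissect such regulation in a
disease context:

1. **Differential expression.** Consistently differentially expressed
   genes (CDEGs) are identified across multiple two-condition expression
   datasets (e.g. several brain regions) with an empirical-Bayes moderated
   t-statistic per dataset and a weighted signed-z combination across
   datasets; differentially expressed miRNAs (DEmiRs) come from a single
   miRNA dataset with the same moderated statistic.
2. **ceRNA network construction.** From a typed miRNA-target edge list,
   every circRNA-mRNA pair sharing at least `minShared` miRNAs (default 5)
   qualifies; each `(circRNA, miRNA, mRNA)` combination with the miRNA in
   the shared set is one *crosstalk triple*. The network retains exactly
   the interactions participating in at least one triple.
3. **Disease subnetwork and prioritization.** Triples containing at least
   one CDEG or DEmiR form the disease subnetwork; within it, triples
   containing at least one curated known disease gene or miRNA are *risk
   crosstalks*, and circRNAs are ranked by their risk-crosstalk count.
4. **Diagnostics and annotation.** Degree-distribution/power-law
   diagnostics assess the scale-free character of the network, and
   hypergeometric over-representation analysis (ORA) annotates the gene
   neighborhood of a prioritized circRNA.

## The moderated t-statistic

For feature $g$ in a dataset with $n_1$ case and $n_2$ control samples, let
$\hat\beta_g$ be the difference of group means (log2 units), $s_g^2$ the
pooled sample variance with $d_g = n_1 + n_2 - 2$ degrees of freedom. The
variances are modelled as draws from a scaled inverse chi-square prior with
degrees of freedom $d_0$ and scale $s_0^2$, giving the posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\qquad
\tilde t_g = \frac{\hat\beta_g}{\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}},$$

with a two-sided p-value from a Student $t$ on $d_0 + d_g$ degrees of
freedom ($d_0 = \infty$ gives a normal reference and $\tilde s_g^2 \equiv
s_0^2$; $d_0 = 0$ recovers the ordinary pooled t-test). The hyperparameters
are estimated by the method of moments on $e_g = \log s_g^2 - \psi(d_g/2) +
\log(d_g/2)$: the excess of $\mathrm{var}(e_g)$ over the sampling
contribution $\psi'(d_g/2)$ determines $d_0$ through the inverse trigamma
function, and $s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the
observed spread does not exceed the sampling contribution the prior is
degenerate ($d_0 = \infty$, $s_0^2 = \exp \bar e$). Features with
non-positive sample variance carry no information about the spread of
$\log\sigma^2$ and are excluded from the fit (they are still shrunk). In
the finite-prior regime this estimator agrees with limma's to numerical
precision (verified in the test suite); in the degenerate branch we keep
the moment formula $\exp(\bar e)$ rather than limma's arithmetic mean of
variances, because it is the same estimator evaluated at the boundary.

```{r moderated}
cfg <- simulationConfig(seed = 1, nFeatures = 1000, nDatasets = 1)
ms <- moderatedT(simulateExpression(cfg)$datasets[[1]])
ms
```

## Cross-dataset combination

Each dataset contributes a signed z-score $z_i =
\mathrm{sign}(\hat\beta_i)\,\Phi^{-1}(1 - p_i/2)$; evidence is combined as a
weighted Stouffer sum $z = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$ with
$w_i = \sqrt{n_{1i} + n_{2i}}$ by default. The signed-z rule was chosen
because it handles unequal designs cleanly and extends naturally to
features observed in only a subset of datasets (platforms differ; dropping
non-universal features would discard most genes), which are combined over
the datasets where they appear. Direction is the sign of the combined z.
Benjamini-Hochberg step-up adjustment is implemented once and shared
bit-for-bit between this module and the enrichment module. Thresholds are
strict inequalities: genes at FDR < 0.01 across datasets, miRNAs at
FDR < 0.05 in their single dataset.

## Network construction choices

The shared-miRNA threshold applies to circRNA-mRNA *pairs*, and an
interaction is retained exactly when it participates in at least one
qualifying triple — the only reading that yields a well-defined
edge-filtered tripartite network. Crosstalk is materialized per mediating
miRNA (one triple per `(circRNA, miRNA, mRNA)`), so a pair sharing $k \ge$
`minShared` miRNAs contributes $k$ triples. Shared-miRNA counts are
computed through an inverted index on the miRNA (a join of the two typed
edge lists on the miRNA key), never by an all-pairs scan; brute-force
pairwise intersection is used as the test oracle only. No
expression-correlation filter between ceRNA partners is applied: circRNA
expression is not measured on the emulated platforms. Identifiers are
opaque case-sensitive strings.

circRNAs themselves are never tested for differential expression or known
disease membership — only their mRNA partners and mediating miRNAs carry
those labels. Risk flagging applies after disease extraction, so risk
triples are always a subset of disease triples. Ranking ties are broken by
ascending circRNA id so runs are reproducible; a normalized coverage (risk
triples / total triples per circRNA) is emitted as an auxiliary column but
the rank uses the raw count.

```{r network}
study <- simulateStudy(simulationConfig(seed = 1))
built <- buildCirceNet(study$interactions, minShared = 5)
built$network
head(built$triples, 3)
```

## Degree distribution and the power-law exponent

Degrees pool all three node classes. `fitPowerLaw()` offers two exponent
estimators. The default, `method = "discrete"`, maximizes the zeta-function
likelihood of the discrete power law $P(k) = k^{-\alpha}/\zeta(\alpha,
x_{min})$ — the appropriate model for integer degrees, unbiased down to
$x_{min} = 1$. The closed-form continuous approximation $\hat\alpha = 1 +
n/\sum \ln(x_i/x_{min})$ is also available (`method = "continuous"`); it is
retained as a quick diagnostic but overestimates the exponent severely on
integer data at small $x_{min}$ (for zeta-distributed degrees with
$\alpha = 2.5$ and $x_{min} = 1$ its expectation is near 4.5), which is why
it is not the default. A log-log least-squares slope and $R^2$ over the
nonzero histogram bins accompany either estimate, mirroring the usual
visual check of scale-freeness. Full Clauset-Shalizi-Newman $x_{min}$
selection and goodness-of-fit testing against alternatives are out of
scope.

```{r powerlaw}
deg <- simulatePowerLawDegrees(5000, alpha = 2.5, seed = 1)
fitPowerLaw(deg)
```

## Over-representation analysis

`runORA()` tests a query gene list against a GMT-derived collection with
the upper-tail hypergeometric probability $P(X \ge k)$, $X \sim
\mathrm{Hyper}(N, K, n)$, followed by the shared BH adjustment. The
background universe dominates ORA results, so it is explicit: the default
policy uses the mRNA nodes of the analyzed (disease) network, and a file
policy allows any user-supplied background. At the bundled synthetic scale
the network universe is deliberately small, so the pipeline's
neighborhood-ORA output is illustrative; calibration tests run against the
full simulated mRNA universe. Annotation comes from a user-supplied GMT
file rather than a live ontology download, keeping analyses version-pinned.

## The synthetic-study generator

The generator produces every input the pipeline consumes, with the
statistical structure the analysis assumes, plus ground-truth labels:

* **Expression.** Six two-condition gene datasets of 2,000 features with
  10+10 samples each (the emulated design: several brain-region microarray
  units sharing one DE membership), and one 4-vs-4 miRNA dataset. True
  variances are drawn from the scaled inverse chi-square prior
  ($d_0 = 4$, $s_0^2 = 0.05$) so hyperparameter recovery is a meaningful
  test; 10% of features are DE with log2 effect magnitudes
  $\mathcal N(1.0, 0.25^2)$, the sign fixed per feature across datasets
  (consistent DE is what the meta-analysis seeks) and the magnitude redrawn
  per dataset (between-region heterogeneity). No probe-level noise, batch
  effects or real brain biology are modelled, so passing tests demonstrate
  correctness of the computations under the model, not robustness to
  real-data artefacts.
* **Interactions.** 24 planted circRNA-mRNA pairs, each sharing a pool of
  8 miRNAs, one pair per circRNA; background edges appear independently
  with probability 0.01. With one pair per circRNA every planted circRNA
  has the same crosstalk topology, so the planted *risk* circRNA is
  distinguished purely by known-disease coverage — the quantity the
  prioritization actually ranks. This is what makes the permutation
  sanity check meaningful: shuffling known labels destroys the planted
  circRNA's rank-1 position almost always.
* **Known lists.** 27 known genes and 45 known miRNAs (the sizes of the
  emulated curated resources). The gene list contains the risk circRNA's
  planted mRNA partner; the miRNA list contains three miRNAs from its
  shared pool (emulating a small number of curated disease miRNAs that
  mediate its crosstalk) and is otherwise filled from a curated namespace
  outside the expression platform, as real curated miRNA lists mostly are.
* **Gene sets.** Random sets over the network mRNA universe plus one
  planted term containing every planted triple's mRNA.

All generators are pure functions of the single config seed; each draws
from its own derived stream, so adding one generator never shifts
another's output, and the caller's RNG state is restored afterwards.
Sample sizes above are package defaults chosen once as a realistic
desk-scale study; they can be changed through `simulationConfig()`.

## Numerical and degenerate-input conventions

* Two-sided p-values are floored at $10^{-300}$ before conversion to
  z-scores so the Stouffer sum never produces infinities.
* A feature with zero variance in both groups is rescued by shrinkage
  (its posterior variance is positive whenever $d_0 s_0^2 > 0$); if fewer
  than 10 features have positive variance, prior estimation fails with an
  explicit error.
* The inverse trigamma is solved by Newton iteration with asymptotic
  guards at both ends; the Hurwitz zeta in the discrete power-law
  likelihood uses a 10,000-term direct sum plus an integral tail.
* Empty inputs degrade explicitly: empty annotation sets give an empty
  disease network with a warning (not an error); an empty risk set gives
  an empty ranking; an empty interaction file warns.
* All tabular outputs are written at full round-trip precision, and a
  manifest of md5 checksums makes run-level determinism checkable.

## The pipeline interface

The package is a programmatic toolkit: `runPipeline()` together with the
readers/writers is the orchestration surface (simulate/load, DE, build,
extract, prioritize, stats, enrich), with `pipelineConfig()` holding
thresholds, the seed and the universe policy, JSON-serializable and
re-loadable. No shell front-end is shipped; the exported functions and
this vignette are the interface.

```{r pipeline, eval = FALSE}
res <- runPipeline(pipelineConfig(outDir = "run1", seed = 1))
res$ranking[1, ]
```

## Known limitations

* The moderated-t p-values with an estimated prior are mildly
  anti-conservative at very small residual degrees of freedom (the
  empirical null FDR at nominal 0.05 is about 0.07 in the bundled null
  simulation) — a property shared with the standard empirical-Bayes
  implementations, controlled but not exactly at nominal level.
* Hypergeometric ORA p-values are discrete and super-uniform under the
  null; uniformity diagnostics must account for the lattice (the test
  suite uses heterogeneous set sizes for this reason).
* The prioritization measures risk-crosstalk frequency; it has no notion
  of statistical significance for the top rank and should be read as a
  screening ranking.
* Probe summarization, normalization and id mapping are out of scope:
  inputs are assumed normalized, log2-transformed and keyed by final
  feature ids.
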