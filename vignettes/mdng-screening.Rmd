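---
title: "Screening drugs through miRNA-regulated drug-pathway networks"
author: "mdngscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening drugs through miRNA-regulated drug-pathway networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdngscreen)
```

## The problem and the model

Many diseases — the motivating case is an autoimmune disease such as
relapsing-remitting multiple sclerosis — have curated catalogues of risk
genes and of miRNAs whose dysregulation accompanies the disease, while
existing drugs come with curated target-gene sets. None of these gene sets
overlap enough, gene by gene, to connect a drug to the disease directly.
The idea implemented here is to connect them at the *pathway* level:

1. **Enrichment.** The disease risk genes, each miRNA's target set and each
   drug's target set are separately tested for pathway over-representation
   with the one-sided hypergeometric (Fisher exact) tail
   \[
   P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),
   \]
   where $N$ is the gene-universe size, $K$ the pathway size, $n$ the query
   size and $k$ the overlap. KEGG-style runs flag pathways at raw $p <
   0.05$; GO-style runs use Benjamini–Hochberg FDR $< 0.05$. Regulators
   (miRNAs or drugs) with five or fewer target genes are excluded before
   testing.

2. **The MDNG.** Pathways significant for the disease become candidate
   nodes. A regulator is linked to a candidate pathway when its own profile
   marks the pathway significant; pathways that fail to attract both a
   miRNA and a drug edge are pruned, as are regulators left without edges.
   The result is the tripartite miRNA-regulated drug-pathway network
   ("MDNG") — a simple undirected graph whose only edges join a regulator
   to a pathway.

3. **Association score.** For each drug $i$, the candidate pathways are
   those significant for both the disease and the drug. The score pathway
   $k$ is the one where the joint enrichment is strongest — the minimiser
   of $P_{\mathrm{dis},k} \cdot P_{\mathrm{drug}_i,k}$ — and
   \[
   S_i \;=\; -\log_{10} P_{\mathrm{dis},k} \;-\; \log_{10} P_{\mathrm{drug}_i,k}.
   \]
   $S_i$ is undefined when no pathway is significant for both.

4. **Permutation Z.** $S_i$ alone rewards promiscuous drugs, so it is
   standardised against a label-permutation null: the disease enrichment
   profile (p-values, counts and significance flags together) is
   reassigned to pathway labels by a uniform random permutation, $S$ is
   recomputed per permutation, and
   \[
   Z_i = \frac{S_i - \overline{S_{\mathrm{random},i}}}
              {\mathrm{sd}(S_{\mathrm{random},i})} .
   \]
   Drugs with $Z > 1.96$ — the two-sided standard-normal critical value at
   significance .05 — pass the screen.

### Interpreting the pieces

* The exact algebra of the score in the original formulation is not fully
  specified; this package adopts the product/min form above, which is the
  reading consistent with "the pathway most significantly impacted by
  both". Alternative aggregations would change $S$'s scale but not the
  permutation logic, since the null recomputes the same statistic.
* "Random pathway rankings" are implemented as permutations of the
  *disease* profile over the full pathway label universe of the collection,
  holding every drug profile fixed. Labels with no enrichment row (zero
  overlap) take part in the permutation, so a permuted profile can leave a
  drug with no shared significant pathway at all. Such permutations yield
  an *undefined* score; they are excluded from the null and counted
  (`n_undefined`), rather than imputed as zero — zero-imputation would
  drag the null mean down by an arbitrary amount that depends only on how
  sparse the profile is.
* The null's standard deviation uses the sample ($n-1$) denominator; a
  degenerate null (sd $= 0$, or fewer than two defined permutations) makes
  $Z$ undefined rather than infinite.
* The cutoff is the literal two-decimal 1.96, and the comparison is
  strict, so $Z = 1.96$ does not pass.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | per-pathway significance threshold (raw p, or BH-adjusted with `adjust = "BH"`) |
| `minTargets` | 6 | minimum target-set size per regulator ("more than 5 targets") |
| `nPerm` | 10000 | permutations per drug |
| `cutoff` | 1.96 | strict Z threshold for passing the screen |
| `ease` | FALSE | EASE-style conservative tail (overlap decremented by 1, floored at 0) |
| `keepPartial` | FALSE | retain pathways with only one regulator class in the network |

The universe supplied by the user is the enrichment background; it is not
silently replaced by the union of pathway members, so absolute p-values are
auditable. Pathways with zero overlap are omitted from tables rather than
reported at $p = 1$.

## Network topology

Two NetworkAnalyzer-style summaries describe the MDNG:

* `fitPowerLaw(degreeDistribution(net))` fits $f(x) = a x^b$ by ordinary
  least squares of $\log_{10}$ count on $\log_{10}$ degree — the log-log
  regression convention, chosen over maximum likelihood because it is the
  convention under which degree-distribution exponents of such networks
  are conventionally reported. A perfect fit reports $r^2 = 1$ even when
  the log-counts have zero variance.
* `topologicalCoefficient()` computes, for each node $v$ of degree
  $\ge 2$, the mean of $J(v, w)/\deg(v)$ over all $w \ne v$ sharing at
  least one neighbour, where $J$ counts shared neighbours plus 1 for a
  direct edge. Nodes of degree < 2 (or with no sharing partner) are
  undefined and reported `NA`. Note this is the *topological coefficient*
  convention, not betweenness centrality, although descriptions of the
  quantity sometimes conflate the two.

## What the synthetic generator emulates

Real inputs to this kind of screen (curated disease genes, validated
miRNA targets, drug-target catalogues) are not redistributable, so the
package ships a generator that emulates their structure with planted
ground truth:

* a gene universe of `nGenes` symbols and `nPathways` pathways whose
  members are drawn independently per pathway — pathways therefore
  overlap, as real collections do, which keeps the "most significant
  shared pathway" selection non-trivial;
* `nRiskPathways` designated risk pathways; disease genes are a mixture of
  a `diseaseSignal` fraction drawn from the risk-pathway union and the
  remainder drawn uniformly;
* regulators draw 10–30 targets each; *responsive* regulators take a
  `regulatorSignal` fraction from the risk-pathway union, *null*
  regulators sample the universe uniformly.

One seed drives a single stream in a fixed generation order (pathways →
disease genes → miRNAs → drugs), so identical configurations are
byte-reproducible across platforms.

The default configuration is deliberately small so that a full screen runs
in seconds: 200 genes, 12 pathways of 10–20 genes, 3 risk pathways, 30
disease genes at `diseaseSignal = 0.8`, and 20 miRNAs plus 20 drugs (5
responsive each) at `regulatorSignal = 0.8`. The pathway count and sizes
scale the KEGG collection down by roughly two orders of magnitude; three
risk pathways keep the risk union (~40 genes) a minority of the universe;
30 disease genes at signal 0.8 give the disease profile unambiguous
enrichment on the risk pathways while leaving room for chance hits
elsewhere, mirroring how curated risk-gene lists concentrate in a handful
of pathways. `synthPreset("paper-scale")` provides genome-scale magnitudes
(6000 genes, 300 pathways, 61 risk pathways, 138 miRNAs, 186 drugs) for
exploratory runs.

What the generator does **not** emulate: sequence-based miRNA targeting,
expression, correlated pathway membership (curated pathways share genes
for biological reasons, not uniformly at random), or heavy-tailed
target-set sizes. Passing tests on synthetic data therefore demonstrate
that the pipeline recovers *planted pathway-level signal* under its own
model, not that it would rank any particular real drug correctly.

## Numerical and design choices

* The hypergeometric tail is computed exactly (`phyper`); $P(X \ge 0)$ is
  returned as exactly 1. Tests check it against explicit
  $\binom{K}{i}\binom{N-K}{n-i}/\binom{N}{n}$ enumeration.
* Ties in the best-pathway selection break on the lexicographically
  smallest pathway id; screen ranking breaks Z ties by drug id; undefined
  Z sorts last. All orderings are deterministic, so reports are
  byte-identical across reruns with one seed.
* Within one screen, all drugs share a single seeded set of pathway-label
  permutations (common random numbers). Each drug's null is marginally
  unchanged; shared permutations merely correlate the drugs' Monte-Carlo
  noise, and make the run cost independent of when each drug is scored.
* Gene symbols are upper-cased everywhere; miRNA identifiers are
  lower-cased (`hsa-miR-…`/`hsa-mir-…` collapse); drug identifiers are
  taken verbatim. Duplicate (regulator, gene) pairs collapse with a
  logged count.
* Degenerate inputs: an empty query enriches to an empty table with a
  warning; an empty network is writable as a header-only SIF file; a
  single-degree distribution refuses a power-law fit.

## Known limitations

* With a small pathway collection the permutation null is supported on few
  distinct values, so $Z$ saturates well below the levels seen with
  hundreds of pathways: a drug significant on a single pathway has
  $(\max - \mathrm{mean})/\mathrm{sd}$ bounded by the handful of
  significant disease p-values it can pair with. On the default 12-pathway
  preset the screen separates responsive from null drugs in rank terms
  much more reliably than in absolute $Z > 1.96$ terms, and occasional
  chance-enriched null drugs can interleave with weakly-scoring responsive
  ones. The test suite measures both behaviours explicitly.
* The enrichment background is whatever universe the user supplies;
  published screens that delegated enrichment to web services used
  backgrounds that are not reconstructible, so absolute p-values (and
  hence $S$) are not comparable across backgrounds.
* Identifier unification across source databases is assumed done upstream;
  the package normalises case only.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on the default
preset: single screens use 200–1000 permutations per drug, the null
calibration aggregates 200 (drug, study) replicates at 1000 permutations,
and rank recovery aggregates 50 studies at 1000 permutations. These sizes
are the package's own trade-off between Monte-Carlo error (about
$\pm 0.03$ on a rate estimated from 200 replicates) and a suite a
developer will actually run while iterating.
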