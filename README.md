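# mdngscreen

Network-based drug repurposing through miRNA-regulated drug–pathway
networks, for computational biologists who have three curated gene-set
resources — disease risk genes, miRNA→target maps, drug→target maps — and a
pathway collection, and want to rank existing drugs against the disease at
the pathway level.

## The method

Every entity (the disease gene set, each miRNA's targets, each drug's
targets) is tested for pathway over-representation with the one-sided
hypergeometric tail

    P(X >= k),  X ~ Hypergeometric(N, K, n)

over a user-supplied gene universe of size *N* (pathway size *K*, query
size *n*, overlap *k*); regulators with ≤ 5 targets are dropped first.
Pathways significant for the disease and for at least one miRNA **and**
one drug form the tripartite **MDNG** (miRNA-regulated drug-pathway
network through genes), whose topology is summarised by degree
distributions, a log–log least-squares power-law fit *f(x) = a·x^b*, and
NetworkAnalyzer-style topological coefficients.

Each drug *i* is then scored on the pathway *k* most significantly shared
with the disease (the minimiser of `P_dis,k · P_drug_i,k` over pathways
significant for both):

    S_i = -log10(P_dis,k) - log10(P_drug_i,k)

and standardised against a permutation null in which the disease
enrichment profile is reassigned to pathway labels uniformly at random
(10,000 permutations by default; permutations leaving no shared
significant pathway are excluded and counted):

    Z_i = (S_i - mean(S_random,i)) / sd(S_random,i)

Drugs with **Z > 1.96** (strict; the two-sided normal critical value at
significance .05) pass the screen.

Because the curated inputs behind published screens of this kind are not
redistributable, the package also ships a synthetic-study generator with
planted ground truth (designated risk pathways, "responsive" regulators
whose targets concentrate there), so the whole pipeline is testable end to
end. See the methods vignette (`vignettes/mdng-screening.Rmd`) for the
model, the generator's assumptions and the package's design choices.

## Worked example

```r
library(mdngscreen)

study <- generateStudy(synthConfig(seed = 7))
study
#> SynthStudy: 200 genes, 12 pathways, 30 disease genes, 20 miRNAs, 20 drugs
#>   truth: 3 risk pathways, 5 responsive miRNAs, 5 responsive drugs

report <- runScreen(study, nPerm = 1000, seed = 7)
head(report, 6)
#>   drug_id best_pathway      S perm_mean perm_sd       Z passed rank
#> 1    DB03          P06 11.663     9.116   1.973  1.2911  FALSE    1
#> 2    DB15          P06  8.888     6.930   1.953  1.0020  FALSE    2
#> 3    DB02          P06  9.526     8.117   2.167  0.6506  FALSE    3
#> 4    DB04          P02 10.175     9.366   2.328  0.3474  FALSE    4
#> 5    DB19          P02  6.985     8.222   2.091 -0.5918  FALSE    5
#> 6    DB01         <NA>     NA     5.893   1.856      NA  FALSE    6

studyTruth(study)$responsiveDrugIds
#> [1] "DB02" "DB03" "DB04" "DB15" "DB19"
```

The five planted responsive drugs occupy ranks 1–5: each scores its `S` on
a risk pathway (`P06`, `P02`) jointly enriched by the disease genes and its
own targets, while the fifteen null drugs either share no significant
pathway with the disease (undefined `Z`, ranked last) or standardise to a
small `Z`. With only 12 pathway labels the permutation null is coarse, so
`Z` rarely clears 1.96 at this toy scale — ranking, not the absolute
cutoff, is the informative output here (the vignette discusses this
saturation).

The network itself, and its topology:

```r
disTab  <- enrich(diseaseGenes(study), studyPathways(study),
                  studyUniverse(study), entityName = "disease")
mirTabs <- enrichAll(filterRegulators(mirnaTargets(study)),
                     studyPathways(study), studyUniverse(study))
drugTabs <- enrichAll(filterRegulators(drugTargets(study)),
                      studyPathways(study), studyUniverse(study))
net <- buildMdng(disTab, mirTabs, drugTabs)
net
#> Mdng: 14 nodes (3 pathways, 6 miRNAs, 5 drugs), 26 edges
fitPowerLaw(degreeDistribution(net))
#> PowerLawFit: f(x) = 2.794 * x^(-0.3576), r^2 = 0.1590 (6 points)
```

`runAll(synthConfig(seed = 7), "out/")` performs the whole
simulate → enrich → network → score chain and writes every artifact
(`net.sif`, `stats.tsv`, `report.tsv`, enrichment tables, a JSON run
manifest). A thin command-line wrapper with subcommands
`simulate`/`enrich`/`network`/`score`/`all` is installed at
`inst/scripts/mdng.R`.

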