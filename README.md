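# tissuetalk

Differential abundance and endocrine cross-talk inference for multi-tissue,
two-condition label-free proteomics cohorts.

When mice (or any subjects) are profiled by LFQ proteomics across several
tissues under two conditions — say thermoneutral vs cold housing — two
questions dominate: which proteins changed in each tissue, and which
tissues signal to which others through secreted proteins. `tissuetalk` is
an R package (S4 classes on top of `SummarizedExperiment`) for analysts who
have per-tissue protein × sample intensity tables, sample metadata keyed by
subject, a secreted-protein annotation, and optionally gene sets in GMT
format.

## Methods at the core

**Differential abundance.** Per tissue, each protein with ≥ `minPerGroup`
non-missing values per group is tested with the pooled-variance Student *t*
(df = *n*<sub>a</sub> + *n*<sub>b</sub> − 2) on log2(v + pseudo) values;
fold changes are log2 of the raw group-mean ratio; p-values get the
Benjamini–Hochberg step-up q within the tissue. Zero-variance proteins are
excluded with a reason, never given p = 0.

**Directional cross-talk (correlation-count scoring).** For an ordered
tissue pair A → B, every secreted protein *s* of A is correlated with every
protein *t* of B across subject-paired samples. With *c<sub>s</sub>* =
#{*t* : p<sub>st</sub> < α}, the edge score is

&nbsp;&nbsp;&nbsp;&nbsp;raw(A→B) = Σ<sub>s</sub> *c<sub>s</sub>*,&nbsp;&nbsp;
normalized(A→B) = raw / (#secreted tested × #targets tested) ∈ [0, 1],

which equals α under a global null and is comparable across tissue pairs of
different proteome sizes. Candidate messengers are ranked by the product of
their mean origin-abundance rank and their count rank; a chosen candidate's
signed correlation vector against the whole target proteome gives its
predicted target program and a preranked statistic for enrichment.

**Gene-set machinery.** A standardized mean-rank single-sample score
(mean 0, sd 1 under random membership; rank-based, hence invariant to
monotone transforms), classic weighted running-sum preranked enrichment
with a gene-label permutation null (ES, NES, permutation p with the
+1 correction), and the hypergeometric overrepresentation test with an
explicit background (the tissue's detected proteome).

**Synthetic cohorts with planted truth.** `simulateCohort()` generates
log-normal multi-tissue cohorts with known condition effects and planted
secreted-driver → target-module edges (the generator's model and defaults
are documented in `vignettes/tissue-crosstalk.Rmd`), so calibration and
recovery are testable end to end.

## Worked example

```r
library(tissuetalk)

spec <- cohortSpec(tissues = c("liver", "sWAT"), proteinsPerTissue = 300,
                   nSubjectsPerCondition = 8, fracRegulated = 0.25, seed = 42)
edge <- plantedEdge("liver", "sWAT", moduleSize = 60, couplingBeta = 1,
                    moduleNoiseSd = 0.15)
sim <- simulateCohort(spec, edge)

diffLiver <- differentialTable(sim$proteomes$liver, sim$metadata,
                               conditions = spec$conditions)
diffLiver
#> DifferentialResult: liver, cold_5C vs thermoneutral_30C
#>   300 proteins tested, 55 significant at q < 0.05; 0 excluded

net <- crosstalkNetwork(sim$proteomes, sim$metadata, sim$secreted)
net$edges[, c("origin", "target", "raw_score", "normalized_score")]
#>   origin target raw_score normalized_score
#> 1  liver   sWAT      1438       0.10651852
#> 2   sWAT  liver       997       0.07385185
```

The planted direction (liver → sWAT) scores above its reverse; both exceed
the null level α = 0.05 because the screen pools a genuine 60-protein
module with chance correlations. The driver is recovered as the top
candidate — high origin abundance (rank 2 of 45 secreted) and the largest
correlation count:

```r
head(rankCandidates(net$edgeObjects[["liver->sWAT"]], sim$proteomes$liver), 3)
#>   protein_id count origin_abundance_rank effect_rank rank_product final_rank
#> 1      P0074    68                     2           1            2          1
#> 2      P0004    65                     3           4           12          2
#> 3      P0146    12                     1          33           33          3
sim$truth$edges[[1]]$driverProtein
#> [1] "P0074"

pairing <- alignSubjects(sim$proteomes$liver, sim$proteomes$sWAT, sim$metadata)
pred <- predictTargets("P0074", sim$proteomes$liver, sim$proteomes$sWAT, pairing)
mean(sim$truth$edges[[1]]$targetModule %in% predictedTargets(pred))
#> [1] 0.95

prerankedGSEA(predictionRanking(pred), sim$truth$edges[[1]]$targetModule,
              nPermutations = 1000, seed = 1, setName = "planted_module")
#>         set_name        es      nes      p_perm n_permutations seed size
#> 1 planted_module 0.9706282 2.615779 0.001005025           1000    1   60
```

95% of the planted target module is recovered at α = 0.05, and the module
is maximally enriched in the candidate's signed-correlation ranking
(ES ≈ 0.97, permutation p at its 1/(n+1) floor).

The same analysis runs file-to-file: `runPipeline()` takes a YAML/list
configuration (see `?runPipeline`; a packaged synthetic fixture lives in
`inst/extdata/`) and writes seeded, hash-stamped, byte-reproducible result
tables. `inst/cli/tissuetalk.R` wraps it for shell use.

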