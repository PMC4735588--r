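# sncmirror

Sex-stratified rank-product analysis of small non-coding RNA (miRNA and
snoRNA) expression across the relapse and remission phases of a
relapsing-remitting cohort, with detection of the **mirror pattern**:
probes dysregulated in *opposite* directions in the two phases when both
are referenced to healthy controls.

The package is aimed at transcriptomics analysts working with probe-level
sncRNA microarray data from paired clinical designs (each patient sampled
once per phase, plus unpaired controls). It provides the full analysis
chain as tested, seed-reproducible R functions, and a synthetic-cohort
generator with planted ground truth so every stage can be exercised and
validated without access to raw arrays.

## What it computes

**Differential expression** uses the rank product. For probe *g* over *K*
ratio columns (one per patient in a paired design; one per case-control
cross pair in an unpaired design), with *r<sub>gk</sub>* the rank of the
probe's log2 ratio in column *k*:

> RP(g) = ( &prod;<sub>k</sub> r<sub>gk</sub> )<sup>1/K</sup>

A small RP flags consistently extreme regulation. Significance comes from
a permutation null — probe labels shuffled within each ratio column for
paired designs, within each underlying array (ratio columns rebuilt) for
unpaired cross-pair designs, which preserves the dependence among columns
sharing an array. Each probe gets a permutation p-value and a pFP
(expected proportion of false positives at its rank, the rank-product
analogue of FDR); probes pass at p &le; 0.001 and pFP &lt; 0.05.

**Mirror analysis** intersects the significant sets of the two phase
comparisons and labels each shared probe opposite or concordant from its
control-referenced fold-change signs. Under the null that each shared
probe is opposite with probability ½ independently, the exact one-sided
sign test gives

> p = &sum;<sub>i=k..n</sub> C(n, i) (½)<sup>n</sup>

for *k* opposite among *n* shared — 8 of 8 opposite yields p = 0.0039.

**Downstream**, predicted miRNA-target interactions are filtered by
supporting-source count (&ge; 3), confidence score (&ge; 40 on the 0-100
scale), target expression in blood, and anti-correlated fold change, then
assembled into an annotated bipartite miRNA&rarr;gene network (TF and
GWAS flags, degree, weak components). Network genes are tested for
gene-set over-representation (hypergeometric, Benjamini-Hochberg). qPCR
plates are quantified by 2<sup>&minus;&Delta;&Delta;CT</sup> against dual
endogenous controls, with Pearson cross-platform concordance and
Shapiro-Wilk-gated t / Wilcoxon group comparisons.

## Worked example

Simulate a cohort of 13 all-female patients (relapse + remission samples)
and 13 controls with 20 planted differentially expressed probes per phase
signature, 8 of them mirror probes, then run the core chain:

```r
library(sncmirror)

cfg <- cohort_config(n_patients = 13, n_controls = 13, n_probes = 500,
                     sex_ratio = 1, n_de_relapse_f = 20, n_de_remission_f = 20,
                     n_mirror = 8, effect_log2 = 2, noise_sd = 0.3, seed = 42)
sim <- simulate_cohort(cfg)

flt <- detection_filter(sim$experiment)
flt$summary
#> 421 / 500 probes retained (84.20%)

de_rel <- differential_expression(flt$experiment,
  comparison("relapse", "relapse", "remission", paired = TRUE,
             stratum = "females"),
  n_permutations = 1000, seed = 42)
de_rel
#> DifferentialResult 'relapse' (relapse vs remission, paired, stratum females)
#>   421 probes, K = 13 columns, 1000 permutations, 20 significant

de_rem <- differential_expression(flt$experiment,
  comparison("remission", "remission", "control", stratum = "females"),
  n_permutations = 1000, seed = 42)

mir <- shared_signature(de_rel, de_rem,
                        control_referenced_fc(flt$experiment,
                                              stratum = "females"))
mir
#> MirrorReport: 8 shared, 8 opposite (100%), sign-test p = 0.003906
```

Both phase signatures recover exactly their 20 planted probes; the 8
probes shared between them are the planted mirror set, all labelled
opposite, and the sign test puts the concordance null at p = 0.0039 —
the shared signature is overwhelmingly mirror-patterned rather than a
chance overlap.

The full pipeline (preprocess &rarr; DE per stratum &rarr; mirror &rarr;
networks &rarr; enrichment &rarr; qPCR) runs from one declarative YAML
config:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "sncmirror"))
res <- run_pipeline(cfg, "demo_out")
```

or from the shell via `inst/scripts/sncmirror-run.R --config ... --out ...`.

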