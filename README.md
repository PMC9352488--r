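# proxscreen

Network-proximity target discovery and drug screening for type 2 diabetes
mellitus (T2DM), built as a tested R package plus a set of narrative
analysis drivers.

## The problem

Identifying a therapeutic target for a heterogeneous disease like T2DM and
then finding drugs likely to act on it involves a chain of well-established
but rarely integrated analyses: which islet β-cell subpopulations shift
between patients and controls, which of their marker genes sit in densely
connected regions of the protein–protein interaction (PPI) network, which of
those genes diagnose the disease in an independent bulk cohort, and which
drugs' targets are unexpectedly close — in network terms — to the resulting
disease gene set. proxscreen implements that whole chain for computational
biologists who want each stage as a reusable, unit-tested function rather
than a one-off script.

## The methods at its core

* **Cluster differential abundance** — per cluster, fold change of
  condition-normalized cell proportions, FC = (n_cT/N_T)/(n_cN/N_N), with a
  two-sided Fisher exact test; clusters with FC > 4 or FC < 0.25 and
  P < 0.05 are called.
* **MCODE** dense-module detection: vertex weight = k · density of the
  highest k-core of each node's closed neighborhood, seeded expansion at
  vertex weight percentage 0.2, 2-core haircut.
* **Diagnostic ranking** — oriented ROC AUC via the Mann–Whitney identity
  plus a two-sided Wilcoxon test; the hub gene is the top-AUC candidate
  *among* the differentially expressed ones.
* **Correlation expansion** — Pearson r with t-transform p-values; genes
  with r > 0.95 and P < 0.001 join the disease gene set S.
* **Network proximity** — for a drug with target set T,

      d(S,T) = (1/|T|) Σ_{t∈T} [ min_{s∈S} d(s,t) + ω_t ],
      ω_t = −ln(D_t + 1) if t ∈ S, else 0

  standardized as z = (d − μ)/σ against 1000 random target-size-matched
  node sets; candidates pass global Benjamini–Hochberg FDR < 0.001.

A synthetic-data module (`synth_config()`, `gen_network()`,
`gen_expression()`, `gen_cell_table()`, `gen_drug_targets()`) generates
every input with planted ground truth — cliques for MCODE, a
factor-model co-expression module for the expansion, an enriched cluster
for the abundance test, a proximal drug for the screen — so the pipeline is
testable end to end. See `vignettes/methods.Rmd` for the full model
description.

## Worked example

The `analysis/` drivers run the five stages in order on the synthetic study
system and print what they find:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_single_cell.R
Rscript analysis/03_network_modules.R
Rscript analysis/04_diagnostics.R
Rscript analysis/05_drug_screen.R
```

Output of a run (seed 20260930):

```
network: 300 nodes, 639 edges
planted cliques: 8 and 6 nodes
...
differentially abundant clusters: C2, C4
...
MCODE complexes: 1 ; top score: 8
top complex contains 100% of the planted module
...
best candidate: G0001 (AUC 1.000, Wilcoxon p 0.00041)
hub gene: G0001
correlated genes at r > 0.95 & p < 0.001: 7 ; disease set size: 8
...
drugs screened: 51
candidates at FDR < 0.001: 1
top drug: DRUG_PLANTED (d = -0.918, z = -6.22, fdr = 1.2e-08)
```

Reading it: the condition-enriched cluster C2 is recovered (C4 appears
through compositional depletion — enriching one cluster necessarily thins
the rest; the vignette discusses this); MCODE returns the planted 8-clique
intact with the maximal score 8 (density 1 × 8 members); the planted
discriminative gene G0001 is the hub with perfect separation of the 18
samples; its expansion recovers the other 7 module genes; and the planted
proximal drug is the only FDR < 0.001 candidate, about 6 standard
deviations closer to the disease genes than random target sets. A negative
d is possible because targets inside the disease set earn the −ln(D+1)
bonus.

The same chain is available as one call:

```r
library(proxscreen)
m <- run_pipeline(pipeline_config(synth = synth_config(seed = 1)), "out/")
m$selected_clusters; m$hub; m$top_drug
```

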