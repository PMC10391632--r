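# bmpc — bone-marrow plasma-cell single-cell + repertoire analysis

Human bone-marrow antibody-secreting cells (ASCs) range from newly minted
plasmablasts to long-lived plasma cells. Studies of their maturation pair
single-cell transcriptomes (cells × genes UMI counts) with matched
heavy-chain V(D)J repertoires, and lean on a handful of bespoke
computational stages that this package implements as tested, reusable
code:

* **Quality control** — exact cell filters: remove cells with
  mitochondrial UMI fraction ≥ 30%, detected genes ≤ 800 or ≥ 6000, UMIs
  ≤ 1000 or ≥ 60000, immunoglobulin UMI fraction ≤ 5%, or any diagnostic
  contaminant marker (CD3E, FCGR3A, CD14, NKG7, GNLY, HBB, MS4A1, PAX5,
  IRF8); Ig genes stripped from variable-feature lists by locus prefix.
* **Cluster stability** — the plain Rand Index
  RI = (#pairs co-clustered in both + #pairs separated in both) / C(n,2),
  averaged over all pairs of labelings from a clustering-parameter grid
  (dims 50/60/70 × PCs 30/50/70 × resolutions 0.2/0.5/1.0/1.5); the
  clusterer is a pluggable contract.
* **Signatures** — markers (avgLogFC > 0.25, Bonferroni p < 0.05),
  preranked gene lists scored by −log₁₀(p)·sign(avgLogFC), a weighted
  Kolmogorov–Smirnov enrichment score with permutation significance, and
  per-cell pathway U-scores (mean normalized expression of
  maturation-associated pathway genes) summarized per cluster.
* **Transcription factors** — assignment to the highest-expressing
  cluster, distinctness at ≥ 0.25 avgLogFC over the runner-up, and
  STRING-style edge filtering (combined score > 500, same cluster).
* **Repertoire** — clonal lineages (same subject/V/J/CDR3 length, 85%
  CDR3 homology, single linkage; clones at 98%), somatic-hypermutation
  frequencies over non-gap V bases per region, replacement/silent
  classification by single-substitution codon translation with the R/S
  silent floor (s → 1 when r > 0, s = 0) and the R/S > 2.9
  antigen-selection flag, Morisita–Horn connectivity
  C(x,y) = 2Σxᵢyᵢ/((Σxᵢ²/X² + Σyᵢ²/Y²)·X·Y), and an ANOVA + Tukey HSD
  permutation test with p = #{Tukey p\* < observed p}/n_perm.
* **Synthetic data** — a generator for paired expression + repertoire
  datasets with full ground truth (cluster labels, lineage membership,
  per-site replacement/silent truth, designed QC violations), so the
  whole pipeline is verifiable offline.

See `vignettes/bm-asc-methods.Rmd` for the full methods account.

## Worked example

The analysis is organized as numbered drivers over the package functions:

```sh
Rscript analysis/01_simulate.R          # synthetic dataset + ground truth
Rscript analysis/02_qc.R                # cell filters
Rscript analysis/03_cluster_stability.R # Rand-Index grid scan
Rscript analysis/04_signatures.R        # markers, enrichment, U-scores
Rscript analysis/05_tf_networks.R       # TF assignment + edges
Rscript analysis/06_repertoire.R        # lineages, SHM, R/S, connectivity
```

`01` writes a 1,030-cell × 800-gene dataset (1,000 regular cells plus 30
designed QC violations, 5 per rule) and a 426-record repertoire under
`results/data/`. `02` then prints:

```
per-rule removals (a cell may violate several):
      mito  genes_low    umi_low genes_high   umi_high     ig_low
         5          5          5          5          5          5
contaminants flagged: 20
kept 980 of 1030 cells
```

— each designed violation is caught by exactly its rule, and the 20
simulated contaminant cells are flagged by the marker screen. `06` prints
the repertoire summary:

```
lineages: 200  clones: 386  mean global SHM: 6.84%
 region    r    s ratio selected
    FR1 1645  507  3.24     TRUE
   CDR1  510  166  3.07     TRUE
    FR2 1110  385  2.88    FALSE
   CDR2  567  153  3.71     TRUE
    FR3 3103  946  3.28     TRUE
    CDR 1077  319  3.38     TRUE
     FR 5858 1838  3.19     TRUE
 global 6935 2157  3.22     TRUE
```

The 200 seeded lineages are recovered exactly at 85% CDR3 homology; the
98% clone threshold splits them into 386 clones; the recovered mean SHM
(6.84%) matches the simulated 6.89% per-base rate within sampling error;
and aggregate R/S ratios sit near the ~3 expected for random substitutions
in this codon composition, with the `selected` column applying the strict
R/S > 2.9 flag. Tables land under `results/`.

Equivalently, `run_pipeline(pipeline_config(seed = 1))` executes all
stages in one call and writes a provenance manifest; rerunning an
identical configuration reproduces byte-identical outputs.

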