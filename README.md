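# lhcomplex

Quantitative analysis of **locus heterogeneity (LH) through protein
complexes**: how often do mutations in *different* genes that cause the
same disease — or clinically similar diseases of one **phenotypic series
(PS)** — hit members of the same **protein complex (PC)?**

The package is for computational geneticists and systems biologists who
want to run, extend or stress-test this analysis without live OMIM /
Gene Ontology / Mouse Genome Informatics downloads. It consumes
documented TSV/OBO dialects of those resources, ships a synthetic-universe
generator with planted ground truth, and covers the whole analysis:

- **Disease catalog** — parse an OMIM-style morbid map; discard
  unconfirmed diseases (`?`), non-diseases (`[ ]`), susceptibilities
  (`{ }`), non-molecular mapping keys (1, 2, 4), unmapped or non-coding
  genes; assemble disease-based and series-based protein-set families.
- **Complex catalog** — select cellular-component terms named
  `*complex*`, attach directly annotated proteins, remove parents of
  parents, generic umbrella terms and singletons.
- **Intersection** — for every group-complex pair sharing at least two
  proteins, the Jaccard coefficient
  `JC = |S ∩ C| / (|S| + |C| − |S ∩ C|)`, with per-group maxima,
  histograms and moments.
- **Randomization** — four permutation controls (pseudo-PS, pseudo-PC,
  non-LH pool, pairwise enrichment) with Z-scores from simulated nulls.
- **Ortholog augmentation** — promote complex members to *presumptive
  disease proteins* when their mouse ortholog's phenotype best-matches a
  human phenotype of the series, and recompute
  `JC' = (i + m) / (g + p − (i + m))`; gain-of-function and pre-birth
  lethality annotation tables.
- **Univocality** — separate 1:1 series-complex relations from
  redundancy (parent-child complexes, shared parents, majority-shared
  membership) and allele heterogeneity.

## Worked example

Generate a synthetic universe (planted with the canonical overlap
geometries) and run the full series-based analysis:

```r
library(lhcomplex)

w   <- generate_universe(world_config(seed = 1), "world")
res <- run_lh_pipeline(w$paths, null_reps = 1000, seed = 1)

res$summary
#> <lh_summary> 13/53 groups hit a complex (24.5%); 18/81 complexes hit (22.2%)
#>   JC 0.30 +/- 0.20 (median 0.25) over 13 records
```

About a quarter of the eligible series share two or more proteins with a
complex. Among the records are the planted geometries — a 4-protein
series fully inside a 12-member complex, and a 12-protein series sharing
the same 5 proteins with a 14- and an 88-member complex (same
intersection, very different coefficients, because the union term grows
with complex size):

```r
res$records[res$records$group_id %in% c("PS310001", "PS310002"), ]
#>   group_id    term_id n_shared         jc group_size pc_size
#> 1 PS310001 GO:0800001        4 0.33333333          4      12
#> 2 PS310002 GO:0800002        5 0.23809524         12      14
#> 3 PS310002 GO:0800003        5 0.05263158         12      88
```

The permutation controls show the real series hit complexes far more
often than size-matched random protein sets, and that same-complex
protein pairs are strongly enriched for causing different diseases of
one series:

```r
res$nulls$pseudo_ps
#> <lh_null_result:pseudo_ps> observed 13 vs null 5.59 +/- 1.96 over 1000 reps (Z = 3.8)
res$nulls$pairwise
#> <lh_null_result:pairwise> observed 35 vs null 6.44 +/- 2.43 over 1000 reps (Z = 11.8)
#>   observed/null ratio = 5.4
```

Mouse-ortholog augmentation promotes the two planted complex members
whose murine mutants phenocopy the series, raising the coefficient from
0.33 to 0.60:

```r
res$augmented[res$augmented$group_id == "PS310001", ]
#>   group_id    term_id n_shared n_presumptive        jc jc_augmented
#> 1 PS310001 GO:0800001        4             2 0.3333333          0.6
```

and the redundancy filters collapse parent-child and majority-shared
complex pairs into univocal relations:

```r
res$relations
#> <lh_relations> 11/13 groups univocal; 5 redundant complex pairs, 1 allele-heterogeneity series pairs
```

Every generated bundle carries a `truth.json` manifest; the test suite
asserts that the pipeline recovers each planted fact exactly. A thin
command-line wrapper is installed under `inst/cli/lh-pipeline.R`
(`simulate` and `run` subcommands) for shell use.

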